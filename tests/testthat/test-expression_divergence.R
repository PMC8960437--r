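make_meta <- function(counts, studies) {
  data.frame(sample = colnames(counts), study = studies)
}

test_that("median-of-ratios size factors respond to library scaling only", {
  counts <- matrix(rpois(200, 50) + 1, ncol = 2,
                   dimnames = list(NULL, c("s1", "s2")))
  counts[, 2] <- counts[, 1]
  expect_equal(size_factors(counts), c(s1 = 1, s2 = 1))
  counts2 <- cbind(s1 = counts[, 1], s2 = counts[, 1] * 2L)
  sf <- size_factors(counts2)
  expect_equal(unname(sf[2] / sf[1]), 2)
  # normalised values coincide after scaling
  norm <- sweep(counts2, 2, sf, "/")
  expect_equal(norm[, 1], norm[, 2])
})

test_that("study centering removes a planted global batch shift", {
  set.seed(51)
  base <- matrix(2^rnorm(300, 7, 1), ncol = 6)
  counts <- round(base)
  colnames(counts) <- paste0("s", 1:6)
  rownames(counts) <- paste0("g", 1:50)
  meta <- make_meta(counts, rep(c("st1", "st2", "st3"), each = 2))
  shifted <- counts
  shifted[, 5:6] <- round(counts[, 5:6] * 4)   # +2 log2 on study 3
  n0 <- normalize_counts(counts, meta)
  n1 <- normalize_counts(shifted, meta)
  # per-study grand means agree with the unshifted data to numerical noise
  m0 <- mean(n0$log_expr[, 5:6])
  m1 <- mean(n1$log_expr[, 5:6])
  expect_lt(abs(m1 - m0), 1e-9)
  # zero-centering: species grand mean is exactly zero
  expect_lt(abs(mean(n1$log_expr)), 1e-9)
  expect_lt(abs(mean(n0$log_expr)), 1e-9)
})

test_that("single-sample studies skip centering with a warning", {
  counts <- matrix(rpois(30, 100), ncol = 3,
                   dimnames = list(paste0("g", 1:10), paste0("s", 1:3)))
  meta <- make_meta(counts, c("st1", "st1", "st2"))
  expect_warning(normalize_counts(counts, meta), "single sample")
})

test_that("Welch statistics match the closed-form and stats::t.test", {
  r <- welch_divergence(c(1, 2, 3), c(2, 4, 6))
  expect_equal(r$t, -1.549, tolerance = 1e-3)
  expect_equal(r$df, 2.941, tolerance = 1e-3)
  expect_equal(r$log2_ratio, -2)

  # identical vectors: ratio 0, p 1
  same <- welch_divergence(c(1, 1), c(1, 1))
  expect_equal(same$p, 1)
  expect_equal(same$log2_ratio, 0)

  set.seed(52)
  for (i in 1:200) {
    a <- rnorm(sample(3:6, 1)); b <- rnorm(sample(3:6, 1), sd = 2)
    got <- welch_divergence(a, b)
    ref <- t.test(a, b)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
    # antisymmetry
    rev <- welch_divergence(b, a)
    expect_equal(rev$t, -got$t)
    expect_equal(rev$p, got$p)
  }
})

test_that("divergence table joins orthologs and vectorises the Welch test", {
  set.seed(53)
  ma <- matrix(rnorm(30), ncol = 3,
               dimnames = list(paste0("a", 1:10), paste0("st", 1:3)))
  mb <- matrix(rnorm(30), ncol = 3,
               dimnames = list(paste0("b", 1:10), paste0("st", 1:3)))
  ort <- data.frame(gene_a = paste0("a", 1:10), gene_b = paste0("b", 1:10))
  div <- divergence_table(ma, mb, ort)
  expect_equal(nrow(div), 10L)
  for (i in c(1, 5, 10)) {
    ref <- welch_divergence(ma[i, ], mb[i, ])
    expect_equal(div$t[i], ref$t)
    expect_equal(div$p_unadjusted[i], ref$p)
    expect_equal(div$log2_ratio[i], ref$log2_ratio)
  }
  # orthologs absent from a matrix are dropped, not errored
  ort2 <- rbind(ort, data.frame(gene_a = "missing", gene_b = "b1"))
  expect_equal(nrow(divergence_table(ma, mb, ort2)), 10L)
})

test_that("under a global null the Welch p-values are calibrated", {
  set.seed(54)
  hits <- 0L; total <- 0L
  for (i in 1:200) {
    ma <- matrix(rnorm(200 * 3), ncol = 3,
                 dimnames = list(paste0("g", 1:200), NULL))
    mb <- matrix(rnorm(200 * 3), ncol = 3,
                 dimnames = list(paste0("g", 1:200), NULL))
    ort <- data.frame(gene_a = rownames(ma), gene_b = rownames(mb))
    div <- divergence_table(ma, mb, ort)
    hits <- hits + sum(div$p_unadjusted < 0.05)
    total <- total + nrow(div)
  }
  expect_equal(hits / total, 0.05, tolerance = 0.2)   # 0.05 +/- 0.01
})

test_that("per-class statistics report means, spreads and reference tests", {
  set.seed(55)
  x <- c(rnorm(50, 0, 1), rnorm(50, 2, 1), rnorm(50, 0, 1))
  cls <- rep(c("conserved", "a_specific", "alternative"), each = 50)
  rec <- data.frame(log2_ratio = x)
  st <- class_divergence_stats(rec, cls)
  per <- st$per_class
  expect_equal(per$p_vs_conserved[per$class == "a_specific"],
               t.test(x[51:100], x[1:50])$p.value)
  expect_true(is.na(per$p_vs_conserved[per$class == "conserved"]))
  # identical distributions: F near 1, never significant by construction
  expect_equal(st$f_conserved_vs_alternative$F,
               var(x[1:50]) / var(x[101:150]))
  # two identical classes give F exactly 1
  rec2 <- data.frame(log2_ratio = c(x[1:50], x[1:50]))
  st2 <- class_divergence_stats(rec2, rep(c("conserved", "alternative"),
                                          each = 50))
  expect_equal(st2$f_conserved_vs_alternative$F, 1)
  # a class with one member yields missing statistics
  st3 <- class_divergence_stats(data.frame(log2_ratio = c(x[1:50], 5)),
                                c(rep("conserved", 50), "b_specific"))
  expect_true(is.na(st3$per_class$mean[st3$per_class$class == "b_specific"]))
})

test_that("tail enrichment reproduces the hand-computed chi-square", {
  # 49 genes beyond +5, 26 of them a_specific; 951 below, 24 specific
  cls <- c(rep("a_specific", 50), rep("conserved", 950))
  ratio <- c(rep(6, 26), rep(0, 24), rep(6, 23), rep(0, 927))
  rec <- data.frame(log2_ratio = ratio)
  suppressWarnings(te <- extreme_tail_enrichment(rec, cls, 5))
  up <- te[te$tail == "upper", ]
  expect_equal(up$n_tail, 49L)
  expect_equal(up$n_specific_in_tail, 26L)
  expect_equal(up$proportion, 26 / 49)
  tab <- table(cls == "a_specific", ratio > 5)
  expect_equal(up$chi2, oracle_chisq(tab)$chi2, tolerance = 1e-12)
  # empty lower tail: missing with a warning
  expect_warning(te2 <- extreme_tail_enrichment(rec, cls, 5), "lower")
  expect_true(is.na(te2$p[te2$tail == "lower"]))
})

test_that("count-difference regression recovers exact and planted slopes", {
  rec <- data.frame(log2_ratio = 0.5 * c(-3, -1, 0, 2, 4))
  fit <- suppressWarnings(ratio_vs_count_difference(rec, c(-3, -1, 0, 2, 4)))
  expect_equal(fit$slope, 0.5, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_error(
    ratio_vs_count_difference(data.frame(log2_ratio = rnorm(5)),
                              rep(0, 5)),
    "identical")
  # only genes bound in both species enter the fit
  cls <- c("conserved", "conserved", "alternative", "unbound", "unbound")
  fit2 <- suppressWarnings(ratio_vs_count_difference(
    data.frame(log2_ratio = c(1, 2, 3, 100, -100)),
    c(1, 2, 3, 4, 5), cls))
  expect_equal(fit2$n, 3L)
  expect_equal(fit2$slope, 1, tolerance = 1e-9)
})

test_that("planted regression slopes are recovered within their confidence intervals", {
  set.seed(56)
  cover <- 0L
  n_rep <- 200
  for (i in seq_len(n_rep)) {
    dn <- sample(-5:5, 500, replace = TRUE)
    y <- 0.8 * dn + rnorm(500, 0, 1.5)
    fit <- ratio_vs_count_difference(data.frame(log2_ratio = y), dn)
    ci <- confint(fit$fit)[2, ]
    if (ci[1] <= 0.8 && 0.8 <= ci[2]) cover <- cover + 1L
  }
  expect_gte(cover / n_rep, 0.93)
})
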