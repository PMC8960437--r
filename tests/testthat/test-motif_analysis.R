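certain_pwm <- function(cons = c("A", "C", "G", "T")) {
  m <- matrix(1e-12, 4, length(cons), dimnames = list(c("A", "C", "G", "T"),
                                                      NULL))
  for (j in seq_along(cons)) m[cons[j], j] <- 1
  pwm(sweep(m, 2, colSums(m), "/"), name = "certain")
}

random_pwm <- function(w, concentration = 0.6) {
  m <- matrix(runif(4 * w, 0.02, 1), 4, w)
  j <- cbind(sample(1:4, w, replace = TRUE), 1:w)
  m[j] <- m[j] + concentration * 4
  pwm(sweep(m, 2, colSums(m), "/"), name = paste0("rnd", w))
}

test_that("PWM construction validates and normalises", {
  expect_error(pwm(matrix(1, 3, 5)), "nrow")
  p <- tbox_pwm()
  expect_equal(colSums(p$mat), rep(1, 12))
  expect_equal(p$width, 12L)
})

test_that("JASPAR and MEME round-trips preserve matrices and background", {
  p <- tbox_pwm()
  f <- withr::local_tempfile()
  writeLines(c(">MA0000.1 TBOX_synthetic",
               paste("A [", paste(round(p$mat[1, ] * 1000), collapse = " "), "]"),
               paste("C [", paste(round(p$mat[2, ] * 1000), collapse = " "), "]"),
               paste("G [", paste(round(p$mat[3, ] * 1000), collapse = " "), "]"),
               paste("T [", paste(round(p$mat[4, ] * 1000), collapse = " "), "]")),
             f)
  pj <- read_jaspar(f)
  expect_equal(names(pj), "TBOX_synthetic")
  expect_equal(pj[[1]]$mat, p$mat, tolerance = 1e-2)

  f2 <- withr::local_tempfile()
  write_meme(list(p), f2, background = c(0.3, 0.2, 0.2, 0.3))
  pm <- read_meme(f2)
  expect_equal(pm[[1]]$mat, p$mat, tolerance = 1e-6)
  expect_equal(attr(pm, "background"), c(0.3, 0.2, 0.2, 0.3))
})

test_that("the exact score distribution behaves at its extremes", {
  p <- certain_pwm(c("A", "C", "G", "T"))
  d <- score_distribution(p, rep(0.25, 4))
  expect_lt(abs(sum(d$probs) - 1), 1e-9)
  smax <- sum(apply(d$int_scores, 2, max))
  expect_equal(score_pvalue(d, smax), 0.25^4)   # one word attains the max
  expect_equal(score_pvalue(d, d$support[1] - 100), 1)  # below all scores
  expect_error(score_distribution(tbox_pwm(), c(0.5, 0.5, 0, 0)),
               "zero background")
})

test_that("the dynamic program equals exhaustive enumeration up to width 8", {
  set.seed(61)
  for (w in 4:8) {
    p <- random_pwm(w)
    bg <- as.numeric(rmultinom(1, 400, rep(0.25, 4)) / 400)
    if (any(bg == 0)) bg <- rep(0.25, 4)
    d <- score_distribution(p, bg)
    words <- as.matrix(expand.grid(rep(list(1:4), w)))
    word_scores <- words
    S <- d$int_scores
    scores <- vapply(seq_len(nrow(words)), function(i) {
      sum(S[cbind(words[i, ], 1:w)])
    }, integer(1))
    word_probs <- vapply(seq_len(nrow(words)), function(i) {
      prod(bg[words[i, ]])
    }, numeric(1))
    enum <- tapply(word_probs, scores, sum)
    got <- d$probs[d$probs > 1e-300]
    expect_equal(sort(unique(scores)), d$support[d$probs > 1e-300])
    expect_equal(as.numeric(enum[order(as.integer(names(enum)))]),
                 as.numeric(got), tolerance = 1e-12)
    # spot-check tail p-values against enumeration
    for (s in sample(unique(scores), 3)) {
      expect_equal(score_pvalue(d, s), sum(word_probs[scores >= s]),
                   tolerance = 1e-12)
    }
  }
})

test_that("scanning finds planted consensus matches on both strands", {
  p <- tbox_pwm()
  cons <- "AGGTGTGAAAAT"
  rc <- as.character(reverseComplement(DNAString(cons)))
  seqs <- c(fwd = paste0(strrep("C", 15), cons, strrep("A", 15)),
            rev = paste0(strrep("G", 15), rc, strrep("T", 15)))
  hits <- scan_sequences(seqs, p, background = rep(0.25, 4))
  fwd <- hits[hits$seq == "fwd", ]
  expect_true(any(fwd$strand == "+" & fwd$offset == 16))
  rev <- hits[hits$seq == "rev", ]
  expect_true(any(rev$strand == "-" & rev$offset == 16))
})

test_that("scanning skips N windows and warns on short sequences", {
  p <- tbox_pwm()
  with_n <- paste0(strrep("C", 5), "AGGTGNGAAAAT", strrep("C", 5))
  hits <- scan_sequences(c(s = with_n), p, background = rep(0.25, 4))
  expect_false(any(hits$offset == 6))
  expect_warning(
    h2 <- scan_sequences(c(s = "ACGT"), p, background = rep(0.25, 4)),
    "shorter")
  expect_equal(nrow(h2), 0L)
})

test_that("scanning is strand symmetric under reverse complementation", {
  set.seed(62)
  p <- random_pwm(8)
  seqs <- vapply(1:30, function(i) {
    paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE), collapse = "")
  }, "")
  names(seqs) <- paste0("s", 1:30)
  rc <- vapply(seqs, function(s) {
    as.character(reverseComplement(DNAString(s)))
  }, "")
  h1 <- scan_sequences(seqs, p, p_threshold = 0.01,
                       background = rep(0.25, 4))
  h2 <- scan_sequences(rc, p, p_threshold = 0.01,
                       background = rep(0.25, 4))
  expect_equal(table(factor(h1$seq, names(seqs))),
               table(factor(h2$seq, names(seqs))))
})

test_that("background hit counts are Poisson-calibrated", {
  set.seed(63)
  p <- tbox_pwm()
  L <- 10000
  seqs <- c(bg = paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                       collapse = ""))
  hits <- scan_sequences(seqs, p, p_threshold = 0.004,
                         background = rep(0.25, 4))
  # expectation: 2 strands x positions x the largest attainable p under
  # the threshold (the discrete ladder sits below 0.004)
  d <- score_distribution(p, rep(0.25, 4))
  rate <- max(d$pvalues[d$pvalues < 0.004])
  lambda <- 2 * (L - p$width + 1) * rate
  expect_gt(nrow(hits), qpois(0.0025, lambda))
  expect_lt(nrow(hits), qpois(0.9975, lambda))
})

test_that("motif proportions carry continuity-corrected Wilson intervals", {
  # degenerate ends of the scale
  p <- tbox_pwm()
  none <- vapply(1:20, function(i) strrep("C", 40), "")
  names(none) <- paste0("n", 1:20)
  mp0 <- motif_proportion(none, p, background = rep(0.25, 4))
  expect_equal(mp0$k, 0L)
  expect_equal(mp0$ci_low, 0)
  all_hit <- vapply(1:20, function(i) {
    paste0(strrep("C", 10), "AGGTGTGAAAAT", strrep("C", 10))
  }, "")
  names(all_hit) <- paste0("a", 1:20)
  mp1 <- motif_proportion(all_hit, p, background = rep(0.25, 4))
  expect_equal(mp1$proportion, 1)
  expect_equal(mp1$ci_high, 1)
  expect_error(motif_proportion(character(0), p), "no sites")

  # the k = 19, n = 100 interval matches the closed-form oracle
  want <- oracle_wilson_cc(19, 100)
  got <- suppressWarnings(prop.test(19, 100)$conf.int)
  expect_equal(c(got[1], got[2]), want, tolerance = 1e-9)
})

test_that("Wilson interval coverage sits at the nominal level", {
  set.seed(64)
  p_true <- 0.3
  n_sim <- 2000
  ns <- sample(c(50, 200, 1000), n_sim, replace = TRUE)
  ks <- rbinom(n_sim, ns, p_true)
  covered <- vapply(seq_len(n_sim), function(i) {
    ci <- oracle_wilson_cc(ks[i], ns[i])
    ci[1] <= p_true && p_true <= ci[2]
  }, logical(1))
  expect_equal(mean(covered), 0.95, tolerance = 0.0158)  # 95% +/- 1.5 points
})

test_that("hypergeometric enrichment equals exhaustive tail summation", {
  # toy counts: 8 of 20 targets, 10 of 100 total contain the motif
  p_direct <- sum(vapply(8:20, function(x) {
    choose(10, x) * choose(90, 20 - x) / choose(100, 20)
  }, numeric(1)))
  expect_equal(phyper(7, 10, 90, 20, lower.tail = FALSE), p_direct,
               tolerance = 1e-12)

  # planted enrichment: motif in ~40% of targets, ~5% of background
  set.seed(65)
  p <- tbox_pwm()
  mk <- function(n, rate) {
    vapply(seq_len(n), function(i) {
      core <- if (runif(1) < rate) "AGGTGTGAAAAT" else strrep("C", 12)
      paste0(strrep("A", 10), core, strrep("G", 10))
    }, "")
  }
  enr <- known_motif_enrichment(mk(200, 0.4), mk(200, 0.05), list(p),
                                background = rep(0.25, 4))
  expect_gt(enr$neg_log10_p, 3)
  # identical planting rates: no signal
  enr0 <- known_motif_enrichment(mk(200, 0.2), mk(200, 0.2), list(p),
                                 background = rep(0.25, 4))
  expect_gt(enr0$p, 0.01)
  expect_error(known_motif_enrichment(character(0), mk(5, 0), list(p)),
               "empty target")
})

test_that("Benjamini-Hochberg adjustment matches the step-up formula", {
  p <- c(0.001, 0.01, 0.02, 0.8)
  expect_equal(p.adjust(p, "BH"), c(0.004, 0.02, 0.8 / 30, 0.8))
})

test_that("enrichment matrices are filtered and min-max normalised per set", {
  m <- rbind(strong = c(10, 1), weak = c(0.2, 0.1), flat = c(0, 0))
  colnames(m) <- c("set1", "set2")
  # feed enough motifs that BH keeps only the strong one
  m2 <- rbind(m, matrix(0.05, 20, 2,
                        dimnames = list(paste0("null", 1:20), NULL)))
  nm <- normalize_enrichment_matrix(m2, q_max = 0.05)
  expect_true("strong" %in% nm$kept_motifs)
  expect_false("flat" %in% nm$kept_motifs)
  expect_true(all(nm$normalized >= 0 & nm$normalized <= 1))
  # single significant motif in a single set normalises to 1
  one <- matrix(8, 1, 1, dimnames = list("only", "set1"))
  n1 <- normalize_enrichment_matrix(one)
  expect_equal(unname(n1$normalized[1, 1]), 1)
  expect_true(n1$significant[1, 1])
  # nothing significant: empty kept set
  n0 <- normalize_enrichment_matrix(matrix(0, 3, 2))
  expect_length(n0$kept_motifs, 0L)
})
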