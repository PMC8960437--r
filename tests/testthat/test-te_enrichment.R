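test_that("TE enclosure requires a single fully containing element", {
  site <- GRanges("c1", IRanges(1001, 1200))   # central window [1081, 1120]
  expect_true(te_overlap_flags(site, GRanges("c1", IRanges(1051, 1150))))
  # one base short of enclosure
  expect_false(te_overlap_flags(site, GRanges("c1", IRanges(1081, 1119))))
  # two adjacent TEs jointly covering the window do not count
  expect_false(te_overlap_flags(site, GRanges("c1", IRanges(c(1051, 1101),
                                                            c(1100, 1150)))))
})

test_that("TE enclosure matches brute-force containment on random fixtures", {
  set.seed(71)
  sites_df <- random_peak_df(300, max_pos = 1200, max_len = 80)
  te_df <- random_peak_df(120, max_pos = 1300, max_len = 120)
  sites <- peaks_df_to_granges(sites_df)
  tes <- peaks_df_to_granges(te_df)
  got <- suppressWarnings(te_overlap_flags(sites, tes))
  win <- suppressWarnings(central_window(sites))
  want <- vapply(seq_along(sites), function(i) {
    oracle_enclosed(as.character(seqnames(win))[i], start(win)[i],
                    end(win)[i],
                    data.frame(chrom = te_df$chrom, start = te_df$start,
                               end = te_df$end))
  }, logical(1))
  expect_equal(got, want)
})

test_that("TE BED reading parses classes from name suffixes", {
  f <- withr::local_tempfile()
  writeLines(c("c1\t100\t600\tL1MD2#LINE1\t0\t+",
               "c1\t800\t900\tAluY#SINE\t0\t-",
               "c2\t10\t500\tweird#XXX\t0\t+"), f)
  expect_warning(te <- read_te_bed(f), "unknown class")
  expect_equal(as.character(te$te_class), c("LINE1", "SINE", "other"))
  expect_equal(te$name, c("L1MD2", "AluY", "weird"))
})

test_that("chi-square independence matches the textbook formula", {
  tab <- matrix(c(10, 30, 20, 40), 2)
  r <- chisq_independence(tab)
  want <- oracle_chisq(tab)
  expect_equal(r$chi2, 0.794, tolerance = 1e-3)
  expect_equal(r$chi2, want$chi2, tolerance = 1e-12)
  expect_equal(unclass(r$residuals), want$residuals, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(r$df, 1L)
  expect_equal(sum(r$observed), sum(r$expected))
  # observed equal to expected: statistic and residuals vanish
  flat <- matrix(c(20, 40, 10, 20), 2)
  r0 <- chisq_independence(flat)
  expect_equal(r0$chi2, 0)
  expect_true(all(abs(r0$residuals) < 1e-12))
  # a cell above expectation has a positive residual
  expect_gt(r$residuals[2, 1], 0)
  # the literal relative variant is available behind the flag
  rr <- chisq_independence(tab, residual_type = "relative")
  expect_equal(unclass(rr$residuals),
               (want$expected * 0 + tab - want$expected) / want$expected,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(chisq_independence(matrix(c(0, 0, 5, 5), 2)), "zero margin")
})

test_that("permutation chi-square is reproducible and matches enumeration on a toy", {
  classes <- rep(c("x", "y"), each = 3)
  flags <- c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  p1 <- permutation_chisq(classes, flags, n = 4000, seed = 99)
  p2 <- permutation_chisq(classes, flags, n = 4000, seed = 99)
  expect_identical(p1$null_values, p2$null_values)
  expect_identical(p1$p_empirical, p2$p_empirical)
  # exact enumeration: the TRUE flag lands in class x (3/6) or y (3/6);
  # both placements give the same chi2, so every permutation reaches the
  # observed value and the empirical p converges to 1
  obs <- p1$observed_chi2
  expect_equal(oracle_chisq(table(classes, flags))$chi2, obs,
               tolerance = 1e-12)
  expect_equal(p1$p_empirical, 1)

  # an informative toy: 2 TRUE flags, both in class x; enumeration over all
  # C(6,2) = 15 placements gives P(chi2 >= obs) = C(3,2)*2/15... computed
  # directly below
  flags2 <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  placements <- combn(6, 2)
  chis <- apply(placements, 2, function(ix) {
    f <- logical(6); f[ix] <- TRUE
    oracle_chisq(table(classes, f))$chi2
  })
  obs2 <- oracle_chisq(table(classes, flags2))$chi2
  exact_p <- mean(chis >= obs2 - 1e-12)
  p3 <- permutation_chisq(classes, flags2, n = 9999, seed = 123)
  se <- sqrt(exact_p * (1 - exact_p) / 9999)
  expect_lt(abs(p3$p_empirical - exact_p), 4 * se + 2e-4)
  expect_error(permutation_chisq(rep("x", 6), flags2), "two site classes")
})

test_that("permutation p-values are uniform under the null", {
  set.seed(72)
  n_runs <- 200
  ps <- vapply(seq_len(n_runs), function(i) {
    classes <- sample(rep(c("a", "b", "c"), times = c(200, 200, 100)))
    flags <- runif(500) < 0.15    # independent of the classes
    permutation_chisq(classes, flags, n = 500,
                      seed = 1000 + i)$p_empirical
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  # and the empirical p tracks the analytic chi-square p on a large table
  classes <- sample(rep(c("a", "b"), each = 1000))
  flags <- runif(2000) < 0.3
  pr <- permutation_chisq(classes, flags, n = 10000, seed = 7)
  se <- 3 * sqrt(pr$p_analytic * (1 - pr$p_analytic) / 10000)
  expect_lt(abs(pr$p_empirical - pr$p_analytic), se + 0.01)
})

test_that("site-class by TE-class tables conserve marginals and flag planted excess", {
  set.seed(73)
  classes <- rep(c("conserved", "species_specific"), times = c(300, 150))
  att <- rep("none", 450)
  # plant LINE1 enrichment under specific sites
  att[sample(which(classes == "species_specific"), 25)] <- "LINE1"
  att[sample(which(classes == "conserved"), 8)] <- "LINE1"
  att[sample(which(att == "none"), 30)] <- "SINE"
  res <- class_by_teclass_table(classes, att)
  expect_equal(sum(res$observed), 450)
  expect_equal(unname(rowSums(res$observed)), c(300, 150))
  expect_gt(res$residuals["species_specific", "LINE1"], 0)
  expect_lt(res$residuals["conserved", "LINE1"], 0)
})

test_that("TE attribution picks the longest enclosing element", {
  site <- GRanges("c1", IRanges(1001, 1200))
  tes <- GRanges("c1", IRanges(c(1051, 951), c(1150, 1400)))
  tes$te_class <- factor(c("SINE", "LINE1"), levels = TE_CLASSES)
  tes$name <- c("short", "long")
  expect_equal(as.character(te_attribution(site, tes)), "LINE1")
  # no enclosure: none
  expect_equal(as.character(te_attribution(site, tes[integer(0)])), "none")
})

test_that("Kruskal-Wallis and distance binning behave across groups", {
  # closed-form H on a fixed 3-group vector without ties
  vals <- c(1, 5, 9, 2, 6, 10, 3, 7, 11)
  grp <- rep(c("g1", "g2", "g3"), times = 3)
  expect_equal(unname(kruskal.test(vals, factor(grp))$statistic),
               oracle_kruskal_h(vals, grp), tolerance = 1e-12)

  # identical groups: H near zero, p near 1
  d0 <- rep(c(-500, 2000, -20000, 150000), 25)
  r0 <- tss_distance_tests(rep(c("u", "v"), each = 50), c(d0[1:50], d0[1:50]))
  expect_lt(r0$kw_h, 1e-9)
  # one group shifted far out is detected
  set.seed(74)
  near <- rnorm(200, 0, 2000)
  far <- rnorm(200, 0, 2000) + sample(c(-1, 1), 200, TRUE) * 50000
  r1 <- tss_distance_tests(rep(c("near", "far"), each = 200), c(near, far))
  expect_lt(r1$p, 0.01)
  # signed bins: the shifted group occupies the outer bins
  far_bins <- r1$bins["far", ]
  expect_gt(far_bins[["10..100kb"]] + far_bins[["-100..-10kb"]], 0.9)
  expect_warning(
    tss_distance_tests(factor(rep(c("u", "v"), each = 5), levels = c("u", "v", "w")),
                       rnorm(10)),
    "empty group")
})
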