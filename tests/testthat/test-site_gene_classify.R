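# A hand-built two-species scenario on one chromosome with an identity
# chain: site classes are dictated by what the "other" species carries at
# the same coordinates.
identity_chains <- function(len = 100000) {
  ch <- list(score = 1, t_name = "c1", t_size = len, t_strand = "+",
             t_start = 0, t_end = len, q_name = "c1", q_size = len,
             q_strand = "+", q_start = 0, q_end = len, id = "1",
             blocks = data.frame(size = len, dt = 0, dq = 0))
  structure(list(ch), class = "chain_set")
}

test_that("site classes follow the high/low evidence rules", {
  sites <- GRanges("c1", IRanges(c(1001, 5001, 9001), width = 200))
  sites$site_id <- paste0("s", 1:3)
  other_high <- GRanges("c1", IRanges(1051, 1150))       # matches site 1
  other_low <- GRanges("c1", IRanges(c(1051, 5051), c(1150, 5150)))
  cls <- classify_sites(sites, identity_chains(), other_high, other_low)
  expect_equal(as.character(cls$site_class),
               c("conserved",       # high-confidence overlap
                 "indeterminate",   # low-confidence evidence only
                 "species_specific" # no evidence below q 0.1
               ))
  expect_equal(cls$mapped_fraction, rep(1, 3))
})

test_that("sites in unalignable territory are not lifted", {
  len <- 100000
  ch <- list(score = 1, t_name = "c1", t_size = len, t_strand = "+",
             t_start = 0, t_end = 30000, q_name = "c1", q_size = len,
             q_strand = "+", q_start = 0, q_end = 30000, id = "1",
             blocks = data.frame(size = 30000, dt = 0, dq = 0))
  chains <- structure(list(ch), class = "chain_set")
  sites <- GRanges("c1", IRanges(c(1001, 50001), width = 100))
  cls <- classify_sites(sites, chains, GRanges(), GRanges(),
                        chrom_sizes = c(c1 = len))
  expect_equal(as.character(cls$site_class),
               c("species_specific", "not_lifted"))
})

test_that("identical species through an identity chain are fully conserved", {
  set.seed(44)
  df <- random_peak_df(30, chroms = "c1", max_pos = 50000, max_len = 300)
  df$q <- 0.001
  peaks <- peaks_df_to_granges(df)
  hi <- high_confidence_consensus(list(peaks, peaks))
  lo <- low_confidence_union(list(peaks, peaks))
  out <- suppressWarnings(classify_all_sites(hi, hi, lo, lo,
                                             identity_chains(),
                                             identity_chains()))
  expect_true(all(out$sites_a$site_class == "conserved"))
  expect_true(all(out$sites_b$site_class == "conserved"))
  expect_equal(unique(out$summary$fraction_lifted), 1)
  expect_equal(sum(out$summary$n), length(hi) * 2)
})

test_that("class counts sum to the total number of sites", {
  w <- get_world("small")
  res <- classify_world(w, noise = 0)
  tab <- table(res$sites_a$site_class)
  expect_equal(sum(tab), length(res$sites_a))
  expect_true(all(res$sites_a$site_class %in%
                    c("conserved", "species_specific", "indeterminate",
                      "not_lifted")))
})

profile_row <- function(ca, cb) {
  data.frame(gene_a = "gA", gene_b = "gB",
             n_sites_a = length(ca), n_sites_b = length(cb),
             delta_n_raw = length(ca) - length(cb),
             delta_n = max(-5, min(5, length(ca) - length(cb))),
             classes_a = paste(ca, collapse = ","),
             classes_b = paste(cb, collapse = ","))
}

test_that("gene classes implement the conservation rules", {
  cases <- list(
    list(c("conserved"), c("conserved"), "conserved"),
    # conserved wins even with extra species-specific sites
    list(c("conserved", "species_specific"), c("conserved"), "conserved"),
    list(c("species_specific"), c("species_specific"), "alternative"),
    list(c("species_specific", "indeterminate"), c("species_specific"),
         "alternative"),
    list(c("species_specific"), character(0), "a_specific"),
    list(character(0), c("species_specific"), "b_specific"),
    list(character(0), character(0), "unbound"),
    # low-confidence evidence in the other species blocks the specific call
    list(c("species_specific", "indeterminate"), character(0),
         "unclassified"),
    # one-sided conserved without a partner: indeterminate at gene level
    list(c("conserved"), c("species_specific"), "unclassified"),
    # only unalignable sites: no cross-species evidence either way
    list(c("not_lifted"), character(0), "unclassified")
  )
  for (cs in cases) {
    got <- classify_genes(profile_row(cs[[1]], cs[[2]]))
    expect_equal(as.character(got$gene_class), cs[[3]],
                 info = paste(cs[[1]], collapse = "+"))
  }
})

test_that("binding profiles count assigned sites and clamp the difference", {
  tss <- data.frame(gene_id = c("a1", "a2"), chrom = "c1",
                    pos = c(10000, 40000), strand = "+")
  g <- GRanges("c1", IRanges(tss$pos, width = 1000))
  g$gene_id <- tss$gene_id
  gm_a <- gene_models(g, tss)
  tss_b <- transform(tss, gene_id = c("b1", "b2"))
  g_b <- g; g_b$gene_id <- tss_b$gene_id
  gm_b <- gene_models(g_b, tss_b)

  sites_a <- GRanges("c1", IRanges(9000 + 700 * (1:8), width = 100))
  sites_a$site_class <- factor(rep("species_specific", 8),
                               levels = c("conserved", "species_specific",
                                          "indeterminate", "not_lifted"))
  sites_a <- assign_sites_to_genes(sites_a, gm_a)
  expect_true(all(sites_a$gene_id == "a1"))
  sites_b <- GRanges("c1", IRanges(40100, width = 100))
  sites_b$site_class <- factor("species_specific",
                               levels = levels(sites_a$site_class))
  sites_b <- assign_sites_to_genes(sites_b, gm_b)
  prof <- gene_binding_profiles(sites_a, sites_b,
                                data.frame(gene_a = c("a1", "a2"),
                                           gene_b = c("b1", "b2")))
  expect_equal(prof$n_sites_a, c(8L, 0L))
  expect_equal(prof$delta_n_raw, c(8L, -1L))
  expect_equal(prof$delta_n, c(5L, -1L))     # clamped at +-5
  expect_error(
    gene_binding_profiles(sites_a, sites_b,
                          data.frame(gene_a = c("a1", "a1"),
                                     gene_b = c("b1", "b2"))),
    "one-to-one")
})

test_that("gene classification ignores site enumeration order", {
  w <- get_world("small")
  res <- classify_world(w, noise = 0)
  set.seed(9)
  perm_a <- res$sites_a[sample.int(length(res$sites_a))]
  perm_b <- res$sites_b[sample.int(length(res$sites_b))]
  ort <- w$orthologs[, c("gene_a", "gene_b")]
  g1 <- classify_genes(gene_binding_profiles(perm_a, perm_b, ort))
  g2 <- res$genes
  m <- match(g1$gene_a, g2$gene_a)
  expect_equal(as.character(g1$gene_class), as.character(g2$gene_class[m]))
})
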