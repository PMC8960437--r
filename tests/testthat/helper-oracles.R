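# Independent brute-force oracles. These deliberately avoid the package's
# own interval/chain machinery: everything is computed per base pair on
# small instances.

# 1-based closed interval -> set of covered positions, keyed by chromosome
bp_set <- function(chrom, start, end) {
  paste0(chrom, ":", seq(start, end))
}

oracle_overlap <- function(chrom_a, s_a, e_a, chrom_b, s_b, e_b) {
  length(intersect(bp_set(chrom_a, s_a, e_a), bp_set(chrom_b, s_b, e_b))) > 0
}

# exhaustive scan over every TSS; ties on |distance| broken by smaller
# gene_id, then smaller position
oracle_nearest_tss <- function(chrom, pos, tss_df) {
  cand <- tss_df[tss_df$chrom == chrom, , drop = FALSE]
  if (nrow(cand) == 0L) return(list(gene_id = NA_character_, distance = NA))
  d <- abs(cand$pos - pos)
  best <- cand[d == min(d), , drop = FALSE]
  best <- best[order(best$gene_id, best$pos), , drop = FALSE][1L, ]
  signed <- if (best$strand == "-") best$pos - pos else pos - best$pos
  list(gene_id = best$gene_id, distance = signed)
}

# per-base image map of a chain set, walking blocks independently of
# lift_intervals; applies the same best-chain rule (top score, then id)
oracle_bp_map <- function(chains, chrom, pos0) {
  cand <- Filter(function(ch) ch$t_name == chrom &&
                   pos0 >= ch$t_start && pos0 < ch$t_end, chains)
  if (length(cand) == 0L) return(NULL)
  sc <- vapply(cand, function(ch) ch$score, numeric(1))
  id <- vapply(cand, function(ch) ch$id, character(1))
  ch <- cand[[order(-sc, id)[1L]]]
  t_cur <- ch$t_start
  q_cur <- ch$q_start
  for (i in seq_len(nrow(ch$blocks))) {
    b <- ch$blocks[i, ]
    if (pos0 < t_cur + b$size) {
      if (pos0 < t_cur) return(NULL)      # inside a previous dt gap
      qc <- q_cur + (pos0 - t_cur)
      fwd <- if (ch$q_strand == "-") ch$q_size - qc - 1 else qc
      return(list(chrom = ch$q_name, pos0 = fwd, strand = ch$q_strand))
    }
    t_cur <- t_cur + b$size + b$dt
    q_cur <- q_cur + b$size + b$dq
  }
  NULL
}

# single-spanning-range lift of [s0, e0) via the per-base map; mirrors the
# best-chain rule by picking the chain that covers the interval's best chain
oracle_lift <- function(chains, chrom, s0, e0) {
  cand <- Filter(function(ch) ch$t_name == chrom &&
                   ch$t_start < e0 && s0 < ch$t_end, chains)
  if (length(cand) == 0L) {
    return(list(status = "unmapped", mapped_fraction = 0))
  }
  sc <- vapply(cand, function(ch) ch$score, numeric(1))
  id <- vapply(cand, function(ch) ch$id, character(1))
  best <- cand[order(-sc, id)[1L]]
  imgs <- lapply(s0:(e0 - 1), function(p) oracle_bp_map(best, chrom, p))
  imgs <- imgs[!vapply(imgs, is.null, logical(1))]
  if (length(imgs) == 0L) {
    return(list(status = "unmapped", mapped_fraction = 0))
  }
  pos <- vapply(imgs, function(x) x$pos0, numeric(1))
  list(status = "mapped", chrom = imgs[[1L]]$chrom,
       start0 = min(pos), end0 = max(pos) + 1,
       strand = imgs[[1L]]$strand,
       mapped_fraction = length(imgs) / (e0 - s0))
}

# consensus by explicit peak components: peaks sharing >= 1 bp are merged
# (transitively, union-find); a component is kept when every replicate
# contributes at least one peak sharing >= 1 bp with it
oracle_consensus <- function(replicate_dfs, q_max) {
  qual <- lapply(replicate_dfs, function(df) {
    df[!is.na(df$q) & df$q < q_max, , drop = FALSE]
  })
  pooled <- do.call(rbind, qual)
  if (nrow(pooled) == 0L) return(NULL)
  n <- nrow(pooled)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && oracle_overlap(pooled$chrom[i], pooled$start[i],
                                  pooled$end[i], pooled$chrom[j],
                                  pooled$start[j], pooled$end[j])) {
        comp[find(i)] <- find(j)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out <- list()
  for (r in unique(roots)) {
    members <- pooled[roots == r, , drop = FALSE]
    lo <- min(members$start); hi <- max(members$end)
    chrom <- members$chrom[1L]
    in_all <- all(vapply(qual, function(df) {
      any(vapply(seq_len(nrow(df)), function(k) {
        oracle_overlap(df$chrom[k], df$start[k], df$end[k], chrom, lo, hi)
      }, logical(1)))
    }, logical(1)))
    if (in_all) out[[length(out) + 1L]] <-
        data.frame(chrom = chrom, start = lo, end = hi)
  }
  if (length(out) == 0L) return(NULL)
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

oracle_union_bp <- function(replicate_dfs, q_max) {
  qual <- do.call(rbind, lapply(replicate_dfs, function(df) {
    df[!is.na(df$q) & df$q < q_max, , drop = FALSE]
  }))
  if (nrow(qual) == 0L) return(character(0))
  unique(unlist(mapply(bp_set, qual$chrom, qual$start, qual$end,
                       SIMPLIFY = FALSE)))
}

# full containment of a window in at least one single TE interval
oracle_enclosed <- function(win_chrom, win_s, win_e, te_df) {
  any(te_df$chrom == win_chrom & te_df$start <= win_s & te_df$end >= win_e)
}

# random peak fixtures on short chromosomes
random_peak_df <- function(n, chroms = c("c1", "c2"), max_pos = 1500,
                           max_len = 60) {
  start <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(max_len, n, replace = TRUE),
             q = 10^(-runif(n, 0.5, 4)))
}

peaks_df_to_granges <- function(df) {
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end))
  gr$q <- df$q
  gr
}

# textbook Pearson chi-square from scratch
oracle_chisq <- function(tab) {
  tab <- as.matrix(tab)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  list(chi2 = sum((tab - e)^2 / e), expected = e,
       residuals = (tab - e) / sqrt(e),
       df = (nrow(tab) - 1) * (ncol(tab) - 1))
}

# continuity-corrected Wilson score interval (Newcombe's closed form, the
# prop.test convention)
oracle_wilson_cc <- function(k, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  lower <- if (k == 0) 0 else
    (2 * n * p + z^2 - 1 -
       z * sqrt(z^2 - 2 - 1 / n + 4 * p * (n * (1 - p) + 1))) /
    (2 * (n + z^2))
  upper <- if (k == n) 1 else
    (2 * n * p + z^2 + 1 +
       z * sqrt(z^2 + 2 - 1 / n + 4 * p * (n * (1 - p) - 1))) /
    (2 * (n + z^2))
  c(max(0, lower), min(1, upper))
}

# Kruskal-Wallis H from ranks, no ties assumed
oracle_kruskal_h <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  tab <- split(r, groups)
  h <- 12 / (n * (n + 1)) *
    sum(vapply(tab, function(x) sum(x)^2 / length(x), numeric(1))) -
    3 * (n + 1)
  h
}
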