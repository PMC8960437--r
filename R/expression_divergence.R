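# Cross-species expression divergence and its association with binding-site
# classes and binding-site-count differences.

#' @importFrom stats pt t.test var.test chisq.test lm coef pf
NULL

#' Median-of-ratios size factors
#'
#' The standard RNA-seq library-size estimator: per-gene geometric means over
#' samples form the pseudo-reference; each sample's factor is the median of
#' its ratios to the reference over genes with an all-positive reference.
#'
#' @param counts Integer matrix, genes x samples.
#' @return Numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  log_gm <- rowMeans(log(counts))
  use <- is.finite(log_gm)
  if (!any(use)) stop("no gene has positive counts in every sample")
  apply(counts[use, , drop = FALSE], 2, function(x) {
    exp(stats::median(log(x) - log_gm[use]))
  })
}

#' Normalise, batch-centre and zero-centre one species' counts
#'
#' Median-of-ratios normalisation, log2(x + 1), removal of per-study global
#' shifts (each study's grand mean over genes is aligned to the species grand
#' mean), then zero-centering of the species (the grand mean over all genes
#' and samples is subtracted), so expression is comparable across species.
#' Studies with a single sample are left uncentred with a warning.
#'
#' @param counts Integer matrix, genes x samples (rownames = gene ids).
#' @param meta data.frame with columns `sample` (matching `colnames(counts)`)
#'   and `study`.
#' @param pseudocount Added before log2 (default 1).
#' @return List with `log_expr` (centred log2 matrix), `size_factors`, and
#'   `meta`.
#' @export
normalize_counts <- function(counts, meta, pseudocount = 1) {
  stopifnot(all(colnames(counts) %in% meta$sample))
  meta <- meta[match(colnames(counts), meta$sample), , drop = FALSE]
  sf <- size_factors(counts)
  le <- log2(sweep(counts, 2, sf, "/") + pseudocount)
  grand <- mean(le)
  for (st in unique(meta$study)) {
    cols <- which(meta$study == st)
    if (length(cols) < 2L) {
      warning("study '", st, "' has a single sample; study centering skipped")
      next
    }
    le[, cols] <- le[, cols] - (mean(le[, cols]) - grand)
  }
  le <- le - mean(le)
  list(log_expr = le, size_factors = sf, meta = meta)
}

#' Per-study mean expression
#'
#' @param log_expr Centred log2 matrix from [normalize_counts()].
#' @param meta Matching sample metadata (columns `sample`, `study`).
#' @return Matrix genes x studies of per-study means.
#' @export
study_means <- function(log_expr, meta) {
  meta <- meta[match(colnames(log_expr), meta$sample), , drop = FALSE]
  studies <- sort(unique(meta$study))
  out <- vapply(studies, function(st) {
    rowMeans(log_expr[, meta$study == st, drop = FALSE])
  }, numeric(nrow(log_expr)))
  colnames(out) <- studies
  out
}

welch_stats <- function(ma, mb, va, vb, na_, nb_) {
  se2 <- va / na_ + vb / nb_
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na_)^2 / (na_ - 1) + (vb / nb_)^2 / (nb_ - 1))
  p <- 2 * pt(-abs(t), df)
  zero <- se2 == 0
  if (any(zero, na.rm = TRUE)) {
    eq <- zero & (ma == mb)
    t[eq] <- 0; df[eq] <- na_ + nb_ - 2; p[eq] <- 1
    ne <- zero & (ma != mb)
    t[ne] <- sign(ma - mb)[ne] * Inf
    df[ne] <- na_ + nb_ - 2
    p[ne] <- .Machine$double.xmin
  }
  list(t = t, df = df, p = p)
}

#' Welch divergence for one gene
#'
#' Unequal-variance two-sided t test of species A per-study means against
#' species B per-study means; the log2 ratio is the difference of the two
#' means.
#'
#' @param values_a,values_b Numeric vectors of per-study mean log2 expression
#'   (>= 2 values each).
#' @return List with `log2_ratio`, `t`, `df`, `p`.
#' @export
welch_divergence <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 2L, length(values_b) >= 2L)
  st <- welch_stats(mean(values_a), mean(values_b),
                    stats::var(values_a), stats::var(values_b),
                    length(values_a), length(values_b))
  list(log2_ratio = mean(values_a) - mean(values_b),
       t = st$t, df = st$df, p = st$p)
}

#' Divergence records for all ortholog pairs
#'
#' Joins per-study mean matrices of the two species on an ortholog table and
#' computes, per pair, the cross-species log2 expression ratio and Welch test
#' (vectorised over genes).
#'
#' @param means_a,means_b Matrices genes x studies (rownames = gene ids) from
#'   [study_means()].
#' @param orthologs data.frame with columns `gene_a`, `gene_b`.
#' @return data.frame: `gene_a`, `gene_b`, `log2_ratio`, `t`, `df`,
#'   `p_unadjusted`, plus per-study mean columns.
#' @export
divergence_table <- function(means_a, means_b, orthologs) {
  keep <- orthologs$gene_a %in% rownames(means_a) &
    orthologs$gene_b %in% rownames(means_b)
  ort <- orthologs[keep, , drop = FALSE]
  a <- means_a[ort$gene_a, , drop = FALSE]
  b <- means_b[ort$gene_b, , drop = FALSE]
  if (is.null(colnames(a))) colnames(a) <- paste0("s", seq_len(ncol(a)))
  if (is.null(colnames(b))) colnames(b) <- paste0("s", seq_len(ncol(b)))
  na_ <- ncol(a); nb_ <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  st <- welch_stats(ma, mb, va, vb, na_, nb_)
  out <- data.frame(gene_a = ort$gene_a, gene_b = ort$gene_b,
                    log2_ratio = ma - mb, t = st$t, df = st$df,
                    p_unadjusted = st$p, stringsAsFactors = FALSE)
  colnames(a) <- paste0("a_", colnames(a))
  colnames(b) <- paste0("b_", colnames(b))
  cbind(out, a, b)
}

#' Per-class divergence statistics
#'
#' Mean and standard deviation of the log2 expression ratio per gene class, a
#' Welch t test of each class against the conserved class, and the F test of
#' variances between the conserved and alternative classes.
#'
#' @param records data.frame from [divergence_table()].
#' @param gene_class Factor/character of gene classes aligned with `records`
#'   rows.
#' @return List with `per_class` (data.frame: class, n, mean, sd,
#'   p_vs_conserved) and `f_conserved_vs_alternative` (ratio and p, NA when a
#'   class has < 2 genes).
#' @export
class_divergence_stats <- function(records, gene_class) {
  stopifnot(length(gene_class) == nrow(records))
  cls <- as.character(gene_class)
  classes <- unique(cls)
  ref <- records$log2_ratio[cls == "conserved"]
  per <- do.call(rbind, lapply(classes, function(cl) {
    x <- records$log2_ratio[cls == cl]
    if (length(x) < 2L) {
      return(data.frame(class = cl, n = length(x), mean = NA_real_,
                        sd = NA_real_, p_vs_conserved = NA_real_))
    }
    p <- if (cl == "conserved" || length(ref) < 2L) NA_real_ else
      t.test(x, ref)$p.value
    data.frame(class = cl, n = length(x), mean = mean(x), sd = stats::sd(x),
               p_vs_conserved = p)
  }))
  alt <- records$log2_ratio[cls == "alternative"]
  f <- if (length(ref) >= 2L && length(alt) >= 2L) {
    vt <- var.test(ref, alt)
    list(F = unname(vt$statistic), p = vt$p.value)
  } else list(F = NA_real_, p = NA_real_)
  list(per_class = per, f_conserved_vs_alternative = f)
}

#' Enrichment of species-specific genes in the expression-ratio tails
#'
#' For each tail (log2 ratio beyond `log2_cutoff` in the matching direction),
#' a 2x2 Pearson chi-square of species-specific class membership against tail
#' membership, with the proportion of tail genes in the specific class.
#'
#' @param records data.frame from [divergence_table()].
#' @param gene_class Aligned gene classes; `a_specific` is tested in the
#'   upper (A over B) tail, `b_specific` in the lower tail.
#' @param log2_cutoff Tail cutoff (default 5).
#' @return data.frame with one row per tail: `tail`, `specific_class`,
#'   `n_tail`, `n_specific_in_tail`, `proportion`, `chi2`, `p` (NA with a
#'   warning when a tail is empty).
#' @export
extreme_tail_enrichment <- function(records, gene_class, log2_cutoff = 5) {
  stopifnot(log2_cutoff > 0)
  cls <- as.character(gene_class)
  one_tail <- function(tail_name, in_tail, spec) {
    is_spec <- cls == spec
    if (!any(in_tail)) {
      warning("empty ", tail_name, " tail at cutoff ", log2_cutoff)
      return(data.frame(tail = tail_name, specific_class = spec,
                        n_tail = 0L, n_specific_in_tail = 0L,
                        proportion = NA_real_, chi2 = NA_real_, p = NA_real_))
    }
    tab <- table(factor(is_spec, c(FALSE, TRUE)),
                 factor(in_tail, c(FALSE, TRUE)))
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    data.frame(tail = tail_name, specific_class = spec,
               n_tail = sum(in_tail),
               n_specific_in_tail = sum(in_tail & is_spec),
               proportion = mean(is_spec[in_tail]),
               chi2 = unname(ct$statistic), p = ct$p.value)
  }
  rbind(
    one_tail("upper", records$log2_ratio > log2_cutoff, "a_specific"),
    one_tail("lower", records$log2_ratio < -log2_cutoff, "b_specific")
  )
}

#' Regression of expression ratio on binding-site count difference
#'
#' Ordinary least squares of the log2 expression ratio on the clamped
#' difference in binding-site counts, restricted to genes bound in both
#' species (conserved or alternative classes) — the expression units per
#' binding site estimate.
#'
#' @param records data.frame from [divergence_table()].
#' @param delta_n Clamped count differences aligned with `records` rows.
#' @param gene_class Optional aligned gene classes; when given, only
#'   `conserved` and `alternative` genes enter the fit.
#' @return List with `slope`, `intercept`, `p` (two-sided slope p), `n`, and
#'   the fitted `lm` object.
#' @export
ratio_vs_count_difference <- function(records, delta_n, gene_class = NULL) {
  stopifnot(length(delta_n) == nrow(records))
  use <- rep(TRUE, nrow(records))
  if (!is.null(gene_class)) {
    use <- as.character(gene_class) %in% c("conserved", "alternative")
  }
  x <- delta_n[use]
  y <- records$log2_ratio[use]
  if (length(unique(x)) < 2L) {
    stop("all binding-site count differences are identical; slope undefined")
  }
  fit <- lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2L]),
       intercept = unname(coef(fit)[1L]),
       p = sm$coefficients[2L, 4L],
       n = length(x), fit = fit)
}
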