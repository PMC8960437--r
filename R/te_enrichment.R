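# Transposable element overlap statistics: enclosure flags, chi-square
# independence with standardized residuals, label-permutation null, and
# TSS-distance distributions.

#' @importFrom stats kruskal.test pchisq
NULL

TE_CLASSES <- c("LINE1", "LINE2", "LTR", "SINE", "DNA", "other")

#' Read transposable element annotations from BED6
#'
#' The TE class is taken from the suffix of the name column after `#`
#' (RepeatMasker-style `name#class`), or looked up in a two-column class map;
#' classes outside the fixed vocabulary (LINE1, LINE2, LTR, SINE, DNA) are
#' coerced to `other`.
#'
#' @param path Path to a BED6 file.
#' @param class_map Optional data.frame with columns `name` and `te_class`.
#' @return `GRanges` with `name` and `te_class` metadata columns.
#' @export
read_te_bed <- function(path, class_map = NULL) {
  gr <- read_bed(path)
  nm <- if (!is.null(gr$name)) gr$name else rep(".", length(gr))
  if (!is.null(class_map)) {
    cls <- class_map$te_class[match(nm, class_map$name)]
  } else {
    cls <- ifelse(grepl("#", nm, fixed = TRUE), sub("^.*#", "", nm),
                  NA_character_)
    nm <- sub("#.*$", "", nm)
  }
  unknown <- !is.na(cls) & !cls %in% TE_CLASSES
  if (any(unknown)) {
    warning(sum(unknown), " TE(s) with unknown class coerced to 'other'")
  }
  cls[is.na(cls) | unknown] <- "other"
  gr$name <- nm
  gr$te_class <- factor(cls, levels = TE_CLASSES)
  gr
}

#' Transposable element enclosure flags
#'
#' A site overlaps a TE iff its central window (default 40 bp) is fully
#' enclosed by a *single* TE interval.
#'
#' @param sites `GRanges` of sites.
#' @param tes `GRanges` of TE intervals.
#' @param width Central window width, bp (default 40).
#' @param chrom_sizes Optional chromosome lengths for window clamping.
#' @return Logical vector along `sites`.
#' @export
te_overlap_flags <- function(sites, tes, width = 40L, chrom_sizes = NULL) {
  win <- central_window(sites, width = width, chrom_sizes = chrom_sizes)
  overlapsAny(win, tes, type = "within")
}

#' Attribute enclosed sites to a TE class
#'
#' Each site whose central window is enclosed by at least one TE is
#' attributed to the class of the longest enclosing TE (ties broken
#' lexicographically on class then name).
#'
#' @inheritParams te_overlap_flags
#' @return Factor along `sites` with TE class levels plus `none`.
#' @export
te_attribution <- function(sites, tes, width = 40L, chrom_sizes = NULL) {
  win <- central_window(sites, width = width, chrom_sizes = chrom_sizes)
  ov <- findOverlaps(win, tes, type = "within")
  out <- rep("none", length(sites))
  if (length(ov) > 0L) {
    qh <- queryHits(ov)
    sh <- subjectHits(ov)
    w <- width(tes)[sh]
    cls <- as.character(tes$te_class[sh])
    nm <- if (!is.null(tes$name)) tes$name[sh] else as.character(sh)
    ord <- order(qh, -w, cls, nm)
    first <- !duplicated(qh[ord])
    ties <- tapply(w, qh, function(x) sum(x == max(x)) > 1L)
    if (any(ties)) {
      message(sum(ties), " site(s) enclosed by equally long TEs; ",
              "class resolved lexicographically")
    }
    out[qh[ord][first]] <- cls[ord][first]
  }
  factor(out, levels = c(TE_CLASSES, "none"))
}

#' Chi-square test of independence with standardized residuals
#'
#' Pearson chi-square without continuity correction (so the statistic is
#' exchangeable with the permutation null), with cell-wise standardized
#' residuals (O - E) / sqrt(E). The relative residual (O - E) / E is
#' available behind a flag. For 2x2 tables the continuity-corrected p-value
#' is additionally reported as a cross-check.
#'
#' @param tab An r x c contingency table/matrix, r, c >= 2, all margins
#'   positive.
#' @param residual_type `"pearson"` (default) or `"relative"`.
#' @return Object of class `contingency_result`: `observed`, `expected`,
#'   `chi2`, `df`, `p`, `residuals`, and `p_yates` for 2x2 tables.
#' @export
chisq_independence <- function(tab, residual_type = c("pearson", "relative")) {
  residual_type <- match.arg(residual_type)
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L) stop("need an r x c table, r, c >= 2")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("contingency table has a zero margin")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  resid <- if (residual_type == "pearson") {
    (ct$observed - ct$expected) / sqrt(ct$expected)
  } else {
    (ct$observed - ct$expected) / ct$expected
  }
  p_yates <- if (all(dim(tab) == 2L)) {
    suppressWarnings(chisq.test(tab, correct = TRUE)$p.value)
  } else NA_real_
  structure(list(observed = ct$observed, expected = ct$expected,
                 chi2 = unname(ct$statistic), df = unname(ct$parameter),
                 p = ct$p.value, residuals = resid, p_yates = p_yates),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat("chi-square independence: X2 =", format(x$chi2, digits = 5),
      "df =", x$df, "p =", format(x$p, digits = 4), "\n")
  invisible(x)
}

# Pearson chi-square of a k x 2 table given per-class totals and per-class
# TRUE counts; closed form, independent of stats::chisq.test, so the
# permutation null can be cross-checked against the wrapped test.
chi2_kx2 <- function(true_by_class, n_by_class) {
  n <- sum(n_by_class)
  t_tot <- sum(true_by_class)
  e1 <- n_by_class * t_tot / n
  e0 <- n_by_class - e1
  o0 <- n_by_class - true_by_class
  sum((true_by_class - e1)^2 / e1) + sum((o0 - e0)^2 / e0)
}

#' Permutation test of the class-by-TE chi-square
#'
#' Holds the site class labels fixed and permutes the TE overlap flags
#' (equivalently, the TE labels) `n` times, recomputing the Pearson
#' chi-square each time. The empirical p-value uses the add-one rule
#' `(1 + #{null >= observed}) / (n + 1)`.
#'
#' @param classes Factor/character of site classes (>= 2 distinct).
#' @param flags Logical TE-overlap flags along `classes`.
#' @param n Number of permutations (default 10000).
#' @param seed Optional seed for reproducibility.
#' @return Object of class `permutation_result`: `observed_chi2`,
#'   `p_empirical`, `p_analytic` (asymptotic reference), `n_permutations`,
#'   `null_values`, `seed`.
#' @export
permutation_chisq <- function(classes, flags, n = 10000L, seed = NULL) {
  classes <- factor(classes)
  if (nlevels(droplevels(classes)) < 2L) {
    stop("need at least two site classes")
  }
  classes <- droplevels(classes)
  stopifnot(is.logical(flags), length(flags) == length(classes))
  if (!is.null(seed)) set.seed(seed)
  idx <- as.integer(classes)
  k <- nlevels(classes)
  n_by_class <- tabulate(idx, nbins = k)
  obs <- chi2_kx2(tabulate(idx[flags], nbins = k), n_by_class)
  nsite <- length(flags)
  null_values <- vapply(seq_len(n), function(i) {
    perm <- flags[sample.int(nsite)]
    chi2_kx2(tabulate(idx[perm], nbins = k), n_by_class)
  }, numeric(1))
  p_emp <- (1 + sum(null_values >= obs)) / (n + 1)
  structure(list(observed_chi2 = obs, p_empirical = p_emp,
                 p_analytic = pchisq(obs, df = k - 1, lower.tail = FALSE),
                 n_permutations = n, null_values = null_values,
                 seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("permutation chi-square: observed =",
      format(x$observed_chi2, digits = 5), "| empirical p =",
      format(x$p_empirical, digits = 4), "(", x$n_permutations,
      "permutations )\n")
  invisible(x)
}

#' Site-class by TE-class contingency
#'
#' Tabulates site classes against the attributed TE class (with a `none`
#' column for sites not enclosed) and runs the chi-square independence test
#' with standardized residuals. TE-class columns absent from the data are
#' dropped.
#'
#' @param classes Site classes (factor/character).
#' @param attribution TE-class attribution from [te_attribution()].
#' @return A `contingency_result` (see [chisq_independence()]).
#' @export
class_by_teclass_table <- function(classes, attribution) {
  tab <- table(class = factor(classes), te_class = factor(attribution))
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  chisq_independence(tab)
}

#' TSS-distance distributions and Kruskal-Wallis test across groups
#'
#' Signed midpoint-to-nearest-TSS distances per feature group, the
#' Kruskal-Wallis test on absolute distances, and a signed stacked-proportion
#' bin table (<=1 kb, 1-10 kb, 10-100 kb, >100 kb, upstream negative).
#'
#' @param groups Factor/character of group labels.
#' @param distances Signed TSS distances (bp) along `groups`.
#' @return List: `kw_h`, `p`, `bins` (proportion matrix groups x bins),
#'   `distances` (list of per-group signed distances). Groups with no
#'   feature are dropped with a warning.
#' @export
tss_distance_tests <- function(groups, distances) {
  stopifnot(length(groups) == length(distances))
  if (!is.factor(groups)) groups <- factor(groups)
  keep <- !is.na(distances) & !is.na(groups)
  groups <- groups[keep]
  distances <- distances[keep]
  empty <- setdiff(levels(groups), levels(droplevels(groups)))
  if (length(empty) > 0L) {
    warning("dropping empty group(s): ", paste(empty, collapse = ", "))
  }
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L) stop("need at least two non-empty groups")
  kw <- kruskal.test(abs(distances), groups)
  brk <- c(-Inf, -1e5, -1e4, -1e3, 0, 1e3, 1e4, 1e5, Inf)
  lab <- c("<-100kb", "-100..-10kb", "-10..-1kb", "-1..0kb",
           "0..1kb", "1..10kb", "10..100kb", ">100kb")
  binned <- cut(distances, breaks = brk, labels = lab)
  tab <- table(groups, binned)
  props <- sweep(tab, 1, rowSums(tab), "/")
  list(kw_h = unname(kw$statistic), p = kw$p.value,
       bins = props,
       distances = split(distances, groups))
}
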