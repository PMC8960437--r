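# Per-species consensus binding sites from replicate peak calls.

filter_q <- function(peaks, q_max) {
  if (is.null(peaks$q)) stop("peaks lack a q metadata column")
  miss <- is.na(peaks$q)
  if (any(miss)) {
    warning(sum(miss), " peak(s) without a q-value excluded")
    peaks <- peaks[!miss]
  }
  peaks[peaks$q < q_max]
}

#' High-confidence consensus sites across replicates
#'
#' Pools the peaks below `q_max` from every replicate, merges overlapping
#' peaks (>= 1 bp shared), and keeps a merged interval only if at least one
#' qualifying peak from *every* replicate overlaps it — the "bound in all
#' replicates" consensus. Merged coordinates are the union of the
#' contributing peaks.
#'
#' @param replicates List of `GRanges`, one per replicate, each with a `q`
#'   metadata column on the probability scale (see [read_narrowpeak()]).
#' @param q_max Per-replicate q-value threshold (default 0.01).
#' @param species Optional species label stored on the result.
#' @return Sorted, non-overlapping `GRanges` with metadata columns `site_id`
#'   and `n_replicates_supporting` (always the replicate count).
#' @export
high_confidence_consensus <- function(replicates, q_max = 0.01,
                                      species = NA_character_) {
  if (length(replicates) == 0L) stop("at least one replicate is required")
  qual <- lapply(replicates, filter_q, q_max = q_max)
  pooled <- reduce(do.call(c, lapply(qual, granges)), min.gapwidth = 0L)
  keep <- rep(TRUE, length(pooled))
  for (r in qual) {
    keep <- keep & overlapsAny(pooled, r, minoverlap = 1L)
  }
  out <- sort(GenomeInfoDb::sortSeqlevels(pooled[keep]))
  out$site_id <- sprintf("%s_site_%05d",
                         ifelse(is.na(species), "cons", species),
                         seq_along(out))
  out$n_replicates_supporting <- rep(length(replicates), length(out))
  out
}

#' Low-confidence union of peaks
#'
#' The merged union of all peaks below `q_max` in *any* replicate — the
#' "any evidence of binding" set used to call species-specific sites.
#'
#' @inheritParams high_confidence_consensus
#' @param q_max Q-value threshold (default 0.1).
#' @return Sorted, non-overlapping `GRanges`.
#' @export
low_confidence_union <- function(replicates, q_max = 0.1) {
  if (length(replicates) == 0L) stop("at least one replicate is required")
  qual <- lapply(replicates, filter_q, q_max = q_max)
  sort(GenomeInfoDb::sortSeqlevels(
    reduce(do.call(c, lapply(qual, granges)), min.gapwidth = 0L)))
}

#' Remove blacklisted sites
#'
#' Drops any site sharing at least one base pair with a blacklist interval.
#'
#' @param sites `GRanges` of sites.
#' @param blacklist `GRanges` of blacklist regions.
#' @return Filtered `GRanges`; the number removed is reported with a message.
#' @export
remove_blacklisted <- function(sites, blacklist) {
  if (length(blacklist) == 0L) return(sites)
  hit <- overlapsAny(sites, blacklist, minoverlap = 1L)
  if (any(hit)) {
    message(sum(hit), " site(s) removed for blacklist overlap")
  }
  sites[!hit]
}
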