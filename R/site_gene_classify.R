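# The core inference: conservation classes for binding sites and for
# orthologous target gene pairs.

SITE_CLASSES <- c("conserved", "species_specific", "indeterminate", "not_lifted")
GENE_CLASSES <- c("conserved", "alternative", "a_specific", "b_specific",
                  "unbound", "unclassified")

#' Classify consensus sites of one species against the other
#'
#' Each high-confidence consensus site is extended by `pad` bp either side,
#' lifted to the other genome, and labelled:
#' \itemize{
#'   \item `not_lifted` — no base of the padded interval has an aligned image;
#'   \item `conserved` — the lifted range overlaps a high-confidence
#'     consensus site of the other species;
#'   \item `species_specific` — the lifted range overlaps nothing in the
#'     other species' low-confidence union (no evidence of binding at q < 0.1
#'     in any replicate);
#'   \item `indeterminate` — anything else (low-confidence evidence only).
#' }
#'
#' @param sites High-confidence consensus sites of the focal species
#'   (`GRanges` from [high_confidence_consensus()]).
#' @param chains `chain_set` mapping the focal genome to the other genome.
#' @param other_high Other species' high-confidence consensus sites.
#' @param other_low Other species' low-confidence union.
#' @param pad Padding before lifting, bp (default 1000).
#' @param chrom_sizes Optional named lengths of the focal genome's
#'   chromosomes (for clamping the padded interval).
#' @return The input `GRanges` with added metadata columns `site_class`,
#'   `lift_chrom`, `lift_start`, `lift_end`, `mapped_fraction`.
#' @export
classify_sites <- function(sites, chains, other_high, other_low,
                           pad = 1000L, chrom_sizes = NULL) {
  lift <- lift_intervals(sites, chains, pad = pad, chrom_sizes = chrom_sizes)
  cls <- rep("not_lifted", length(sites))
  mapped <- lift$status == "mapped"
  if (any(mapped)) {
    img <- GRanges(lift$chrom[mapped],
                   IRanges(lift$start[mapped], lift$end[mapped]))
    hi <- overlapsAny(img, other_high, minoverlap = 1L)
    lo <- overlapsAny(img, other_low, minoverlap = 1L)
    cls[mapped] <- ifelse(hi, "conserved",
                          ifelse(!lo, "species_specific", "indeterminate"))
  }
  sites$site_class <- factor(cls, levels = SITE_CLASSES)
  sites$lift_chrom <- lift$chrom
  sites$lift_start <- lift$start
  sites$lift_end <- lift$end
  sites$mapped_fraction <- lift$mapped_fraction
  sites
}

#' Classify all sites in both directions
#'
#' Runs [classify_sites()] independently for each species (counts need not
#' match across species) and tabulates the class counts.
#'
#' @param sites_a,sites_b High-confidence consensus sites per species.
#' @param low_a,low_b Low-confidence unions per species.
#' @param chains_ab `chain_set` from genome A to genome B.
#' @param chains_ba `chain_set` from genome B to genome A.
#' @param pad Padding before lifting, bp.
#' @param sizes_a,sizes_b Optional chromosome length vectors.
#' @return List with classified `sites_a`, `sites_b`, and a `summary`
#'   data.frame of per-species class counts and the fraction of sites lifted.
#' @export
classify_all_sites <- function(sites_a, sites_b, low_a, low_b,
                               chains_ab, chains_ba, pad = 1000L,
                               sizes_a = NULL, sizes_b = NULL) {
  a <- classify_sites(sites_a, chains_ab, sites_b, low_b, pad, sizes_a)
  b <- classify_sites(sites_b, chains_ba, sites_a, low_a, pad, sizes_b)
  summ <- function(x, label) {
    tab <- table(x$site_class)
    data.frame(species = label,
               class = names(tab),
               n = as.integer(tab),
               fraction_lifted = mean(x$site_class != "not_lifted"))
  }
  list(sites_a = a, sites_b = b,
       summary = rbind(summ(a, "A"), summ(b, "B")))
}

#' Assign sites to their nearest gene
#'
#' Each site is assigned to the gene with the TSS nearest its midpoint
#' (own-chromosome search; sites on gene-free chromosomes stay unassigned).
#'
#' @param sites `GRanges` of sites.
#' @param genes A [gene_models()] object.
#' @return The sites with added `gene_id`, `tss_distance` (signed bp, by gene
#'   strand) metadata columns.
#' @export
assign_sites_to_genes <- function(sites, genes) {
  mid <- interval_midpoint(sites)
  nt <- nearest_tss(as.character(seqnames(sites)), mid, genes)
  sites$gene_id <- nt$gene_id
  sites$tss_distance <- nt$distance
  sites
}

#' Per-ortholog binding profiles
#'
#' Collects, for every 1:1 ortholog pair, the number and classes of
#' high-confidence sites assigned to each gene, and the clamped
#' binding-site-count difference.
#'
#' @param sites_a,sites_b Classified, gene-assigned sites per species
#'   (from [classify_sites()] then [assign_sites_to_genes()]).
#' @param orthologs data.frame with columns `gene_a`, `gene_b`; each gene may
#'   appear in at most one pair.
#' @param clamp Count-difference clamp (default 5, the `[-5, +5]` window).
#' @return data.frame, one row per pair: `gene_a`, `gene_b`, `n_sites_a`,
#'   `n_sites_b`, `delta_n_raw`, `delta_n` (clamped), `classes_a`,
#'   `classes_b` (comma-collapsed).
#' @export
gene_binding_profiles <- function(sites_a, sites_b, orthologs, clamp = 5L) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(orthologs)))
  if (anyDuplicated(orthologs$gene_a) || anyDuplicated(orthologs$gene_b)) {
    stop("ortholog table is not one-to-one")
  }
  per_gene <- function(sites) {
    keep <- !is.na(sites$gene_id)
    split(as.character(sites$site_class[keep]), sites$gene_id[keep])
  }
  by_a <- per_gene(sites_a)
  by_b <- per_gene(sites_b)
  cls_a <- unname(by_a[orthologs$gene_a])
  cls_b <- unname(by_b[orthologs$gene_b])
  n_a <- lengths(cls_a)
  n_b <- lengths(cls_b)
  dn <- n_a - n_b
  data.frame(
    gene_a = orthologs$gene_a,
    gene_b = orthologs$gene_b,
    n_sites_a = as.integer(n_a),
    n_sites_b = as.integer(n_b),
    delta_n_raw = as.integer(dn),
    delta_n = as.integer(pmax(-clamp, pmin(clamp, dn))),
    classes_a = vapply(cls_a, function(x) paste(x, collapse = ","), ""),
    classes_b = vapply(cls_b, function(x) paste(x, collapse = ","), ""),
    stringsAsFactors = FALSE
  )
}

classify_gene_pair <- function(ca, cb) {
  has <- function(x, what) any(x == what)
  if (length(ca) == 0L && length(cb) == 0L) return("unbound")
  if (has(ca, "conserved") && has(cb, "conserved")) return("conserved")
  if (length(ca) > 0L && length(cb) > 0L &&
      !has(ca, "conserved") && !has(cb, "conserved") &&
      has(ca, "species_specific") && has(cb, "species_specific")) {
    return("alternative")
  }
  if (length(cb) == 0L && has(ca, "species_specific") &&
      !has(ca, "conserved") && !has(ca, "indeterminate")) {
    return("a_specific")
  }
  if (length(ca) == 0L && has(cb, "species_specific") &&
      !has(cb, "conserved") && !has(cb, "indeterminate")) {
    return("b_specific")
  }
  "unclassified"
}

#' Classify ortholog gene pairs
#'
#' Applies the gene-level conservation rules to binding profiles:
#' \itemize{
#'   \item `conserved` — a conserved-class site assigned in both species;
#'   \item `alternative` — bound in both species through species-specific
#'     sites, with no conserved site on either side;
#'   \item `a_specific` / `b_specific` — species-specific site(s) in exactly
#'     one species and no assigned site of any class in the other, with no
#'     conserved or indeterminate evidence;
#'   \item `unbound` — no site in either species;
#'   \item `unclassified` — anything else (indeterminate at gene level);
#'     excluded, together with `unbound`, from class statistics.
#' }
#'
#' @param profiles data.frame from [gene_binding_profiles()].
#' @return The profiles with an added `gene_class` factor column.
#' @export
classify_genes <- function(profiles) {
  split_cls <- function(s) if (nzchar(s)) strsplit(s, ",", fixed = TRUE)[[1L]] else character(0)
  cls <- vapply(seq_len(nrow(profiles)), function(i) {
    classify_gene_pair(split_cls(profiles$classes_a[i]),
                       split_cls(profiles$classes_b[i]))
  }, "")
  profiles$gene_class <- factor(cls, levels = GENE_CLASSES)
  profiles
}
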