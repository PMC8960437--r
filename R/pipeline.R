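# End-to-end orchestration: consensus -> lift -> classify -> genes ->
# expression -> motifs -> TE statistics, with report tables on disk.

#' Assemble a pipeline run configuration
#'
#' Collects input paths and the analysis thresholds. All thresholds default
#' to the values used throughout the conservation analysis: q < 0.01
#' (high confidence), q < 0.1 (any evidence), 1 kb lift padding, motif match
#' P < 0.004, 40 bp TE enclosure window, 10,000 permutations, log2 ratio
#' tail cutoff 5, binding-count clamp 5.
#'
#' @param inputs Named list of input paths: `peaks_a`/`peaks_b` (character
#'   vectors of narrowPeak files), `chain_ab`, `chain_ba`, `chrom_sizes_a`,
#'   `chrom_sizes_b`, `gtf_a`, `gtf_b`, `orthologs`, `te_a`, `te_b`,
#'   `blacklist_a`, `blacklist_b`, `genome_a`, `genome_b`, `counts_a`,
#'   `counts_b`, `samples_a`, `samples_b`, `motifs`.
#' @param out_dir Report output directory.
#' @param seed Seed for the permutation test.
#' @param q_high,q_low,pad,fimo_p,te_window,n_perm,tail_cutoff,delta_clamp
#'   Analysis thresholds.
#' @param species Two-element labels, names `a` and `b`.
#' @return List of class `run_config`.
#' @export
run_config <- function(inputs, out_dir, seed = 1L,
                       q_high = 0.01, q_low = 0.1, pad = 1000L,
                       fimo_p = 0.004, te_window = 40L, n_perm = 10000L,
                       tail_cutoff = 5, delta_clamp = 5L,
                       species = c(a = "hs", b = "mm")) {
  stopifnot(q_high < q_low, q_high > 0, pad >= 0, n_perm > 0)
  structure(list(inputs = inputs, out_dir = out_dir, seed = as.integer(seed),
                 q_high = q_high, q_low = q_low, pad = pad, fimo_p = fimo_p,
                 te_window = te_window, n_perm = n_perm,
                 tail_cutoff = tail_cutoff, delta_clamp = delta_clamp,
                 species = species),
            class = "run_config")
}

#' Run configuration for a written synthetic world
#'
#' Builds a [run_config()] from the `manifest.json` of a [write_world()]
#' directory.
#'
#' @param dir Directory holding a written world.
#' @param out_dir Report output directory (default `file.path(dir, "report")`).
#' @param ... Passed to [run_config()].
#' @return A `run_config`.
#' @export
world_run_config <- function(dir, out_dir = file.path(dir, "report"), ...) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"))
  sp <- c(a = mf$species$a, b = mf$species$b)
  f <- function(key) {
    hits <- mf$files[grep(key, names(mf$files))]
    unname(vapply(hits, function(x) file.path(dir, x), ""))
  }
  inputs <- list(
    peaks_a = f(paste0("^peaks_", sp[["a"]])),
    peaks_b = f(paste0("^peaks_", sp[["b"]])),
    chain_ab = f("^chain_ab$"), chain_ba = f("^chain_ba$"),
    chrom_sizes_a = f(paste0("^chrom_sizes_", sp[["a"]])),
    chrom_sizes_b = f(paste0("^chrom_sizes_", sp[["b"]])),
    gtf_a = f(paste0("^gtf_", sp[["a"]])), gtf_b = f(paste0("^gtf_", sp[["b"]])),
    orthologs = f("^orthologs$"),
    te_a = f(paste0("^te_", sp[["a"]])), te_b = f(paste0("^te_", sp[["b"]])),
    blacklist_a = f(paste0("^blacklist_", sp[["a"]])),
    blacklist_b = f(paste0("^blacklist_", sp[["b"]])),
    genome_a = f(paste0("^genome_", sp[["a"]])),
    genome_b = f(paste0("^genome_", sp[["b"]])),
    counts_a = f(paste0("^counts_", sp[["a"]])),
    counts_b = f(paste0("^counts_", sp[["b"]])),
    samples_a = f(paste0("^samples_", sp[["a"]])),
    samples_b = f(paste0("^samples_", sp[["b"]])),
    motifs = f("^motifs$")
  )
  run_config(inputs, out_dir, species = sp, ...)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full conservation analysis
#'
#' Executes every stage on the configured inputs and writes the report
#' tables: per-site classifications and class summary, gene classes with
#' proportions, expression divergence per class with tail enrichment and the
#' count-difference regression, motif proportions per site set, motif
#' enrichment between conserved and specific sites, and TE contingency,
#' permutation and TSS-distance statistics. Outputs are a pure function of
#' (inputs, thresholds, seed); rerunning with the same seed reproduces the
#' tables bit for bit.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all intermediate and final objects.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  ip <- config$inputs
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outp <- function(...) file.path(config$out_dir, paste0(...))
  sp <- config$species

  # consensus
  res <- stage("peak_consensus", {
    pk_a <- lapply(ip$peaks_a, read_narrowpeak)
    pk_b <- lapply(ip$peaks_b, read_narrowpeak)
    bl_a <- read_bed(ip$blacklist_a)
    bl_b <- read_bed(ip$blacklist_b)
    list(
      high_a = remove_blacklisted(
        high_confidence_consensus(pk_a, config$q_high, sp[["a"]]), bl_a),
      high_b = remove_blacklisted(
        high_confidence_consensus(pk_b, config$q_high, sp[["b"]]), bl_b),
      low_a = remove_blacklisted(low_confidence_union(pk_a, config$q_low), bl_a),
      low_b = remove_blacklisted(low_confidence_union(pk_b, config$q_low), bl_b))
  })

  sizes_a <- stage("chain_lift", read_chrom_sizes(ip$chrom_sizes_a))
  sizes_b <- read_chrom_sizes(ip$chrom_sizes_b)
  chains_ab <- stage("chain_lift", read_chain(ip$chain_ab))
  chains_ba <- read_chain(ip$chain_ba)

  cls <- stage("site_classification", classify_all_sites(
    res$high_a, res$high_b, res$low_a, res$low_b,
    chains_ab, chains_ba, pad = config$pad,
    sizes_a = sizes_a, sizes_b = sizes_b))

  genes_a <- stage("gene_models", read_gene_models(ip$gtf_a))
  genes_b <- read_gene_models(ip$gtf_b)
  sites_a <- assign_sites_to_genes(cls$sites_a, genes_a)
  sites_b <- assign_sites_to_genes(cls$sites_b, genes_b)

  ort_raw <- read_tsv_table(ip$orthologs)
  orthologs <- data.frame(gene_a = ort_raw[[1L]], gene_b = ort_raw[[2L]])
  gene_table <- stage("gene_classification", classify_genes(
    gene_binding_profiles(sites_a, sites_b, orthologs,
                          clamp = config$delta_clamp)))

  # expression divergence
  expr <- stage("expression", {
    read_counts <- function(path) {
      df <- read_tsv_table(path)
      m <- as.matrix(df[, -1L, drop = FALSE])
      rownames(m) <- df[[1L]]
      m
    }
    cn_a <- normalize_counts(read_counts(ip$counts_a),
                             read_tsv_table(ip$samples_a))
    cn_b <- normalize_counts(read_counts(ip$counts_b),
                             read_tsv_table(ip$samples_b))
    div <- divergence_table(study_means(cn_a$log_expr, cn_a$meta),
                            study_means(cn_b$log_expr, cn_b$meta),
                            orthologs)
    gm <- match(div$gene_a, gene_table$gene_a)
    div$gene_class <- as.character(gene_table$gene_class[gm])
    div$delta_n <- gene_table$delta_n[gm]
    stats_cls <- class_divergence_stats(div, div$gene_class)
    tails <- extreme_tail_enrichment(div, div$gene_class, config$tail_cutoff)
    regression <- tryCatch(
      ratio_vs_count_difference(div, div$delta_n, div$gene_class),
      error = function(e) list(slope = NA_real_, intercept = NA_real_,
                               p = NA_real_, n = 0L))
    list(div = div, stats_cls = stats_cls, tails = tails,
         regression = regression)
  })

  # motif analysis: proportions per site set (unpadded lift for the
  # specific-site equivalent loci) and conserved-vs-specific enrichment
  motifs <- stage("motif_analysis", {
    genome_a <- readDNAStringSet(ip$genome_a)
    genome_b <- readDNAStringSet(ip$genome_b)
    names(genome_a) <- sub("\\s.*$", "", names(genome_a))
    names(genome_b) <- sub("\\s.*$", "", names(genome_b))
    pwms <- read_meme(ip$motifs)
    pw <- pwms[[1L]]
    genome_bg <- function(genome) {
      f <- as.numeric(Biostrings::letterFrequency(genome, DNA_BASES,
                                                  collapse = TRUE))
      f / sum(f)
    }
    # the motif file's own background (FIMO convention) when present,
    # otherwise the order-0 genome composition
    meme_bg <- attr(pwms, "background")
    bg_a <- if (!is.null(meme_bg)) meme_bg else genome_bg(genome_a)
    bg_b <- if (!is.null(meme_bg)) meme_bg else genome_bg(genome_b)
    one_species <- function(sites, genome, other_genome, chains, szs,
                            bg, bg_other) {
      cons <- sites[sites$site_class == "conserved"]
      spec <- sites[sites$site_class == "species_specific"]
      sets <- list(all = sites, conserved = cons, specific = spec)
      props <- do.call(rbind, lapply(names(sets), function(nm) {
        s <- sets[[nm]]
        if (length(s) == 0L) return(NULL)
        cbind(set = nm, motif_proportion(site_sequences(genome, s), pw,
                                         config$fimo_p, background = bg))
      }))
      lifted <- NULL
      if (length(spec) > 0L) {
        lf <- lift_intervals(spec, chains, pad = 0L, chrom_sizes = szs)
        img <- lift_as_granges(lf)
        if (length(img) > 0L) {
          lifted <- cbind(set = "specific_lifted",
                          motif_proportion(site_sequences(other_genome, img),
                                           pw, config$fimo_p,
                                           background = bg_other))
        }
      }
      enr <- if (length(cons) > 0L && length(spec) > 0L) {
        known_motif_enrichment(site_sequences(genome, cons),
                               site_sequences(genome, spec), pwms,
                               config$fimo_p, background = bg)
      } else NULL
      list(proportions = rbind(props, lifted), enrichment = enr)
    }
    list(a = one_species(sites_a, genome_a, genome_b, chains_ab, sizes_a,
                         bg_a, bg_b),
         b = one_species(sites_b, genome_b, genome_a, chains_ba, sizes_b,
                         bg_b, bg_a))
  })

  # transposable elements
  te <- stage("te_enrichment", {
    te_a <- read_te_bed(ip$te_a)
    te_b <- read_te_bed(ip$te_b)
    one_species <- function(sites, tes, szs) {
      flags <- te_overlap_flags(sites, tes, config$te_window, szs)
      classes <- droplevels(sites$site_class)
      cont <- chisq_independence(table(class = classes,
                                       te = factor(flags, c(FALSE, TRUE))))
      perm <- permutation_chisq(classes, flags, n = config$n_perm,
                                seed = config$seed)
      attribution <- te_attribution(sites, tes, config$te_window, szs)
      byclass <- class_by_teclass_table(classes, attribution)
      dist_t <- tss_distance_tests(classes, sites$tss_distance)
      rates <- vapply(split(flags, classes), mean, numeric(1))
      list(flags = flags, contingency = cont, permutation = perm,
           byclass = byclass, tss = dist_t, rates = rates)
    }
    list(a = one_species(sites_a, te_a, sizes_a),
         b = one_species(sites_b, te_b, sizes_b))
  })

  # ---- report emission -----------------------------------------------------
  site_df <- function(s) {
    data.frame(site_id = s$site_id, chrom = as.character(seqnames(s)),
               start = start(s), end = end(s),
               class = as.character(s$site_class),
               lift_chrom = s$lift_chrom, lift_start = s$lift_start,
               lift_end = s$lift_end, gene_id = s$gene_id,
               tss_distance = s$tss_distance)
  }
  write_tsv_table(site_df(sites_a), outp("site_classes_", sp[["a"]], ".tsv"))
  write_tsv_table(site_df(sites_b), outp("site_classes_", sp[["b"]], ".tsv"))
  write_tsv_table(cls$summary, outp("site_class_summary.tsv"))
  write_tsv_table(gene_table[, names(gene_table) != "fit"],
                  outp("gene_classes.tsv"))
  gc_tab <- table(gene_table$gene_class)
  informative <- !names(gc_tab) %in% c("unbound", "unclassified")
  gene_summary <- data.frame(
    class = names(gc_tab), n = as.integer(gc_tab),
    proportion_of_target_genes =
      ifelse(informative, as.integer(gc_tab) / sum(gc_tab[informative]), NA))
  write_tsv_table(gene_summary, outp("gene_class_summary.tsv"))
  write_tsv_table(expr$div, outp("divergence.tsv"))
  write_tsv_table(expr$stats_cls$per_class, outp("class_divergence.tsv"))
  write_tsv_table(expr$tails, outp("tail_enrichment.tsv"))
  write_json(list(slope = expr$regression$slope,
                  intercept = expr$regression$intercept,
                  p = expr$regression$p, n = expr$regression$n,
                  f_conserved_vs_alternative =
                    expr$stats_cls$f_conserved_vs_alternative),
             outp("regression.json"), auto_unbox = TRUE, digits = NA)
  prop_tab <- rbind(cbind(species = sp[["a"]], motifs$a$proportions),
                    cbind(species = sp[["b"]], motifs$b$proportions))
  write_tsv_table(prop_tab, outp("motif_proportions.tsv"))
  enr_tab <- rbind(
    if (!is.null(motifs$a$enrichment))
      cbind(species = sp[["a"]], motifs$a$enrichment),
    if (!is.null(motifs$b$enrichment))
      cbind(species = sp[["b"]], motifs$b$enrichment))
  if (!is.null(enr_tab)) write_tsv_table(enr_tab, outp("motif_enrichment.tsv"))
  for (side in c("a", "b")) {
    lab <- sp[[side]]
    t <- te[[side]]
    write_tsv_table(as.data.frame(t$contingency$observed),
                    outp("te_contingency_", lab, ".tsv"))
    write_tsv_table(as.data.frame(as.table(t$byclass$residuals)),
                    outp("te_residuals_", lab, ".tsv"))
    write_json(list(observed_chi2 = t$permutation$observed_chi2,
                    p_empirical = t$permutation$p_empirical,
                    p_analytic = t$permutation$p_analytic,
                    n_permutations = t$permutation$n_permutations,
                    seed = config$seed,
                    kruskal_wallis_h = t$tss$kw_h,
                    kruskal_wallis_p = t$tss$p),
               outp("te_permutation_", lab, ".json"),
               auto_unbox = TRUE, digits = NA)
    write_tsv_table(as.data.frame(as.table(t$tss$bins)),
                    outp("tss_distance_bins_", lab, ".tsv"))
  }
  write_json(list(package_version = as.character(
    utils::packageVersion("orthopeak")),
    seed = config$seed,
    thresholds = list(q_high = config$q_high, q_low = config$q_low,
                      pad = config$pad, fimo_p = config$fimo_p,
                      te_window = config$te_window, n_perm = config$n_perm,
                      tail_cutoff = config$tail_cutoff,
                      delta_clamp = config$delta_clamp)),
    outp("run_log.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(config = config, consensus = res, classification = cls,
                 sites_a = sites_a, sites_b = sites_b,
                 gene_table = gene_table, gene_summary = gene_summary,
                 expression = expr, motifs = motifs, te = te))
}
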