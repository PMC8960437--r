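# Two-species synthetic world with planted ground truth: toy genomes related
# by a constructed block chain, replicate peak calls with q-value noise,
# planted site and gene conservation classes, motif instances, transposable
# elements, and negative-binomial expression counts with study batch effects.

#' @importFrom stats rnorm runif rbinom rnbinom rlnorm
#' @importFrom jsonlite write_json
NULL

#' Default configuration of the synthetic two-species world
#'
#' All defaults reflect the study conditions the pipeline is meant to
#' emulate: ~10% of the genome unalignable (so ~90% of sites lift), gene
#' class proportions of roughly 69/16/8/7 percent among bound target genes,
#' class-specific motif planting rates, transposable-element overlap rates,
#' and class-linked expression effects (conserved mean -0.59 sd 1.59,
#' species-A-specific +1.95, species-B-specific -1.55), three RNA-seq
#' studies per species and 3 vs 2 ChIP replicates.
#'
#' @param seed Integer seed; all world randomness derives from it.
#' @param ... Named overrides of any default listed below.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    species = c(a = "hs", b = "mm"),
    chrom_lengths = c(chr1 = 5e6, chr2 = 4e6),
    margin = 10000,
    block_len = c(40000, 60000),
    gap_t_len = c(5000, 9000),
    gap_q_len = c(2600, 6000),
    gap_t_prob = 0.55,
    gap_q_prob = 0.55,
    unalignable_fraction = 0.10,
    gene_spacing = 9000,
    block_margin = 6000,
    n_genes = c(conserved = 200, alternative = 45, a_specific = 25,
                b_specific = 20, unbound = 350, nonortholog = 20),
    site_slots = c(-3750, -1250, 1250, 3750),
    site_width = 60,
    conserved_sites_per_gene = c(1, 2),
    specific_sites_per_gene = c(1, 2),
    extra_specific_rate = 0.35,
    n_indeterminate = c(a = 30, b = 30),
    pad = 1000,
    jitter = 30,
    q_noise_rate = 0.005,
    replicates = c(a = 3, b = 2),
    n_blacklist = 4,
    blacklist_halfwidth = 2500,
    motif_rates = list(
      conserved = c(own_a = 0.121, own_b = 0.132),
      a_specific = c(own = 0.191, lifted = 0.067),
      b_specific = c(own = 0.182, lifted = 0.077),
      other = c(own = 0.10, lifted = 0.05)
    ),
    te_rates = list(conserved = c(a = 0.034, b = 0.006),
                    specific = c(a = 0.108, b = 0.06),
                    other = c(a = 0.02, b = 0.02)),
    te_class_weights = list(
      conserved = c(LINE1 = 0.10, LINE2 = 0.20, LTR = 0.10,
                    SINE = 0.40, DNA = 0.20),
      specific = c(LINE1 = 0.40, LINE2 = 0.05, LTR = 0.35,
                   SINE = 0.15, DNA = 0.05),
      background = c(LINE1 = 0.25, LINE2 = 0.10, LTR = 0.20,
                     SINE = 0.35, DNA = 0.10)
    ),
    n_background_tes = 200,
    base_freq = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
    scrub_pad = 40,
    fimo_p = 0.004,
    studies = 3,
    samples_per_study = 2,
    base_meanlog = log(200),
    base_sdlog = 1,
    dispersion = 0.05,
    batch_sd = 0.5,
    noise_sd = 0.2,
    effects = list(conserved = c(mean = -0.59, sd = 1.59),
                   alternative = c(mean = -0.21, sd = 2.46),
                   a_specific = c(mean = 1.95, sd = 2.0),
                   b_specific = c(mean = -1.55, sd = 2.0),
                   unbound_sd = 1.3),
    count_effect_log2 = 0.5
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0L) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "synthetic_config")
}

# ---- chain construction ----------------------------------------------------

build_chrom_chain <- function(chrom, t_size, q_strand, cfg, chain_id) {
  t_cur <- cfg$margin
  q_cur <- cfg$margin
  sizes <- numeric(0); dts <- numeric(0); dqs <- numeric(0)
  repeat {
    size <- round(runif(1, cfg$block_len[1], cfg$block_len[2]))
    if (t_cur + size + cfg$margin > t_size) break
    sizes <- c(sizes, size)
    t_cur <- t_cur + size
    q_cur <- q_cur + size
    dt <- if (runif(1) < cfg$gap_t_prob)
      round(runif(1, cfg$gap_t_len[1], cfg$gap_t_len[2])) else 0
    dq <- if (runif(1) < cfg$gap_q_prob)
      round(runif(1, cfg$gap_q_len[1], cfg$gap_q_len[2])) else 0
    if (dt == 0 && dq == 0) dq <- round(runif(1, 500, 1500))
    dts <- c(dts, dt); dqs <- c(dqs, dq)
    t_cur <- t_cur + dt
    q_cur <- q_cur + dq
  }
  n <- length(sizes)
  dts <- c(dts[seq_len(n - 1L)], 0)
  dqs <- c(dqs[seq_len(n - 1L)], 0)
  t_end <- cfg$margin + sum(sizes) + sum(dts)
  q_end <- cfg$margin + sum(sizes) + sum(dqs)
  q_size <- q_end + cfg$margin
  ch <- list(score = 1000 * chain_id, t_name = chrom, t_size = t_size,
             t_strand = "+", t_start = cfg$margin, t_end = t_end,
             q_name = chrom, q_size = q_size, q_strand = q_strand,
             q_start = cfg$margin, q_end = q_end,
             id = as.character(chain_id),
             blocks = data.frame(size = sizes, dt = dts, dq = dqs))
  validate_chain(ch)
  ch
}

# vectorised A (target) 0-based position -> forward-strand B 0-based position
a2b_pos <- function(ch, pos0) {
  bc <- chain_block_coords(ch)
  i <- findInterval(pos0, bc$t_starts)
  ok <- i >= 1L & pos0 < (bc$t_starts[pmax(i, 1L)] + bc$sizes[pmax(i, 1L)])
  qc <- rep(NA_real_, length(pos0))
  qc[ok] <- bc$q_starts[i[ok]] + (pos0[ok] - bc$t_starts[i[ok]])
  if (ch$q_strand == "-") ch$q_size - qc - 1 else qc
}

a2b_interval <- function(ch, s0, e0) {
  lo <- a2b_pos(ch, s0)
  hi <- a2b_pos(ch, e0 - 1)
  cbind(start0 = pmin(lo, hi), end0 = pmax(lo, hi) + 1)
}

# ---- world construction ----------------------------------------------------

#' Build the synthetic two-species world
#'
#' Constructs toy genomes related by a block chain (with the configured
#' unalignable fraction), places genes and planted binding sites of each
#' conservation class, plants motif instances and transposable elements at
#' class-specific rates, draws per-gene expression effects, and derives the
#' gene-level ground truth implied by the placements. Deterministic given
#' `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @param include_sequences Generate genome sequences (needed for motif
#'   analysis and FASTA emission; skip for speed when only coordinates are
#'   needed).
#' @return A list of class `synthetic_world`: chains in both directions,
#'   chromosome sizes, gene models and ortholog table, TE and blacklist
#'   annotations, site-level and gene-level ground truth, genome sequences,
#'   and the config.
#' @export
build_world <- function(config = synthetic_config(), include_sequences = TRUE) {
  cfg <- config
  set.seed(cfg$seed)
  chroms <- names(cfg$chrom_lengths)

  chains <- lapply(seq_along(chroms), function(k) {
    build_chrom_chain(chroms[k], cfg$chrom_lengths[k],
                      if (k %% 2L == 0L) "-" else "+", cfg, k)
  })
  names(chains) <- chroms
  chains_ab <- structure(unname(chains), class = "chain_set")
  chains_ba <- chain_invert(chains_ab)
  sizes_a <- vapply(chains, function(ch) ch$t_size, numeric(1))
  sizes_b <- vapply(chains, function(ch) ch$q_size, numeric(1))
  names(sizes_b) <- chroms

  # candidate gene slots: aligned-block interiors, spaced so nearest-gene
  # assignment of slot-offset sites is unambiguous in both genomes
  slot_list <- lapply(chroms, function(chn) {
    bc <- chain_block_coords(chains[[chn]])
    pos <- unlist(lapply(seq_along(bc$sizes), function(i) {
      lo <- bc$t_starts[i] + cfg$block_margin
      hi <- bc$t_starts[i] + bc$sizes[i] - cfg$block_margin
      if (hi <= lo) return(numeric(0))
      seq(lo, hi, by = cfg$gene_spacing)
    }))
    if (length(pos) == 0L) return(NULL)
    data.frame(chrom = chn, pos0 = round(pos))
  })
  slots <- do.call(rbind, slot_list)
  ng <- cfg$n_genes
  need <- sum(ng) + ng[["nonortholog"]] + cfg$n_blacklist * 2L
  if (nrow(slots) < need) {
    stop("infeasible packing: ", need, " gene/blacklist slots needed but only ",
         nrow(slots), " available; enlarge the genome or reduce counts")
  }
  slots <- slots[sample.int(nrow(slots)), , drop = FALSE]
  cat_names <- c(rep("conserved", ng[["conserved"]]),
                 rep("alternative", ng[["alternative"]]),
                 rep("a_specific", ng[["a_specific"]]),
                 rep("b_specific", ng[["b_specific"]]),
                 rep("unbound", ng[["unbound"]]),
                 rep("nonortholog_a", ng[["nonortholog"]]),
                 rep("nonortholog_b", ng[["nonortholog"]]),
                 rep("blacklist_a", cfg$n_blacklist),
                 rep("blacklist_b", cfg$n_blacklist))
  slots <- slots[seq_along(cat_names), , drop = FALSE]
  slots$category <- cat_names

  lab_a <- toupper(cfg$species[["a"]]); lab_b <- toupper(cfg$species[["b"]])
  gene_rows <- slots[!slots$category %in%
                       c("blacklist_a", "blacklist_b"), , drop = FALSE]
  gene_rows$idx <- seq_len(nrow(gene_rows))
  is_ortho <- !gene_rows$category %in% c("nonortholog_a", "nonortholog_b")
  gene_rows$gene_a <- ifelse(gene_rows$category != "nonortholog_b",
                             sprintf("%sG%05d", lab_a, gene_rows$idx), NA)
  gene_rows$gene_b <- ifelse(gene_rows$category != "nonortholog_a",
                             sprintf("%sG%05d", lab_b, gene_rows$idx), NA)
  gene_rows$strand <- sample(c("+", "-"), nrow(gene_rows), TRUE)
  gene_rows$span_len <- round(runif(nrow(gene_rows), 2000, 8000))
  gene_rows$second_tss <- ifelse(runif(nrow(gene_rows)) < 0.3,
                                 round(runif(nrow(gene_rows), 50, 300)), NA)

  # B-side coordinates of ortholog (and nonortholog_b) genes
  chain_of <- function(chn) chains[[chn]]
  gene_rows$tss_a0 <- gene_rows$pos0
  gene_rows$tss_b0 <- NA_real_
  for (chn in chroms) {
    sel <- gene_rows$chrom == chn
    gene_rows$tss_b0[sel] <- a2b_pos(chain_of(chn), gene_rows$tss_a0[sel])
  }
  flip <- vapply(gene_rows$chrom,
                 function(chn) chain_of(chn)$q_strand == "-", logical(1))
  gene_rows$strand_b <- ifelse(flip, chartr("+-", "-+", gene_rows$strand),
                               gene_rows$strand)

  make_gene_models <- function(side) {
    if (side == "a") {
      rows <- gene_rows[!is.na(gene_rows$gene_a), , drop = FALSE]
      ids <- rows$gene_a; tss0 <- rows$tss_a0; strand <- rows$strand
      szs <- sizes_a
    } else {
      rows <- gene_rows[!is.na(gene_rows$gene_b), , drop = FALSE]
      ids <- rows$gene_b; tss0 <- rows$tss_b0; strand <- rows$strand_b
      szs <- sizes_b
    }
    tss1 <- tss0 + 1
    sp_start <- ifelse(strand == "+", tss1, tss1 - rows$span_len)
    sp_end <- ifelse(strand == "+", tss1 + rows$span_len, tss1)
    lim <- szs[rows$chrom]
    sp_start <- pmax(1, sp_start); sp_end <- pmin(lim, sp_end)
    g <- GRanges(rows$chrom, IRanges(sp_start, sp_end), strand = strand)
    g$gene_id <- ids
    g$symbol <- ids
    tss <- data.frame(gene_id = ids, chrom = rows$chrom, pos = tss1,
                      strand = strand)
    extra <- which(!is.na(rows$second_tss))
    if (length(extra) > 0L) {
      off <- ifelse(strand[extra] == "+", rows$second_tss[extra],
                    -rows$second_tss[extra])
      tss <- rbind(tss, data.frame(gene_id = ids[extra],
                                   chrom = rows$chrom[extra],
                                   pos = tss1[extra] + off,
                                   strand = strand[extra]))
    }
    gene_models(g, tss)
  }
  genes_a <- make_gene_models("a")
  genes_b <- make_gene_models("b")
  orthologs <- gene_rows[is_ortho, c("gene_a", "gene_b", "category")]
  names(orthologs)[3L] <- "planted_class"
  rownames(orthologs) <- NULL

  # ---- site placement ------------------------------------------------------
  w <- cfg$site_width
  half <- w %/% 2L
  site_acc <- list()
  add_site <- function(species, class, gene_id, chrom, center0, has_image) {
    ch <- chain_of(chrom)
    s0 <- center0 - half; e0 <- center0 + half
    if (species == "a") {
      own <- c(s0, e0)
      other <- if (has_image) a2b_interval(ch, s0, e0) else
        cbind(start0 = NA_real_, end0 = NA_real_)
    } else {
      iv <- if (has_image) a2b_interval(ch, s0, e0) else
        cbind(start0 = NA_real_, end0 = NA_real_)
      own <- c(iv[1L], iv[2L])
      other <- cbind(start0 = s0, end0 = e0)
      if (!has_image) stop("B-side sites must lie in aligned blocks")
    }
    list(species = species, class = class, gene_id = gene_id, chrom = chrom,
         start0 = own[1L], end0 = own[2L],
         other_start0 = other[1L], other_end0 = other[2L])
  }
  rng <- function(r) sample(seq(r[1L], r[2L]), 1L)

  gene_rows$free_slots <- NA_integer_
  gene_rows$free_slot1 <- NA_real_
  for (i in seq_len(nrow(gene_rows))) {
    row <- gene_rows[i, ]
    if (row$category %in% c("unbound", "nonortholog_a", "nonortholog_b")) next
    free <- sample(cfg$site_slots)
    take <- function(n) {
      got <- free[seq_len(min(n, length(free)))]
      free <<- free[-seq_len(min(n, length(free)))]
      got
    }
    centers <- function(offs) round(row$tss_a0 + offs)
    if (row$category == "conserved") {
      for (cc in centers(take(rng(cfg$conserved_sites_per_gene)))) {
        site_acc[[length(site_acc) + 1L]] <-
          add_site("a", "conserved", row$gene_a, row$chrom, cc, TRUE)
        site_acc[[length(site_acc) + 1L]] <-
          add_site("b", "conserved", row$gene_b, row$chrom, cc, TRUE)
      }
      if (runif(1) < cfg$extra_specific_rate && length(free) > 0L) {
        site_acc[[length(site_acc) + 1L]] <-
          add_site("a", "species_specific", row$gene_a, row$chrom,
                   centers(take(1L)), TRUE)
      }
      if (runif(1) < cfg$extra_specific_rate && length(free) > 0L) {
        site_acc[[length(site_acc) + 1L]] <-
          add_site("b", "species_specific", row$gene_b, row$chrom,
                   centers(take(1L)), TRUE)
      }
    } else if (row$category == "alternative") {
      for (cc in centers(take(rng(cfg$specific_sites_per_gene)))) {
        site_acc[[length(site_acc) + 1L]] <-
          add_site("a", "species_specific", row$gene_a, row$chrom, cc, TRUE)
      }
      for (cc in centers(take(rng(cfg$specific_sites_per_gene)))) {
        site_acc[[length(site_acc) + 1L]] <-
          add_site("b", "species_specific", row$gene_b, row$chrom, cc, TRUE)
      }
    } else if (row$category == "a_specific") {
      for (cc in centers(take(rng(cfg$specific_sites_per_gene)))) {
        site_acc[[length(site_acc) + 1L]] <-
          add_site("a", "species_specific", row$gene_a, row$chrom, cc, TRUE)
      }
    } else if (row$category == "b_specific") {
      for (cc in centers(take(rng(cfg$specific_sites_per_gene)))) {
        site_acc[[length(site_acc) + 1L]] <-
          add_site("b", "species_specific", row$gene_b, row$chrom, cc, TRUE)
      }
    }
    gene_rows$free_slots[i] <- length(free)
    gene_rows$free_slot1[i] <- if (length(free) > 0L) free[1L] else NA
  }

  # indeterminate sites at conserved genes with a free slot
  for (side in c("a", "b")) {
    host <- which(gene_rows$category == "conserved" &
                    !is.na(gene_rows$free_slot1))
    n_ind <- min(cfg$n_indeterminate[[side]], length(host))
    pick <- sample(host, n_ind)
    for (i in pick) {
      row <- gene_rows[i, ]
      cc <- round(row$tss_a0 + row$free_slot1)
      gid <- if (side == "a") row$gene_a else row$gene_b
      site_acc[[length(site_acc) + 1L]] <-
        add_site(side, "indeterminate", gid, row$chrom, cc, TRUE)
      gene_rows$free_slot1[i] <- NA
    }
  }

  sites <- do.call(rbind, lapply(site_acc, as.data.frame))

  # not-lifted sites inside alignment gaps (dt gaps for A, dq gaps for B)
  gap_table <- function(side) {
    out <- lapply(chroms, function(chn) {
      ch <- chain_of(chn)
      bc <- chain_block_coords(ch)
      n <- length(bc$sizes)
      if (n < 2L) return(NULL)
      if (side == "a") {
        gs <- bc$t_starts[-n] + bc$sizes[-n]
        ge <- bc$t_starts[-1L]
      } else {
        qs <- bc$q_starts[-n] + bc$sizes[-n]
        qe <- bc$q_starts[-1L]
        if (ch$q_strand == "-") {
          gs <- ch$q_size - qe; ge <- ch$q_size - qs
        } else {
          gs <- qs; ge <- qe
        }
      }
      keep <- (ge - gs) >= 2 * (cfg$pad + half) + 200
      if (!any(keep)) return(NULL)
      data.frame(chrom = chn, gap_s0 = gs[keep], gap_e0 = ge[keep])
    })
    do.call(rbind, out)
  }
  frac <- cfg$unalignable_fraction
  if (frac > 0) {
    for (side in c("a", "b")) {
      n_bound <- sum(sites$species == side)
      n_gap <- rbinom(1L, n_bound, frac / (1 - frac))
      gaps <- gap_table(side)
      n_gap <- min(n_gap, nrow(gaps))
      if (n_gap > 0L) {
        pick <- gaps[sample.int(nrow(gaps), n_gap), , drop = FALSE]
        cc <- round((pick$gap_s0 + pick$gap_e0) / 2)
        gap_sites <- data.frame(
          species = side, class = "not_lifted", gene_id = NA_character_,
          chrom = pick$chrom, start0 = cc - half, end0 = cc + half,
          other_start0 = NA_real_, other_end0 = NA_real_)
        sites <- rbind(sites, gap_sites)
      }
    }
  }

  # decoy consensus peaks inside blacklist regions
  bl_rows <- slots[slots$category %in% c("blacklist_a", "blacklist_b"), ,
                   drop = FALSE]
  hw <- cfg$blacklist_halfwidth
  blacklist <- list()
  for (side in c("a", "b")) {
    rows <- bl_rows[bl_rows$category == paste0("blacklist_", side), ,
                    drop = FALSE]
    cc0 <- rows$pos0
    chn <- rows$chrom
    if (side == "b") {
      cc0 <- vapply(seq_len(nrow(rows)),
                    function(i) a2b_pos(chain_of(chn[i]), rows$pos0[i]),
                    numeric(1))
    }
    blacklist[[side]] <- GRanges(chn, IRanges(cc0 - hw + 1, cc0 + hw))
    sites <- rbind(sites, data.frame(
      species = side, class = "decoy", gene_id = NA_character_,
      chrom = chn, start0 = cc0 - half, end0 = cc0 + half,
      other_start0 = NA_real_, other_end0 = NA_real_))
  }

  sites$site_id <- sprintf("truth_%s_%04d", sites$species,
                           as.integer(stats::ave(seq_len(nrow(sites)),
                                                 sites$species,
                                                 FUN = seq_along)))
  rownames(sites) <- NULL

  # ---- motif planting flags ------------------------------------------------
  mr <- cfg$motif_rates
  n_s <- nrow(sites)
  sites$motif_own <- FALSE
  sites$motif_other <- FALSE
  for (i in seq_len(n_s)) {
    cls <- sites$class[i]; sp <- sites$species[i]
    if (cls == "decoy") next
    if (cls == "conserved") {
      own <- if (sp == "a") mr$conserved[["own_a"]] else mr$conserved[["own_b"]]
      oth <- 0   # the partner site carries its own flag
    } else if (cls == "species_specific") {
      r <- if (sp == "a") mr$a_specific else mr$b_specific
      own <- r[["own"]]; oth <- r[["lifted"]]
    } else {
      own <- mr$other[["own"]]; oth <- mr$other[["lifted"]]
    }
    sites$motif_own[i] <- runif(1) < own
    sites$motif_other[i] <- !is.na(sites$other_start0[i]) && runif(1) < oth
  }

  # ---- TE planting ---------------------------------------------------------
  tr <- cfg$te_rates
  tw <- cfg$te_class_weights
  sites$te <- FALSE
  sites$te_class <- NA_character_
  te_acc <- list(a = list(), b = list())
  for (i in seq_len(n_s)) {
    cls <- sites$class[i]; sp <- sites$species[i]
    if (cls == "decoy") next
    rate <- switch(cls,
                   conserved = tr$conserved[[sp]],
                   species_specific = tr$specific[[sp]],
                   tr$other[[sp]])
    if (runif(1) >= rate) next
    wts <- if (cls == "species_specific") tw$specific else tw$conserved
    tcl <- sample(names(wts), 1L, prob = wts)
    mid0 <- floor((sites$start0[i] + sites$end0[i]) / 2)
    ext_l <- round(runif(1, 150, 800)); ext_r <- round(runif(1, 150, 800))
    te_acc[[sp]][[length(te_acc[[sp]]) + 1L]] <- data.frame(
      chrom = sites$chrom[i], start0 = mid0 - 20 - ext_l,
      end0 = mid0 + 20 + ext_r, te_class = tcl)
    sites$te[i] <- TRUE
    sites$te_class[i] <- tcl
  }
  tes <- list()
  for (side in c("a", "b")) {
    planted <- do.call(rbind, te_acc[[side]])
    szs <- if (side == "a") sizes_a else sizes_b
    own_mid <- floor((sites$start0 + sites$end0) / 2)[sites$species == side]
    own_chr <- sites$chrom[sites$species == side]
    bg <- list()
    tries <- 0L
    while (length(bg) < cfg$n_background_tes && tries < cfg$n_background_tes * 20L) {
      tries <- tries + 1L
      chn <- sample(chroms, 1L)
      pos <- round(runif(1, 1000, szs[[chn]] - 5000))
      if (any(own_chr == chn & abs(own_mid - pos) < 3000)) next
      len <- round(runif(1, 300, 3000))
      bg[[length(bg) + 1L]] <- data.frame(
        chrom = chn, start0 = pos, end0 = pos + len,
        te_class = sample(names(tw$background), 1L, prob = tw$background))
    }
    df <- rbind(planted, do.call(rbind, bg))
    gr <- GRanges(df$chrom, IRanges(df$start0 + 1, df$end0))
    gr$name <- sprintf("TE%s%05d", toupper(side), seq_along(gr))
    gr$te_class <- factor(df$te_class, levels = TE_CLASSES)
    tes[[side]] <- sort(gr)
  }

  # ---- expression effects --------------------------------------------------
  eff <- cfg$effects
  pc <- orthologs$planted_class
  bound_a <- sites$species == "a" & !sites$class %in% c("decoy", "not_lifted")
  bound_b <- sites$species == "b" & !sites$class %in% c("decoy", "not_lifted")
  n_a <- table(sites$gene_id[bound_a])
  n_b <- table(sites$gene_id[bound_b])
  cnt <- function(tab, id) ifelse(is.na(id) | is.na(tab[id]), 0,
                                  as.integer(tab[id]))
  dn <- pmax(-5, pmin(5, cnt(n_a, orthologs$gene_a) -
                        cnt(n_b, orthologs$gene_b)))
  orthologs$delta_n_planted <- as.integer(dn)
  slope <- cfg$count_effect_log2
  e <- numeric(nrow(orthologs))
  for (cl in c("conserved", "alternative", "a_specific", "b_specific")) {
    sel <- pc == cl
    mu <- eff[[cl]][["mean"]]; sd_cl <- eff[[cl]][["sd"]]
    if (cl %in% c("conserved", "alternative") && sum(sel) > 1L) {
      # genes bound in both species carry an additive per-site count effect;
      # the residual variance is reduced so the marginal class sd stays at
      # its configured value
      d <- dn[sel] - mean(dn[sel])
      sd_res <- sqrt(max(sd_cl^2 - slope^2 * stats::var(d), 0.01))
      e[sel] <- rnorm(sum(sel), mu, sd_res) + slope * d
    } else {
      e[sel] <- rnorm(sum(sel), mu, sd_cl)
    }
  }
  ub <- pc == "unbound"
  comp <- -sum(e[!ub]) / sum(ub)   # pins the expected global mean ratio to 0
  e[ub] <- rnorm(sum(ub), comp, eff$unbound_sd)
  orthologs$effect <- e

  # ---- derived gene-level ground truth ------------------------------------
  derive <- function(side, gm) {
    s <- sites[sites$species == side & sites$class != "decoy", , drop = FALSE]
    mid1 <- floor((s$start0 + s$end0) / 2) + 1
    nt <- nearest_tss(s$chrom, mid1, gm)
    split(s$class, nt$gene_id)
  }
  by_a <- derive("a", genes_a)
  by_b <- derive("b", genes_b)
  orthologs$class <- vapply(seq_len(nrow(orthologs)), function(i) {
    ca <- by_a[[orthologs$gene_a[i]]]
    cb <- by_b[[orthologs$gene_b[i]]]
    classify_gene_pair(if (is.null(ca)) character(0) else ca,
                       if (is.null(cb)) character(0) else cb)
  }, "")

  world <- list(config = cfg,
                chains_ab = chains_ab, chains_ba = chains_ba,
                sizes_a = sizes_a, sizes_b = sizes_b,
                genes_a = genes_a, genes_b = genes_b,
                orthologs = orthologs,
                truth_sites = sites,
                tes = tes,
                blacklist = blacklist,
                sequences = NULL)
  if (include_sequences) world$sequences <- world_sequences(world)
  class(world) <- "synthetic_world"
  world
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("synthetic_world: seed", x$config$seed, "|",
      nrow(x$orthologs), "ortholog pairs |",
      sum(x$truth_sites$species == "a"), "+",
      sum(x$truth_sites$species == "b"), "planted sites\n")
  invisible(x)
}

# order-0 genomes with planted motif instances; site neighbourhoods are
# rejection-sampled to be free of chance matches at the scan threshold, so
# measured motif proportions equal the planted rates
world_sequences <- function(world) {
  cfg <- world$config
  p <- tbox_pwm()
  dist <- score_distribution(p, unname(cfg$base_freq))
  thr <- dist$support[which(dist$pvalues < cfg$fimo_p)[1L]]
  S_fwd <- dist$int_scores
  S_rev <- revcomp_int_matrix(S_fwd)
  cons <- apply(pwm_probs(p), 2, which.max)
  cons_rc <- rev(5L - cons)
  sites <- world$truth_sites
  out <- list()
  for (side in c("a", "b")) {
    szs <- if (side == "a") world$sizes_a else world$sizes_b
    # scrub regions: own sites of this species + lifted loci of the other
    own <- sites[sites$species == side & sites$class != "decoy", , drop = FALSE]
    # lifted loci of the other species' specific/indeterminate sites; the
    # lifted locus of a conserved site coincides with its partner's own
    # interval and must not be scrubbed twice (it would erase planted motifs)
    oth <- sites[sites$species != side & !is.na(sites$other_start0) &
                   sites$class %in% c("species_specific", "indeterminate"), ,
                 drop = FALSE]
    regs <- rbind(
      data.frame(chrom = own$chrom, s0 = own$start0, e0 = own$end0,
                 plant = own$motif_own),
      data.frame(chrom = oth$chrom, s0 = oth$other_start0,
                 e0 = oth$other_end0, plant = oth$motif_other))
    regs$s0 <- regs$s0 - cfg$scrub_pad
    regs$e0 <- regs$e0 + cfg$scrub_pad
    seqs <- list()
    for (chn in names(szs)) {
      L <- szs[[chn]]
      codes <- sample.int(4L, L, replace = TRUE, prob = cfg$base_freq)
      rr <- regs[regs$chrom == chn, , drop = FALSE]
      for (j in seq_len(nrow(rr))) {
        s1 <- rr$s0[j] + 1L; e1 <- rr$e0[j]
        if (rr$plant[j]) {
          mid <- floor((s1 + e1) / 2)
          ins <- if (runif(1) < 0.5) cons else cons_rc
          at <- mid - floor(length(ins) / 2)
          codes[at:(at + length(ins) - 1L)] <- ins
        } else {
          for (try in 1:100) {
            seg <- codes[s1:e1]
            hit <- any(scan_codes(seg, S_fwd) >= thr, na.rm = TRUE) ||
              any(scan_codes(seg, S_rev) >= thr, na.rm = TRUE)
            if (!hit) break
            codes[s1:e1] <- sample.int(4L, e1 - s1 + 1L, replace = TRUE,
                                       prob = cfg$base_freq)
          }
        }
      }
      seqs[[chn]] <- paste(DNA_BASES[codes], collapse = "")
    }
    dss <- DNAStringSet(unlist(seqs))
    names(dss) <- names(szs)
    out[[side]] <- dss
  }
  out
}

# ---- emissions -------------------------------------------------------------

#' Replicate ChIP peak calls for the synthetic world
#'
#' Emits one peak set per replicate per species: every truly bound site gets
#' a jittered peak with q < 0.01 (degraded into (0.01, 0.1) with probability
#' `q_noise_rate`, the replicate-dropout noise model); indeterminate sites of
#' the other species contribute a low-confidence (0.01 < q < 0.1) peak at
#' their lifted locus in one replicate; blacklist decoys get strong peaks in
#' every replicate.
#'
#' @param world A [build_world()] result.
#' @param noise Override of `config$q_noise_rate` (0 disables dropout noise).
#' @return List with elements `a` and `b`, each a list of `GRanges` (one per
#'   replicate) with narrowPeak-style metadata.
#' @export
emit_replicate_peaks <- function(world, noise = NULL) {
  cfg <- world$config
  if (is.null(noise)) noise <- cfg$q_noise_rate
  set.seed(cfg$seed + 1L)
  sites <- world$truth_sites
  out <- list()
  for (side in c("a", "b")) {
    n_rep <- cfg$replicates[[side]]
    own <- sites[sites$species == side, , drop = FALSE]
    other_ind <- sites[sites$species != side &
                         sites$class == "indeterminate", , drop = FALSE]
    lowconf_rep <- sample.int(n_rep, nrow(other_ind), replace = TRUE)
    reps <- list()
    for (r in seq_len(n_rep)) {
      js <- round(runif(nrow(own), 0, cfg$jitter))
      je <- round(runif(nrow(own), 0, cfg$jitter))
      neglog_q <- runif(nrow(own), 2.35, 8)
      drop <- runif(nrow(own)) < noise & own$class != "decoy"
      neglog_q[drop] <- runif(sum(drop), 1.06, 1.95)
      gr <- GRanges(own$chrom,
                    IRanges(own$start0 + 1 - js, own$end0 + je))
      li <- other_ind[lowconf_rep == r, , drop = FALSE]
      if (nrow(li) > 0L) {
        gr2 <- GRanges(li$chrom,
                       IRanges(li$other_start0 + 1, li$other_end0))
        gr <- c(gr, gr2)
        neglog_q <- c(neglog_q, runif(nrow(li), 1.06, 1.95))
      }
      gr$name <- sprintf("%s_rep%d_peak%04d", cfg$species[[side]], r,
                         seq_along(gr))
      gr$score <- round(neglog_q * 10)
      gr$signalValue <- round(10^(neglog_q / 4), 3)
      gr$pValue <- round(neglog_q + 1, 3)
      gr$qValue <- round(neglog_q, 4)
      gr$peak <- width(gr) %/% 2L
      gr$q <- 10^(-gr$qValue)
      reps[[r]] <- sort(gr)
    }
    out[[side]] <- reps
  }
  out
}

#' RNA-seq count matrices for the synthetic world
#'
#' Negative-binomial counts for every gene of each species across the
#' configured studies, with per-(study) global library shifts, per-gene
#' between-study noise, and the planted class-linked species effects split
#' symmetrically across species (A gets +effect/2 in log2, B gets -effect/2).
#'
#' @param world A [build_world()] result.
#' @return List with elements `a` and `b`, each holding `counts` (matrix) and
#'   `meta` (sample metadata data.frame with `sample`, `species`, `study`).
#' @export
emit_counts <- function(world) {
  cfg <- world$config
  set.seed(cfg$seed + 2L)
  ort <- world$orthologs
  base <- rlnorm(nrow(ort), cfg$base_meanlog, cfg$base_sdlog)
  out <- list()
  for (side in c("a", "b")) {
    gm <- if (side == "a") world$genes_a else world$genes_b
    ids <- gm$genes$gene_id
    key <- if (side == "a") ort$gene_a else ort$gene_b
    oi <- match(ids, key)
    mu0 <- ifelse(is.na(oi), rlnorm(length(ids), cfg$base_meanlog,
                                    cfg$base_sdlog), base[oi])
    e <- ifelse(is.na(oi), 0, ort$effect[oi])
    log2_gene <- if (side == "a") e / 2 else -e / 2
    n_st <- cfg$studies
    n_sp <- cfg$samples_per_study
    cols <- list(); meta <- list()
    for (st in seq_len(n_st)) {
      batch <- rnorm(1, 0, cfg$batch_sd)
      z <- rnorm(length(ids), 0, cfg$noise_sd)
      mu <- mu0 * 2^(log2_gene + batch + z)
      for (sp in seq_len(n_sp)) {
        nm <- sprintf("%s_st%d_s%d", cfg$species[[side]], st, sp)
        cols[[nm]] <- rnbinom(length(ids), mu = mu, size = 1 / cfg$dispersion)
        meta[[nm]] <- data.frame(sample = nm, species = cfg$species[[side]],
                                 study = paste0("study", st))
      }
    }
    counts <- do.call(cbind, cols)
    rownames(counts) <- ids
    out[[side]] <- list(counts = counts, meta = do.call(rbind, meta))
  }
  out
}

#' Write a synthetic world to disk in standard formats
#'
#' Emits genomes (FASTA + chrom.sizes), chains in both directions, GTF gene
#' annotations, the ortholog table, TE and blacklist BEDs, per-replicate
#' narrowPeak files, count matrices with sample metadata, the bundled PWM in
#' MEME format, ground-truth tables, and a manifest recording the seed.
#'
#' @param world A [build_world()] result (with sequences for FASTA output).
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of file paths (also stored in
#'   `manifest.json`).
#' @export
write_world <- function(world, dir) {
  cfg <- world$config
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(dir, paste0(...))
  sp <- cfg$species
  seed_cmt <- paste("seed:", cfg$seed)
  files <- list()

  for (side in c("a", "b")) {
    lab <- sp[[side]]
    szs <- if (side == "a") world$sizes_a else world$sizes_b
    write.table(data.frame(names(szs), unname(szs)),
                pth(lab, ".chrom.sizes"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    files[[paste0("chrom_sizes_", lab)]] <- pth(lab, ".chrom.sizes")
    if (!is.null(world$sequences)) {
      writeXStringSet(world$sequences[[side]], pth("genome_", lab, ".fa"))
      files[[paste0("genome_", lab)]] <- pth("genome_", lab, ".fa")
    }
    gm <- if (side == "a") world$genes_a else world$genes_b
    write_gtf(gm, pth("genes_", lab, ".gtf"), source_tag = "synthetic")
    files[[paste0("gtf_", lab)]] <- pth("genes_", lab, ".gtf")
    te <- world$tes[[side]]
    te_out <- te
    te_out$name <- paste0(te$name, "#", te$te_class)
    write_bed(te_out, pth("te_", lab, ".bed"))
    files[[paste0("te_", lab)]] <- pth("te_", lab, ".bed")
    write_bed(world$blacklist[[side]], pth("blacklist_", lab, ".bed"))
    files[[paste0("blacklist_", lab)]] <- pth("blacklist_", lab, ".bed")
  }
  write_chain(world$chains_ab, pth(sp[["a"]], "To", sp[["b"]], ".chain"))
  write_chain(world$chains_ba, pth(sp[["b"]], "To", sp[["a"]], ".chain"))
  files$chain_ab <- pth(sp[["a"]], "To", sp[["b"]], ".chain")
  files$chain_ba <- pth(sp[["b"]], "To", sp[["a"]], ".chain")

  ort <- world$orthologs
  write_tsv_table(ort[, c("gene_a", "gene_b")], pth("orthologs.tsv"),
                  comment = seed_cmt)
  files$orthologs <- pth("orthologs.tsv")

  peaks <- emit_replicate_peaks(world)
  for (side in c("a", "b")) {
    for (r in seq_along(peaks[[side]])) {
      f <- pth("peaks_", sp[[side]], "_rep", r, ".narrowPeak")
      write_narrowpeak(peaks[[side]][[r]], f)
      files[[paste0("peaks_", sp[[side]], "_rep", r)]] <- f
    }
  }
  cnt <- emit_counts(world)
  for (side in c("a", "b")) {
    lab <- sp[[side]]
    cdf <- data.frame(gene_id = rownames(cnt[[side]]$counts),
                      cnt[[side]]$counts, check.names = FALSE)
    write_tsv_table(cdf, pth("counts_", lab, ".tsv"), comment = seed_cmt)
    write_tsv_table(cnt[[side]]$meta, pth("samples_", lab, ".tsv"),
                    comment = seed_cmt)
    files[[paste0("counts_", lab)]] <- pth("counts_", lab, ".tsv")
    files[[paste0("samples_", lab)]] <- pth("samples_", lab, ".tsv")
  }
  write_meme(list(tbox_pwm()), pth("motifs.meme"),
             background = unname(cfg$base_freq))
  files$motifs <- pth("motifs.meme")

  write_tsv_table(world$truth_sites, pth("truth_sites.tsv"),
                  comment = seed_cmt)
  write_tsv_table(world$orthologs, pth("truth_genes.tsv"),
                  comment = seed_cmt)
  files$truth_sites <- pth("truth_sites.tsv")
  files$truth_genes <- pth("truth_genes.tsv")

  manifest <- list(seed = cfg$seed, species = as.list(sp),
                   files = lapply(files, basename))
  write_json(manifest, pth("manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  files$manifest <- pth("manifest.json")
  invisible(files)
}

write_gtf <- function(gm, path, source_tag = "synthetic") {
  con <- file(path, "w")
  on.exit(close(con))
  g <- gm$genes
  tss <- gm$tss
  for (i in seq_along(g)) {
    gid <- g$gene_id[i]
    attr_g <- sprintf('gene_id "%s"; gene_name "%s";', gid, g$symbol[i])
    writeLines(paste(as.character(seqnames(g))[i], source_tag, "gene",
                     start(g)[i], end(g)[i], ".",
                     as.character(strand(g))[i], ".", attr_g, sep = "\t"),
               con)
    tx <- tss[tss$gene_id == gid, , drop = FALSE]
    for (k in seq_len(nrow(tx))) {
      tid <- sprintf("%s.t%d", gid, k)
      attr_t <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                        gid, tid, g$symbol[i])
      if (tx$strand[k] == "+") {
        ts <- tx$pos[k]; te <- max(tx$pos[k] + 200, end(g)[i])
      } else {
        te <- tx$pos[k]; ts <- min(tx$pos[k] - 200, start(g)[i])
      }
      writeLines(paste(tx$chrom[k], source_tag, "transcript", ts, te, ".",
                       tx$strand[k], ".", attr_t, sep = "\t"), con)
      writeLines(paste(tx$chrom[k], source_tag, "exon", ts, te, ".",
                       tx$strand[k], ".", attr_t, sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Simulate a complete world on disk
#'
#' Convenience wrapper: [build_world()] then [write_world()].
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory.
#' @return The in-memory world, invisibly; files are written under `dir`.
#' @export
simulate_world <- function(config = synthetic_config(), dir) {
  world <- build_world(config)
  write_world(world, dir)
  invisible(world)
}

# ---- recovery metrics ------------------------------------------------------

#' Site-class recovery against planted truth
#'
#' Fraction of planted, truly bound sites of one species that appear in the
#' classified consensus set with the correct conservation class (a planted
#' site missing from the consensus counts as a miss).
#'
#' @param classified Classified consensus `GRanges` (with `site_class`).
#' @param world The generating [build_world()] world.
#' @param side `"a"` or `"b"`.
#' @return Fraction in `[0, 1]`.
#' @export
site_class_recovery <- function(classified, world, side) {
  truth <- world$truth_sites
  truth <- truth[truth$species == side & truth$class != "decoy", ,
                 drop = FALSE]
  tg <- GRanges(truth$chrom, IRanges(truth$start0 + 1, truth$end0))
  ov <- findOverlaps(tg, classified)
  got <- rep(NA_character_, length(tg))
  got[queryHits(ov)] <- as.character(classified$site_class[subjectHits(ov)])
  mean(!is.na(got) & got == truth$class)
}

#' Gene-class recovery against derived truth
#'
#' Fraction of ortholog pairs whose recovered gene class equals the
#' generator's derived ground-truth class.
#'
#' @param gene_table Classified profiles from [classify_genes()].
#' @param world The generating world.
#' @return Fraction in `[0, 1]`.
#' @export
gene_class_recovery <- function(gene_table, world) {
  truth <- world$orthologs
  m <- match(truth$gene_a, gene_table$gene_a)
  mean(as.character(gene_table$gene_class[m]) == truth$class, na.rm = TRUE)
}
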