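# PWM scanning with exact p-values (dynamic programming over the discretised
# log-odds null distribution), proportion estimates, and known-motif
# enrichment between site sets.

#' @importFrom stats prop.test phyper p.adjust
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix object
#'
#' @param mat 4 x w matrix of base probabilities (rows A, C, G, T) or counts
#'   (normalised per column).
#' @param name Motif name.
#' @param pseudocount Added to every cell (as a fraction of the column sum)
#'   when any probability is zero, to keep log-odds finite.
#' @return Object of class `pwm`.
#' @export
pwm <- function(mat, name = "motif", pseudocount = 1e-3) {
  stopifnot(nrow(mat) == 4L, ncol(mat) >= 4L)
  rownames(mat) <- DNA_BASES
  mat <- sweep(mat, 2, colSums(mat), "/")
  if (any(abs(colSums(mat) - 1) > 1e-9)) stop("PWM columns must sum to 1")
  structure(list(name = name, mat = mat, width = ncol(mat),
                 pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cons <- paste(DNA_BASES[apply(x$mat, 2, which.max)], collapse = "")
  cat("pwm '", x$name, "': width ", x$width, ", consensus ", cons, "\n",
      sep = "")
  invisible(x)
}

#' Read PWMs from JASPAR text format
#'
#' Expects records of the form `>ID NAME` followed by four rows
#' `A [ counts... ]` (C, G, T), or four bare count rows in ACGT order.
#'
#' @param path Path to a JASPAR-format file.
#' @return Named list of [pwm()] objects.
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no JASPAR records in ", path)
  out <- list()
  for (k in seq_along(hdr)) {
    name_parts <- strsplit(sub("^>\\s*", "", lines[hdr[k]]), "\\s+")[[1L]]
    nm <- name_parts[length(name_parts)]
    rows <- lines[hdr[k] + 1:4]
    mat <- do.call(rbind, lapply(rows, function(r) {
      r <- gsub("^[ACGTacgt]\\s*\\[|\\]", "", r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1L]])
    }))
    out[[nm]] <- pwm(mat, name = nm)
  }
  out
}

#' Read PWMs from MEME minimal format
#'
#' Parses `MOTIF` records with their `letter-probability matrix:` blocks
#' (rows are positions, columns A, C, G, T). A `Background letter
#' frequencies` section, when present, is returned as the `background`
#' attribute of the result (the background FIMO would use).
#'
#' @param path Path to a MEME minimal-format file.
#' @return Named list of [pwm()] objects, with an optional `background`
#'   attribute (numeric A, C, G, T frequencies).
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  motif_idx <- grep("^MOTIF\\b", lines)
  if (length(motif_idx) == 0L) stop("no MOTIF records in ", path)
  out <- list()
  bg_idx <- grep("^Background letter frequencies", lines)
  bg <- NULL
  if (length(bg_idx) > 0L) {
    toks <- strsplit(trimws(lines[bg_idx[1L] + 1L]), "\\s+")[[1L]]
    vals <- suppressWarnings(as.numeric(toks))
    bg <- vals[!is.na(vals)]
    names(bg) <- toks[which(!is.na(vals)) - 1L]
    bg <- unname(bg[DNA_BASES])
    if (length(bg) != 4L || anyNA(bg)) bg <- NULL
  }
  for (mi in motif_idx) {
    nm <- strsplit(trimws(lines[mi]), "\\s+")[[1L]][2L]
    li <- grep("^letter-probability matrix", lines[seq(mi, length(lines))])[1L] + mi - 1L
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[li]))
    rows <- lines[li + seq_len(w)]
    mat <- t(vapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1L]][1:4])
    }, numeric(4)))
    dimnames(mat) <- NULL
    out[[nm]] <- pwm(t(mat), name = nm)
  }
  attr(out, "background") <- bg
  out
}

#' Write PWMs in MEME minimal format
#'
#' @param pwms List of [pwm()] objects.
#' @param path Output path.
#' @param background Background base frequencies recorded in the header.
#' @export
write_meme <- function(pwms, path, background = rep(0.25, 4)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies", paste(
                 paste(DNA_BASES, sprintf("%.3f", background)),
                 collapse = " "), ""), con)
  for (p in pwms) {
    writeLines(c(paste("MOTIF", p$name),
                 sprintf("letter-probability matrix: alength= 4 w= %d",
                         p$width)), con)
    writeLines(apply(p$mat, 2, function(col) {
      paste(sprintf("%.6f", col), collapse = " ")
    }), con)
    writeLines("", con)
  }
  invisible(path)
}

pwm_probs <- function(p) {
  m <- p$mat
  if (any(m == 0)) {
    m <- sweep(m + p$pseudocount / 4, 2, 1 + p$pseudocount, "/")
  }
  m
}

#' Exact null distribution of the PWM log-odds score
#'
#' Log-odds scores (bits) are discretised to `bin`-width integer units; the
#' exact null distribution of the total window score under an order-0
#' background is built by dynamic programming over motif positions. P-values
#' are upper tails: `p(s) = P(score >= s)`.
#'
#' @param p A [pwm()].
#' @param background Base frequencies (A, C, G, T), summing to 1.
#' @param bin Discretisation bin width in bits (default 0.01).
#' @return List of class `pwm_score_dist` with the integer score matrix
#'   (`int_scores`), the null probabilities (`probs`) over total scores
#'   `support`, and upper-tail `pvalues`.
#' @export
score_distribution <- function(p, background = rep(0.25, 4), bin = 0.01) {
  stopifnot(abs(sum(background) - 1) < 1e-6, all(background >= 0))
  m <- pwm_probs(p)
  if (any(background == 0 & m > 0)) {
    stop("zero background frequency with non-zero motif probability")
  }
  S <- round(log2(sweep(m, 1, background, "/")) / bin)
  storage.mode(S) <- "integer"
  lo <- sum(apply(S, 2, min))
  hi <- sum(apply(S, 2, max))
  dist <- numeric(hi - lo + 1L)          # index k <-> score lo + k - 1
  # DP: running support is [cur_lo, cur_hi]
  cur <- 1
  cur_lo <- 0L
  for (j in seq_len(ncol(S))) {
    cmin <- min(S[, j]); cmax <- max(S[, j])
    new_lo <- cur_lo + cmin
    new <- numeric(length(cur) + (cmax - cmin))
    for (b in 1:4) {
      sh <- S[b, j] - cmin
      idx <- seq_along(cur) + sh
      new[idx] <- new[idx] + cur * background[b]
    }
    cur <- new
    cur_lo <- new_lo
  }
  probs <- numeric(hi - lo + 1L)
  probs[(cur_lo - lo + 1L):(cur_lo - lo + length(cur))] <- cur
  structure(list(int_scores = S, bin = bin, background = background,
                 support = lo:hi, probs = probs,
                 pvalues = rev(cumsum(rev(probs)))),
            class = "pwm_score_dist")
}

#' Upper-tail p-value of an integer window score
#'
#' @param dist A `pwm_score_dist` from [score_distribution()].
#' @param int_score Integer score(s) in discretised units.
#' @return `P(score >= int_score)` under the background model (1 below the
#'   support, the minimum tail above it).
#' @export
score_pvalue <- function(dist, int_score) {
  lo <- dist$support[1L]
  hi <- dist$support[length(dist$support)]
  i <- pmin(pmax(int_score, lo), hi + 1L) - lo + 1L
  c(dist$pvalues, 0)[i]
}

seq_codes <- function(s) {
  x <- match(strsplit(toupper(as.character(s)), "")[[1L]], DNA_BASES)
  x
}

revcomp_int_matrix <- function(S) {
  S[4:1, rev(seq_len(ncol(S))), drop = FALSE]
}

scan_codes <- function(codes, S) {
  w <- ncol(S)
  L <- length(codes)
  if (L < w) return(integer(0))
  n_win <- L - w + 1L
  sc <- rep(0L, n_win)
  ok <- rep(TRUE, n_win)
  for (j in seq_len(w)) {
    cj <- codes[j:(j + n_win - 1L)]
    na <- is.na(cj)
    ok <- ok & !na
    cj[na] <- 1L
    sc <- sc + S[cbind(cj, j)]
  }
  sc[!ok] <- NA_integer_
  sc
}

#' Scan sequences for significant PWM matches
#'
#' Scores every window on both strands against the discretised PWM and keeps
#' positions whose exact upper-tail p-value is below the threshold. Windows
#' containing N (or any non-ACGT base) are skipped; sequences shorter than
#' the motif yield no hits, with a warning.
#'
#' @param seqs `DNAStringSet` or named character vector of uppercase
#'   sequences.
#' @param p A [pwm()].
#' @param p_threshold Per-position match p-value threshold (default 0.004).
#' @param background Optional base frequencies; estimated from the scanned
#'   sequences when missing.
#' @param bin Score bin width in bits.
#' @return data.frame of hits: `seq` (name), `offset` (1-based window start
#'   on the forward sequence), `strand`, `score_bits`, `p`.
#' @export
scan_sequences <- function(seqs, p, p_threshold = 0.004,
                           background = NULL, bin = 0.01) {
  nms <- names(seqs)
  seqs_chr <- toupper(as.character(seqs))
  names(seqs_chr) <- if (is.null(nms)) seq_along(seqs_chr) else nms
  if (is.null(background)) {
    tab <- table(factor(unlist(strsplit(seqs_chr, "")), levels = DNA_BASES))
    if (sum(tab) == 0) stop("cannot estimate background: no ACGT bases")
    background <- as.numeric(tab / sum(tab))
  }
  dist <- score_distribution(p, background, bin)
  S_fwd <- dist$int_scores
  S_rev <- revcomp_int_matrix(S_fwd)
  if (any(nchar(seqs_chr) < p$width)) {
    warning("sequence(s) shorter than the motif width: no hits possible")
  }
  hits <- vector("list", length(seqs_chr))
  for (i in seq_along(seqs_chr)) {
    codes <- seq_codes(seqs_chr[i])
    rows <- list()
    for (strand in c("+", "-")) {
      S <- if (strand == "+") S_fwd else S_rev
      sc <- scan_codes(codes, S)
      if (length(sc) == 0L) next
      pv <- score_pvalue(dist, sc)
      sel <- which(!is.na(sc) & pv < p_threshold)
      if (length(sel) > 0L) {
        rows[[strand]] <- data.frame(
          seq = names(seqs_chr)[i], offset = sel, strand = strand,
          score_bits = sc[sel] * bin, p = pv[sel],
          stringsAsFactors = FALSE)
      }
    }
    hits[[i]] <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(seq = character(0), offset = integer(0),
                      strand = character(0), score_bits = numeric(0),
                      p = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Proportion of sites containing a motif
#'
#' Counts the sites with at least one significant match and attaches the 95%
#' confidence interval of the binomial proportion (continuity-corrected
#' Wilson score interval, the `prop.test` convention).
#'
#' @param seqs Site sequences (`DNAStringSet` or character).
#' @param p A [pwm()].
#' @param p_threshold Match p-value threshold (default 0.004).
#' @param background Optional base frequencies.
#' @return data.frame: `k`, `n`, `proportion`, `ci_low`, `ci_high`.
#' @export
motif_proportion <- function(seqs, p, p_threshold = 0.004,
                             background = NULL) {
  n <- length(seqs)
  if (n == 0L) stop("no sites to scan")
  hits <- scan_sequences(seqs, p, p_threshold, background)
  nm <- names(seqs)
  if (is.null(nm)) nm <- as.character(seq_len(n))
  k <- sum(nm %in% hits$seq)
  ci <- suppressWarnings(prop.test(k, n)$conf.int)
  data.frame(k = k, n = n, proportion = k / n,
             ci_low = ci[1L], ci_high = ci[2L])
}

#' Known-motif enrichment of target over background sites
#'
#' For each PWM: the one-sided hypergeometric p-value for over-representation
#' of motif-containing sites among targets, drawing from the pooled
#' target-plus-background universe.
#'
#' @param target_seqs,background_seqs Disjoint site sequence sets.
#' @param pwms List of [pwm()] objects.
#' @param p_threshold Match p-value threshold.
#' @param background Optional base frequencies (estimated from the pooled
#'   sequences when missing).
#' @return data.frame per motif: `motif`, `k_target`, `n_target`, `k_total`,
#'   `n_total`, `p`, `neg_log10_p`.
#' @export
known_motif_enrichment <- function(target_seqs, background_seqs, pwms,
                                   p_threshold = 0.004, background = NULL) {
  nt <- length(target_seqs)
  if (nt == 0L) stop("empty target set")
  t_chr <- toupper(as.character(target_seqs))
  b_chr <- toupper(as.character(background_seqs))
  names(t_chr) <- paste0("t", seq_along(t_chr))
  names(b_chr) <- paste0("b", seq_along(b_chr))
  pooled <- c(t_chr, b_chr)
  if (is.null(background)) {
    tab <- table(factor(unlist(strsplit(pooled, "")), levels = DNA_BASES))
    background <- as.numeric(tab / sum(tab))
  }
  rows <- lapply(pwms, function(p) {
    hits <- scan_sequences(pooled, p, p_threshold, background)
    with_hit <- unique(hits$seq)
    kt <- sum(names(t_chr) %in% with_hit)
    kk <- length(with_hit)
    nn <- length(pooled)
    pv <- phyper(kt - 1, kk, nn - kk, nt, lower.tail = FALSE)
    data.frame(motif = p$name, k_target = kt, n_target = nt,
               k_total = kk, n_total = nn, p = pv,
               neg_log10_p = -log10(pv), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Normalise a motif-enrichment matrix across site sets
#'
#' Benjamini-Hochberg q-values are computed within each site set (column);
#' motifs significant (q < `q_max`) in at least one set are kept and the
#' -log10 p-values are min-max normalised within each column. Cells that are
#' not themselves significant are flagged (they would be greyed out in a
#' heat map).
#'
#' @param neglog10_mat Matrix of -log10 p-values, motifs x site sets.
#' @param q_max BH q-value cutoff (default 0.05).
#' @return List: `normalized` (matrix on kept motifs), `significant`
#'   (logical matrix), `kept_motifs`, `q` (full q-value matrix).
#' @export
normalize_enrichment_matrix <- function(neglog10_mat, q_max = 0.05) {
  m <- as.matrix(neglog10_mat)
  pmat <- 10^(-m)
  qmat <- apply(pmat, 2, p.adjust, method = "BH")
  qmat <- matrix(qmat, nrow = nrow(m), dimnames = dimnames(m))
  keep <- apply(qmat < q_max, 1, any)
  if (!any(keep)) {
    return(list(normalized = m[integer(0), , drop = FALSE],
                significant = qmat[integer(0), , drop = FALSE] < q_max,
                kept_motifs = character(0), q = qmat))
  }
  norm <- apply(m[keep, , drop = FALSE], 2, function(x) {
    rng <- range(x)
    if (diff(rng) == 0) rep(1, length(x)) else (x - rng[1L]) / diff(rng)
  })
  norm <- matrix(norm, ncol = ncol(m),
                 dimnames = list(rownames(m)[keep], colnames(m)))
  list(normalized = norm,
       significant = qmat[keep, , drop = FALSE] < q_max,
       kept_motifs = rownames(m)[keep],
       q = qmat)
}

#' Bundled synthetic T-box-like PWM
#'
#' A 12-column near-deterministic matrix with consensus AGGTGTGAAAAT,
#' loosely shaped like a T-box binding motif. It is a synthetic construction
#' used by the data generator, not an experimentally derived matrix. With
#' near-deterministic columns and a balanced background, the null score
#' distribution is a coarse ladder of well-separated atoms (one per number
#' of matching positions), so the set of significant matches at the scan
#' threshold is stable under small perturbations of the background estimate
#' (see the methods vignette).
#'
#' @param sharp Probability mass on the consensus base per column.
#' @return A [pwm()].
#' @export
tbox_pwm <- function(sharp = 0.997) {
  cons <- c("A", "G", "G", "T", "G", "T", "G", "A", "A", "A", "A", "T")
  mat <- matrix((1 - sharp) / 3, nrow = 4, ncol = length(cons),
                dimnames = list(DNA_BASES, NULL))
  for (j in seq_along(cons)) mat[cons[j], j] <- sharp
  pwm(mat, name = "TBOX_synthetic")
}

#' Extract site sequences from a genome
#'
#' @param genome `DNAStringSet` keyed by chromosome name.
#' @param gr Site intervals (`GRanges`).
#' @return `DNAStringSet` named by `site_id` (or index).
#' @export
site_sequences <- function(genome, gr) {
  chroms <- as.character(seqnames(gr))
  if (!all(chroms %in% names(genome))) {
    stop("sites reference chromosomes absent from the genome")
  }
  out <- DNAStringSet(vapply(seq_along(gr), function(i) {
    as.character(Biostrings::subseq(genome[[chroms[i]]],
                                    start(gr)[i], end(gr)[i]))
  }, ""))
  names(out) <- if (!is.null(gr$site_id)) gr$site_id else seq_along(gr)
  out
}
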