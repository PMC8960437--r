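#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom GenomeInfoDb seqnames seqlevels
#' @importFrom methods is
#' @importFrom utils read.table write.table
#' @importFrom stats setNames
NULL

# Internal convention: all GRanges are 1-based closed (Bioconductor native).
# BED-family files (BED6, narrowPeak, chain) are 0-based half-open and are
# converted on read/write.

#' Read an ENCODE narrowPeak file
#'
#' Parses the 10-column ENCODE narrowPeak dialect (the MACS2 output format).
#' Column 9 holds -log10(qValue), with -1 as the "not available" sentinel.
#'
#' @param path Path to a narrowPeak file.
#' @return A `GRanges` with metadata columns `name`, `score`, `signalValue`,
#'   `pValue`, `qValue` (the -log10 values as stored in the file), `peak`
#'   (summit offset, `NA` if absent), and `q` (the q-value back-transformed to
#'   the probability scale, `NA` when the sentinel -1 was stored).
#' @export
read_narrowpeak <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(GRanges(q = numeric(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 10L)
  if (length(bad) > 0L) {
    stop("narrowPeak parse error at line ", bad[1L], " of ", path,
         ": expected 10 tab-separated columns, found ", nf[bad[1L]])
  }
  m <- matrix(unlist(fields), ncol = 10L, byrow = TRUE)
  start0 <- suppressWarnings(as.integer(m[, 2L]))
  end0 <- suppressWarnings(as.integer(m[, 3L]))
  if (anyNA(start0) || anyNA(end0)) {
    stop("narrowPeak parse error in ", path, ": non-integer coordinates at line ",
         which(is.na(start0) | is.na(end0))[1L])
  }
  if (any(end0 <= start0)) {
    stop("narrowPeak invariant error in ", path, ": end <= start at line ",
         which(end0 <= start0)[1L])
  }
  qcol <- as.numeric(m[, 9L])
  gr <- GRanges(m[, 1L], IRanges(start0 + 1L, end0),
                strand = ifelse(m[, 6L] %in% c("+", "-"), m[, 6L], "*"))
  mcols(gr) <- S4Vectors::DataFrame(
    name = m[, 4L],
    score = as.numeric(m[, 5L]),
    signalValue = as.numeric(m[, 7L]),
    pValue = as.numeric(m[, 8L]),
    qValue = qcol,
    peak = ifelse(as.integer(m[, 10L]) < 0L, NA_integer_, as.integer(m[, 10L])),
    q = ifelse(qcol < 0, NA_real_, 10^(-qcol))
  )
  gr
}

#' Write intervals as narrowPeak
#'
#' @param gr A `GRanges`, ideally carrying the metadata columns produced by
#'   [read_narrowpeak()]; missing columns are filled with format sentinels.
#' @param path Output path.
#' @export
write_narrowpeak <- function(gr, path) {
  mc <- mcols(gr)
  get_col <- function(nm, default) {
    if (nm %in% names(mc)) mc[[nm]] else rep(default, length(gr))
  }
  peak <- get_col("peak", NA_integer_)
  df <- data.frame(
    chrom = as.character(seqnames(gr)),
    start = start(gr) - 1L,
    end = end(gr),
    name = as.character(get_col("name", ".")),
    score = get_col("score", 0),
    strand = ifelse(as.character(strand(gr)) == "*", ".",
                    as.character(strand(gr))),
    signalValue = get_col("signalValue", 0),
    pValue = get_col("pValue", -1),
    qValue = get_col("qValue", -1),
    peak = ifelse(is.na(peak), -1L, peak)
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 (or BED3/4/5) file as GRanges
#'
#' @param path Path to a BED file (0-based half-open; converted to 1-based
#'   closed coordinates).
#' @return A `GRanges` with `name` and `score` metadata columns when present.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L) return(GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- min(lengths(fields))
  if (nf < 3L) stop("BED parse error in ", path, ": fewer than 3 columns")
  m <- matrix(unlist(lapply(fields, `[`, seq_len(nf))), ncol = nf, byrow = TRUE)
  start0 <- as.integer(m[, 2L])
  end0 <- as.integer(m[, 3L])
  if (any(end0 <= start0)) {
    stop("BED invariant error in ", path, ": end <= start at line ",
         which(end0 <= start0)[1L])
  }
  str <- if (nf >= 6L) ifelse(m[, 6L] %in% c("+", "-"), m[, 6L], "*") else "*"
  gr <- GRanges(m[, 1L], IRanges(start0 + 1L, end0), strand = str)
  if (nf >= 4L) gr$name <- m[, 4L]
  if (nf >= 5L) gr$score <- suppressWarnings(as.numeric(m[, 5L]))
  gr
}

#' Write GRanges as BED6
#'
#' @param gr A `GRanges`; `name` and `score` metadata columns are used when
#'   present.
#' @param path Output path.
#' @export
write_bed <- function(gr, path) {
  df <- data.frame(
    chrom = as.character(seqnames(gr)),
    start = start(gr) - 1L,
    end = end(gr),
    name = if (!is.null(gr$name)) as.character(gr$name) else ".",
    score = if (!is.null(gr$score)) gr$score else 0,
    strand = ifelse(as.character(strand(gr)) == "*", ".",
                    as.character(strand(gr)))
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column chromosome sizes table
#'
#' @param path Path to a TSV with columns chromosome name and length in bp.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "size"),
                   colClasses = c("character", "numeric"))
  setNames(as.integer(df$size), df$chrom)
}

#' Construct a gene model set
#'
#' Bundles gene spans with per-transcript transcription start sites. The TSS of
#' a minus-strand transcript is its largest coordinate; each gene may have
#' several TSS (one per transcript).
#'
#' @param genes `GRanges` of gene spans with metadata columns `gene_id` and
#'   optionally `symbol`.
#' @param tss data.frame with columns `gene_id`, `chrom`, `pos` (1-based TSS
#'   position), `strand`.
#' @return An object of class `gene_models`.
#' @export
gene_models <- function(genes, tss) {
  stopifnot(is(genes, "GRanges"), !is.null(genes$gene_id))
  stopifnot(all(c("gene_id", "chrom", "pos", "strand") %in% names(tss)))
  if (any(!tss$gene_id %in% genes$gene_id)) {
    stop("tss table references unknown gene_id")
  }
  if (!all(genes$gene_id %in% tss$gene_id)) {
    stop("every gene needs at least one TSS")
  }
  tss <- tss[order(tss$chrom, tss$pos, tss$gene_id), , drop = FALSE]
  structure(list(genes = genes, tss = tss), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models: ", length(x$genes), " genes, ",
      nrow(x$tss), " TSS on ",
      length(unique(x$tss$chrom)), " chromosomes\n", sep = "")
  invisible(x)
}

#' Read gene models from a GTF file
#'
#' Imports a GTF (1-based inclusive; via rtracklayer) and extracts gene spans
#' and per-transcript TSS. Transcript rows define the TSS (5' end on the
#' transcript strand); gene spans come from `gene` rows, or are computed as
#' the transcript hull when absent.
#'
#' @param path Path to a GTF file with `gene_id` (and optionally `gene_name`,
#'   `transcript_id`) attributes.
#' @return A [gene_models()] object.
#' @export
read_gene_models <- function(path) {
  gtf <- rtracklayer::import(path, format = "gtf")
  tx <- gtf[gtf$type == "transcript"]
  if (length(tx) == 0L) tx <- gtf[gtf$type == "exon"]
  if (length(tx) == 0L) stop("GTF has no transcript or exon rows: ", path)
  tss_pos <- ifelse(as.character(strand(tx)) == "-", end(tx), start(tx))
  tss <- unique(data.frame(
    gene_id = tx$gene_id,
    chrom = as.character(seqnames(tx)),
    pos = tss_pos,
    strand = as.character(strand(tx)),
    stringsAsFactors = FALSE
  ))
  g <- gtf[gtf$type == "gene"]
  if (length(g) == 0L) {
    spl <- split(tx, tx$gene_id)
    g <- unlist(range(spl))
    g$gene_id <- names(g)
    names(g) <- NULL
  }
  g$symbol <- if (!is.null(g$gene_name)) g$gene_name else g$gene_id
  keep <- c("gene_id", "symbol")
  mcols(g) <- mcols(g)[, keep]
  gene_models(g, tss)
}

#' Pairwise interval overlap test
#'
#' TRUE iff the two intervals share at least one base pair (same chromosome
#' and strictly intersecting ranges). Vectorised over pairs.
#'
#' @param a,b `GRanges` of equal length (or length 1, recycled).
#' @return Logical vector.
#' @export
interval_overlaps <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep(a, length.out = n)
  b <- rep(b, length.out = n)
  as.character(seqnames(a)) == as.character(seqnames(b)) &
    start(a) <= end(b) & start(b) <= end(a)
}

#' Feature midpoints
#'
#' The midpoint used throughout for gene assignment and TSS distances:
#' `floor((start0 + end0) / 2)` in 0-based coordinates, returned 1-based.
#'
#' @param gr A `GRanges`.
#' @return Integer vector of 1-based midpoint positions.
#' @export
interval_midpoint <- function(gr) {
  as.integer(floor(((start(gr) - 1L) + end(gr)) / 2)) + 1L
}

#' Nearest TSS of a set of points
#'
#' For each point, finds the gene whose closest transcription start site
#' minimises the absolute distance, searching only the point's own chromosome.
#' The signed distance follows the transcription direction of the winning
#' gene: negative upstream of the TSS, positive downstream. Ties on absolute
#' distance are broken by lexicographically smaller `gene_id`.
#'
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of 1-based positions.
#' @param genes A [gene_models()] object.
#' @return data.frame with columns `gene_id` (NA when the chromosome carries
#'   no gene), `distance` (signed bp), `abs_distance`.
#' @export
nearest_tss <- function(chrom, pos, genes) {
  stopifnot(length(chrom) == length(pos))
  if (nrow(genes$tss) == 0L) stop("empty gene set")
  tss <- genes$tss
  out_gene <- rep(NA_character_, length(pos))
  out_dist <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    pts <- which(chrom == ch)
    t_ch <- tss[tss$chrom == ch, , drop = FALSE]
    if (nrow(t_ch) == 0L) next
    ord <- order(t_ch$pos, t_ch$gene_id)
    t_ch <- t_ch[ord, , drop = FALSE]
    idx <- findInterval(pos[pts], t_ch$pos)
    for (k in seq_along(pts)) {
      i <- idx[k]
      p <- pos[pts[k]]
      cand <- unique(pmax(1L, pmin(nrow(t_ch), c(i - 1L, i, i + 1L, i + 2L))))
      d_abs <- abs(t_ch$pos[cand] - p)
      best_abs <- min(d_abs)
      # all TSS at the winning distance (possibly on both sides), then the
      # lexicographically smallest gene_id among them
      at_best <- which(abs(t_ch$pos - p) == best_abs)
      g <- t_ch[at_best, , drop = FALSE]
      g <- g[order(g$gene_id, g$pos), , drop = FALSE][1L, ]
      signed <- if (g$strand == "-") g$pos - p else p - g$pos
      out_gene[pts[k]] <- g$gene_id
      out_dist[pts[k]] <- signed
    }
  }
  data.frame(gene_id = out_gene, distance = out_dist,
             abs_distance = abs(out_dist), stringsAsFactors = FALSE)
}

#' Central window of a site
#'
#' The fixed-width window centred on the site midpoint (used for transposable
#' element enclosure). In 0-based terms the window is
#' `[mid - width/2, mid + width/2)` with `mid = floor((start0 + end0)/2)`.
#' Windows running past position 0 or the chromosome end are clamped with a
#' warning.
#'
#' @param gr A `GRanges`.
#' @param width Even window width in bp (default 40).
#' @param chrom_sizes Optional named vector of chromosome lengths for clamping
#'   at the right edge.
#' @return A `GRanges` of windows, metadata preserved.
#' @export
central_window <- function(gr, width = 40L, chrom_sizes = NULL) {
  stopifnot(width >= 2L, width %% 2L == 0L)
  mid0 <- as.integer(floor(((start(gr) - 1L) + end(gr)) / 2))
  s <- mid0 - width %/% 2L + 1L
  e <- mid0 + width %/% 2L
  clamped <- FALSE
  if (any(s < 1L)) {
    s <- pmax(s, 1L)
    clamped <- TRUE
  }
  if (!is.null(chrom_sizes)) {
    lim <- unname(chrom_sizes[as.character(seqnames(gr))])
    over <- !is.na(lim) & e > lim
    if (any(over)) {
      e[over] <- as.integer(lim[over])
      clamped <- TRUE
    }
  }
  if (clamped) warning("central_window clamped at chromosome bounds")
  out <- GRanges(seqnames(gr), IRanges(s, e), strand = strand(gr))
  mcols(out) <- mcols(gr)
  out
}

#' Read a TSV table with a header row, skipping comment lines
#'
#' @param path Path to the table.
#' @return data.frame.
#' @export
read_tsv_table <- function(path) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a TSV table with a header row
#'
#' @param df data.frame.
#' @param path Output path.
#' @param comment Optional character vector of comment lines (written with a
#'   leading `#`, used to record the generating seed).
#' @export
write_tsv_table <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
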