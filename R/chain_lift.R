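# UCSC chain parsing and interval lifting with single-spanning-range
# semantics: an interval's image is the single range from the smallest to the
# largest aligned base image on the other genome.

#' Read a UCSC chain file
#'
#' Parses chain headers ("chain score tName tSize tStrand tStart tEnd qName
#' qSize qStrand qStart qEnd id") and their alignment block lines
#' (size, dt, dq). Coordinates are kept in chain convention: 0-based half-open,
#' with minus-strand query coordinates on the reverse-complemented sequence.
#'
#' @param path Path to a chain file.
#' @return A list of class `chain_set`; each element has the header fields and
#'   a `blocks` data.frame with columns `size`, `dt`, `dq`.
#' @export
read_chain <- function(path) {
  lines <- readLines(path)
  hdr_idx <- grep("^chain\\b", lines)
  if (length(hdr_idx) == 0L) stop("no chain records in ", path)
  bounds <- c(hdr_idx, length(lines) + 1L)
  chains <- vector("list", length(hdr_idx))
  for (k in seq_along(hdr_idx)) {
    h <- strsplit(trimws(lines[hdr_idx[k]]), "\\s+")[[1L]]
    if (length(h) < 12L) stop("malformed chain header at line ", hdr_idx[k])
    body <- lines[seq(hdr_idx[k] + 1L, bounds[k + 1L] - 1L)]
    body <- body[nzchar(trimws(body))]
    bl <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), function(x) {
      c(as.numeric(x[1L]),
        if (length(x) >= 3L) as.numeric(x[2L:3L]) else c(0, 0))
    }))
    blocks <- data.frame(size = bl[, 1L], dt = bl[, 2L], dq = bl[, 3L])
    ch <- list(
      score = as.numeric(h[2L]),
      t_name = h[3L], t_size = as.numeric(h[4L]), t_strand = h[5L],
      t_start = as.numeric(h[6L]), t_end = as.numeric(h[7L]),
      q_name = h[8L], q_size = as.numeric(h[9L]), q_strand = h[10L],
      q_start = as.numeric(h[11L]), q_end = as.numeric(h[12L]),
      id = if (length(h) >= 13L) h[13L] else as.character(k),
      blocks = blocks
    )
    validate_chain(ch)
    chains[[k]] <- ch
  }
  structure(chains, class = "chain_set")
}

validate_chain <- function(ch) {
  b <- ch$blocks
  if (b$dt[nrow(b)] != 0 || b$dq[nrow(b)] != 0) {
    stop("chain ", ch$id, ": last block must have no gaps")
  }
  if (sum(b$size) + sum(b$dt) != ch$t_end - ch$t_start) {
    stop("chain ", ch$id, ": target extent inconsistent with blocks")
  }
  if (sum(b$size) + sum(b$dq) != ch$q_end - ch$q_start) {
    stop("chain ", ch$id, ": query extent inconsistent with blocks")
  }
  invisible(ch)
}

#' Write a chain set to a UCSC chain file
#'
#' @param chains A `chain_set` (see [read_chain()]).
#' @param path Output path.
#' @export
write_chain <- function(chains, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in chains) {
    writeLines(paste("chain", format(ch$score, scientific = FALSE), ch$t_name,
                     format(ch$t_size, scientific = FALSE), ch$t_strand,
                     format(ch$t_start, scientific = FALSE),
                     format(ch$t_end, scientific = FALSE), ch$q_name,
                     format(ch$q_size, scientific = FALSE), ch$q_strand,
                     format(ch$q_start, scientific = FALSE),
                     format(ch$q_end, scientific = FALSE), ch$id), con)
    b <- ch$blocks
    n <- nrow(b)
    if (n > 1L) {
      writeLines(paste(b$size[-n], b$dt[-n], b$dq[-n]), con)
    }
    writeLines(format(b$size[n], scientific = FALSE), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Invert a chain set
#'
#' Produces the exact inverse mapping (query becomes target). For
#' minus-strand chains, blocks are reversed and coordinates re-expressed so
#' the new target is on the forward strand, as chain convention requires.
#'
#' @param chains A `chain_set`.
#' @return A `chain_set` mapping in the opposite direction.
#' @export
chain_invert <- function(chains) {
  inv <- lapply(chains, function(ch) {
    b <- ch$blocks
    n <- nrow(b)
    if (ch$q_strand == "+") {
      out <- list(score = ch$score,
                  t_name = ch$q_name, t_size = ch$q_size, t_strand = "+",
                  t_start = ch$q_start, t_end = ch$q_end,
                  q_name = ch$t_name, q_size = ch$t_size, q_strand = "+",
                  q_start = ch$t_start, q_end = ch$t_end,
                  id = ch$id,
                  blocks = data.frame(size = b$size, dt = b$dq, dq = b$dt))
    } else {
      sizes <- rev(b$size)
      dt_new <- c(rev(b$dq[-n]), 0)
      dq_new <- c(rev(b$dt[-n]), 0)
      out <- list(score = ch$score,
                  t_name = ch$q_name, t_size = ch$q_size, t_strand = "+",
                  t_start = ch$q_size - ch$q_end,
                  t_end = ch$q_size - ch$q_start,
                  q_name = ch$t_name, q_size = ch$t_size, q_strand = "-",
                  q_start = ch$t_size - ch$t_end,
                  q_end = ch$t_size - ch$t_start,
                  id = ch$id,
                  blocks = data.frame(size = sizes, dt = dt_new, dq = dq_new))
    }
    validate_chain(out)
    out
  })
  structure(inv, class = "chain_set")
}

# Cumulative block coordinates of a chain: target starts, query (chain-space)
# starts, per block.
chain_block_coords <- function(ch) {
  b <- ch$blocks
  t_starts <- ch$t_start + c(0, cumsum(b$size + b$dt))[seq_len(nrow(b))]
  q_starts <- ch$q_start + c(0, cumsum(b$size + b$dq))[seq_len(nrow(b))]
  list(t_starts = t_starts, q_starts = q_starts, sizes = b$size)
}

lift_one <- function(chrom, s0, e0, chains) {
  cand <- Filter(function(ch) {
    ch$t_name == chrom && ch$t_start < e0 && s0 < ch$t_end
  }, chains)
  none <- list(status = "unmapped", chrom = NA_character_,
               start = NA_integer_, end = NA_integer_,
               strand = NA_character_, mapped_fraction = 0)
  if (length(cand) == 0L) return(none)
  # best-chain rule: highest score, ties by chain id
  scores <- vapply(cand, `[[`, numeric(1), "score")
  ids <- vapply(cand, `[[`, character(1), "id")
  ch <- cand[[order(-scores, ids)[1L]]]
  bc <- chain_block_coords(ch)
  lo <- pmax(s0, bc$t_starts)
  hi <- pmin(e0, bc$t_starts + bc$sizes)
  hit <- which(lo < hi)
  if (length(hit) == 0L) return(none)
  aligned <- sum(hi[hit] - lo[hit])
  q_lo <- bc$q_starts[hit] + (lo[hit] - bc$t_starts[hit])
  q_hi <- q_lo + (hi[hit] - lo[hit])            # half-open in chain space
  q_min <- min(q_lo)
  q_max <- max(q_hi) - 1                        # last aligned base image
  if (ch$q_strand == "-") {
    fwd_min <- ch$q_size - q_max - 1
    fwd_max <- ch$q_size - q_min - 1
  } else {
    fwd_min <- q_min
    fwd_max <- q_max
  }
  list(status = "mapped", chrom = ch$q_name,
       start = as.integer(fwd_min + 1), end = as.integer(fwd_max + 1),
       strand = ch$q_strand,
       mapped_fraction = aligned / (e0 - s0))
}

#' Lift intervals through a chain set
#'
#' Maps each interval to the other genome. When several chains overlap the
#' source interval the highest-scoring chain is used alone (ties broken by
#' chain id), mirroring liftOver's best-chain behaviour. The image is the
#' single spanning range from the smallest to the largest aligned base image,
#' on forward-strand coordinates. An interval with no aligned base is
#' `unmapped`.
#'
#' @param gr Source intervals (`GRanges`, 1-based closed).
#' @param chains A `chain_set` indexed on the source genome.
#' @param pad Padding in bp added to both sides before lifting (the
#'   conservation analysis uses 1000); the padded interval is clamped at
#'   chromosome bounds when `chrom_sizes` is given.
#' @param chrom_sizes Optional named vector of source chromosome lengths.
#' @return data.frame with columns `status` (mapped/unmapped), `chrom`,
#'   `start`, `end` (1-based closed image), `strand`, `mapped_fraction`.
#' @export
lift_intervals <- function(gr, chains, pad = 0L, chrom_sizes = NULL) {
  stopifnot(pad >= 0L)
  s0 <- start(gr) - 1L - pad
  e0 <- end(gr) + pad
  if (any(s0 < 0L)) {
    s0 <- pmax(s0, 0L)
    warning("padded interval clamped at chromosome start")
  }
  if (!is.null(chrom_sizes)) {
    lim <- unname(chrom_sizes[as.character(seqnames(gr))])
    over <- !is.na(lim) & e0 > lim
    if (any(over)) {
      e0[over] <- lim[over]
      warning("padded interval clamped at chromosome end")
    }
  }
  chroms <- as.character(seqnames(gr))
  rows <- lapply(seq_along(gr), function(i) {
    lift_one(chroms[i], s0[i], e0[i], chains)
  })
  out <- do.call(rbind, lapply(rows, as.data.frame))
  rownames(out) <- NULL
  out
}

#' Lifted images as GRanges
#'
#' Helper turning the mapped rows of a [lift_intervals()] result into a
#' `GRanges` (unmapped rows are dropped; `source_index` records the original
#' row).
#'
#' @param lift data.frame from [lift_intervals()].
#' @return `GRanges` with a `source_index` metadata column.
#' @export
lift_as_granges <- function(lift) {
  ok <- which(lift$status == "mapped")
  if (length(ok) == 0L) {
    gr <- GRanges()
    gr$source_index <- integer(0)
    return(gr)
  }
  gr <- GRanges(lift$chrom[ok], IRanges(lift$start[ok], lift$end[ok]),
                strand = lift$strand[ok])
  gr$source_index <- ok
  gr
}
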