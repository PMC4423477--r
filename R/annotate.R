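# Homology annotation of sequence segments against a TE library, built on
# the package's affine-gap local aligner with k-mer seeding for large
# targets.

# low-level wrapper around the C++ DP; band = c(dlo, dhi) on diagonals
.swLocal <- function(a, b, match = 5, mismatch = -4, gap_open = 30,
                     gap_ext = 0.1, band = NULL) {
  if (is.null(band)) band <- c(NA_integer_, NA_integer_)
  r <- cpp_sw_affine(a, b, match, mismatch, gap_open, gap_ext,
                     as.integer(band[1L]), as.integer(band[2L]))
  r$columns <- nchar(r$a_row)
  r$identity <- if (r$columns) .alnIdentity(r$a_row, r$b_row) else 0
  r
}

# seed-derived diagonal band for a window pair; NULL if too few seeds
.bandFromSeeds <- function(q, t, k = 14L, margin = 300L, min_seeds = 5L) {
  h <- cpp_seed_hits(q, t, k = k)
  if (nrow(h) < min_seeds) return(NULL)
  o <- order(h[, "qpos"], h[, "tpos"])
  chain <- .lisIndices(h[o, "tpos"])
  if (length(chain) < min_seeds) return(NULL)
  d <- h[o, "tpos"][chain] - h[o, "qpos"][chain]
  c(min(d) - margin, max(d) + margin + k)
}

# all local hits of `query` in `genome` (one long string), both strands.
# Seeds (k-mers) are clustered into candidate loci; each locus is refined
# with a banded DP. Returns data.frame with 1-based genome coordinates.
.searchGenome <- function(query, genome, k = 12L, min_len = 50L,
                          min_identity = 0.7, max_occ = 200L) {
  res <- list()
  qn <- nchar(query)
  for (strand in c("+", "-")) {
    q <- if (strand == "+") query else .revcomp(query)
    h <- cpp_seed_hits(q, genome, k = k, max_occ = max_occ)
    if (!nrow(h)) next
    o <- order(h[, "tpos"])
    tp <- h[o, "tpos"]; qp <- h[o, "qpos"]
    brk <- c(0L, which(diff(tp) > qn + 100L), length(tp))
    for (ci in seq_len(length(brk) - 1L)) {
      sel <- (brk[ci] + 1L):brk[ci + 1L]
      tlo <- max(1L, min(tp[sel]) - min(qp[sel]) - 50L)
      thi <- min(nchar(genome), max(tp[sel]) + (qn - min(qp[sel])) + 50L + k)
      sub <- substr(genome, tlo, thi)
      d <- (tp[sel] - tlo + 1L) - qp[sel]
      r <- .swLocal(q, sub, band = c(min(d) - 100L, max(d) + 100L + k))
      if (r$columns >= min_len && r$identity >= min_identity) {
        res[[length(res) + 1L]] <- data.frame(
          tstart = tlo + r$b_start - 1L, tend = tlo + r$b_end - 1L,
          qstart = r$a_start, qend = r$a_end, strand = strand,
          identity = r$identity, columns = r$columns, score = r$score)
      }
    }
  }
  if (!length(res))
    return(data.frame(tstart = integer(0), tend = integer(0),
                      qstart = integer(0), qend = integer(0),
                      strand = character(0), identity = numeric(0),
                      columns = integer(0), score = numeric(0)))
  out <- do.call(rbind, res)
  # collapse duplicate loci found on both strands: keep best per interval
  out <- out[order(-out$score), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    if (i < nrow(out)) for (j in (i + 1L):nrow(out)) {
      ov <- min(out$tend[i], out$tend[j]) - max(out$tstart[i], out$tstart[j]) + 1L
      if (keep[j] && ov > 0.5 * (out$tend[j] - out$tstart[j] + 1L))
        keep[j] <- FALSE
    }
  }
  out[keep, , drop = FALSE]
}

# repeated local hits of one consensus inside one segment (both given as
# strings); masks each hit and realigns, so multiple copies are reported
.localHits <- function(segment, consensus, min_len, min_identity,
                       max_rounds = 8L) {
  hits <- list()
  seg <- segment
  for (round in seq_len(max_rounds)) {
    r <- .swLocal(seg, consensus)
    if (r$columns < 1L || r$score <= 0) break
    if (r$columns >= min_len && r$identity >= min_identity)
      hits[[length(hits) + 1L]] <-
        list(start = r$a_start, end = r$a_end, columns = r$columns,
             identity = r$identity, score = r$score,
             cstart = r$b_start, cend = r$b_end)
    else break
    substr(seg, r$a_start, r$a_end) <-
      strrep("N", r$a_end - r$a_start + 1L)
  }
  hits
}

#' Annotate a sequence segment against a TE library
#'
#' Reports all local similarity hits between \code{segment} and the family
#' consensus sequences meeting the admission thresholds (alignment length of
#' at least \code{min_len} columns and identity of at least
#' \code{min_identity}, computed as matches over alignment columns including
#' gap columns). Hits to the same family overlapping by more than 50\% are
#' merged, keeping the union interval and the maximum identity. Both strands
#' are searched.
#'
#' @param segment nucleotide string.
#' @param library a \linkS4class{TELibrary}.
#' @param min_len minimum alignment size in columns (default 50 bp).
#' @param min_identity minimum identity fraction (default 0.70).
#' @return \code{data.frame} with columns \code{family}, \code{superfamily},
#'   \code{start}, \code{end} (1-based in the segment), \code{length},
#'   \code{identity}, \code{strand}, \code{score}, best identity first.
#' @export
annotateSegment <- function(segment, library, min_len = 50L,
                            min_identity = 0.70) {
  stopifnot(nzchar(segment), min_identity > 0, min_identity <= 1,
            min_len >= 1)
  empty <- data.frame(family = character(0), superfamily = character(0),
                      start = integer(0), end = integer(0),
                      length = integer(0), identity = numeric(0),
                      strand = character(0), score = numeric(0),
                      full_start = integer(0), full_end = integer(0))
  if (!grepl("[ACGTacgt]", segment)) return(empty)
  rows <- list()
  info <- library@info
  cons <- as.character(library@consensus)
  for (i in seq_along(cons)) {
    for (strand in c("+", "-")) {
      cseq <- if (strand == "+") cons[i] else .revcomp(cons[i])
      for (h in .localHits(segment, cseq, min_len, min_identity)) {
        # full-length element borders inferred from the consensus
        # coordinates of the hit (terminal bases can be clipped by the
        # local alignment or by gap-placement ambiguity in the event)
        clen <- nchar(cseq)
        miss5 <- if (strand == "+") h$cstart - 1L else clen - h$cend
        miss3 <- if (strand == "+") clen - h$cend else h$cstart - 1L
        rows[[length(rows) + 1L]] <- data.frame(
          family = info$family[i], superfamily = info$superfamily[i],
          start = h$start, end = h$end, length = h$columns,
          identity = h$identity, strand = strand, score = h$score,
          full_start = h$start - miss5, full_end = h$end + miss3)
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  # merge >50% overlapping hits to the same family
  out <- out[order(out$family, out$start), , drop = FALSE]
  merged <- list()
  for (fam in unique(out$family)) {
    f <- out[out$family == fam, , drop = FALSE]
    i <- 1L
    while (i <= nrow(f)) {
      cur <- f[i, , drop = FALSE]
      j <- i + 1L
      while (j <= nrow(f)) {
        ov <- min(cur$end, f$end[j]) - max(cur$start, f$start[j]) + 1L
        shorter <- min(cur$end - cur$start, f$end[j] - f$start[j]) + 1L
        if (ov > 0.5 * shorter) {
          cur$start <- min(cur$start, f$start[j])
          cur$end <- max(cur$end, f$end[j])
          cur$identity <- max(cur$identity, f$identity[j])
          cur$score <- max(cur$score, f$score[j])
          cur$length <- max(cur$length, f$length[j])
          cur$full_start <- min(cur$full_start, f$full_start[j])
          cur$full_end <- max(cur$full_end, f$full_end[j])
          f <- f[-j, , drop = FALSE]
        } else j <- j + 1L
      }
      merged[[length(merged) + 1L]] <- cur
      i <- i + 1L
    }
  }
  out <- do.call(rbind, merged)
  out <- out[order(-out$identity, -out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}
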