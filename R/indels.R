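# Extraction of presence/absence polymorphisms (> 50 bp indels) from
# assembled chromosome alignments, with the merge, gap-adjacency and
# N-content filter rules.

.emptyEvents <- function() {
  S4Vectors::DataFrame(
    event_id = integer(0), block = integer(0),
    col_start = integer(0), col_end = integer(0),
    bearing = character(0), bear_start = integer(0), bear_end = integer(0),
    empty_pos = integer(0), length = integer(0),
    extra = character(0), n_fraction = numeric(0),
    flank_quality = logical(0),
    bctx0 = integer(0), bctx1 = integer(0),
    ectx0 = integer(0), ectx1 = integer(0),
    bear_up = character(0), bear_down = character(0),
    empty_up = character(0), empty_down = character(0))
}

#' Scan a chromosome alignment for indels larger than a threshold
#'
#' Every maximal gap run longer than \code{min_len} in either row becomes a
#' presence/absence event attributed to the gap-free (sequence-bearing)
#' species. Each event carries flanking genomic context, a flank-quality
#' flag (embedded between \code{quality_flank_bp} contiguous aligned
#' columns with more than \code{quality_identity} matches on both sides)
#' and homologous context anchors used downstream for footprint
#' measurement.
#'
#' @param ca a \linkS4class{ChromosomeAlignment}.
#' @param query_seq,target_seq the two chromosome sequences (strings).
#' @param min_len events must be strictly longer than this (default 50).
#' @param flank_bp genomic flank stored per event (default 500).
#' @param ctx_bp homologous context anchor distance (default 300 aligned
#'   columns beyond the event).
#' @param quality_flank_bp,quality_identity flank-quality rule parameters.
#' @return \code{DataFrame} of events (columns include \code{bearing}
#'   "query"/"target", coordinates in both genomes, \code{extra},
#'   \code{n_fraction}, \code{flank_quality}).
#' @export
scanIndels <- function(ca, query_seq, target_seq, min_len = 50L,
                       flank_bp = 500L, ctx_bp = 300L,
                       quality_flank_bp = 200L, quality_identity = 0.90) {
  blocks <- .fuseContiguousBlocks(ca@blocks)
  rows <- list()
  eid <- 0L
  for (bi in seq_len(nrow(blocks))) {
    b <- blocks[bi, ]
    qv <- .chars(b$qrow); tv <- .chars(b$trow)
    qpos <- b$qstart - 1L + cumsum(qv != "-")
    tpos <- b$tstart - 1L + cumsum(tv != "-")
    gapq <- qv == "-"; gapt <- tv == "-"
    anycol <- gapq | gapt
    mat <- qv == tv & !anycol & qv %in% DNA_BASES4
    for (side in c("query", "target")) {
      gaps <- if (side == "query") .runsOf(ifelse(gapt, "G", "M"), "G")
      else .runsOf(ifelse(gapq, "G", "M"), "G")
      if (!nrow(gaps)) next
      othergap <- if (side == "query") gapq else gapt
      gaps <- .fuseSplitRuns(gaps, mat, othergap)
      gaps <- gaps[gaps$length > min_len, , drop = FALSE]
      for (gi in seq_len(nrow(gaps))) {
        c1 <- gaps$start[gi]; c2 <- gaps$end[gi]
        eid <- eid + 1L
        if (side == "query") {
          bs <- qpos[c1]; be <- qpos[c2]
          ep <- if (c1 > 1L) tpos[c1 - 1L] else b$tstart - 1L
          bseq <- query_seq; eseq <- target_seq
        } else {
          bs <- tpos[c1]; be <- tpos[c2]
          ep <- if (c1 > 1L) qpos[c1 - 1L] else b$qstart - 1L
          bseq <- target_seq; eseq <- query_seq
        }
        # flank quality: contiguous aligned columns adjacent to the run
        own <- if (side == "query") gapt else gapq
        oth <- if (side == "query") gapq else gapt
        lq <- .flankQualityOK(anycol, mat, c1, c2, quality_flank_bp,
                              quality_identity, own_gap = own,
                              other_gap = oth)
        # homologous context anchors: nearest fully aligned column at
        # least ctx_bp columns away on each side (fall back to block edge)
        a1 <- .ctxColumn(anycol, c1, -ctx_bp)
        a2 <- .ctxColumn(anycol, c2, +ctx_bp)
        if (side == "query") {
          bctx0 <- if (is.na(a1)) b$qstart else qpos[a1]
          bctx1 <- if (is.na(a2)) b$qend else qpos[a2]
          ectx0 <- if (is.na(a1)) b$tstart else tpos[a1]
          ectx1 <- if (is.na(a2)) b$tend else tpos[a2]
        } else {
          bctx0 <- if (is.na(a1)) b$tstart else tpos[a1]
          bctx1 <- if (is.na(a2)) b$tend else tpos[a2]
          ectx0 <- if (is.na(a1)) b$qstart else qpos[a1]
          ectx1 <- if (is.na(a2)) b$qend else qpos[a2]
        }
        extra <- substr(bseq, bs, be)
        rows[[length(rows) + 1L]] <- S4Vectors::DataFrame(
          event_id = eid, block = bi, col_start = c1, col_end = c2,
          bearing = side, bear_start = bs, bear_end = be,
          empty_pos = ep, length = be - bs + 1L, extra = extra,
          n_fraction = .nFraction(extra), flank_quality = lq,
          bctx0 = bctx0, bctx1 = bctx1, ectx0 = ectx0, ectx1 = ectx1,
          bear_up = substr(bseq, max(1L, bs - flank_bp), bs - 1L),
          bear_down = substr(bseq, be + 1L,
                             min(nchar(bseq), be + flank_bp)),
          empty_up = substr(eseq, max(1L, ep - flank_bp + 1L), ep),
          empty_down = substr(eseq, ep + 1L,
                              min(nchar(eseq), ep + flank_bp)))
      }
    }
  }
  if (!length(rows)) return(.emptyEvents())
  out <- do.call(rbind, rows)
  out[order(out$block, out$col_start), ]
}

# With a low gap-extension penalty, one long gap can be spuriously split in
# two when a few bases of the opposing sequence (e.g. filler DNA) happen to
# half-align against the gap interior: splitting costs only one extra gap
# opening. Gap runs separated by a short spacer that is not confidently
# aligned (poor match fraction, or containing opposite-direction gap
# columns) are therefore fused back into one run before event extraction.
.fuseSplitRuns <- function(runs, mat, othergap, max_spacer = 150L,
                           max_match = 0.9) {
  if (nrow(runs) < 2L) return(runs)
  out <- runs[1L, , drop = FALSE]
  for (i in 2L:nrow(runs)) {
    r <- runs[i, ]
    sep <- r$start - out$end[nrow(out)] - 1L
    fuse <- FALSE
    if (sep >= 1L && sep <= max_spacer) {
      sel <- (out$end[nrow(out)] + 1L):(r$start - 1L)
      aligned <- sel[!othergap[sel]]
      frac <- if (length(aligned)) mean(mat[aligned]) else 0
      fuse <- frac < max_match || any(othergap[sel])
    }
    if (fuse) {
      out$end[nrow(out)] <- r$end
      out$length[nrow(out)] <- out$end[nrow(out)] - out$start[nrow(out)] + 1L
    } else {
      out <- rbind(out, r)
    }
  }
  out
}

# blocks that abut exactly in both genomes are seams from window assembly,
# not alignment breaks; fuse them so events near seams keep their flanks
.fuseContiguousBlocks <- function(blocks) {
  if (nrow(blocks) < 2L) return(blocks)
  out <- list()
  cur <- blocks[1L, ]
  for (i in 2L:nrow(blocks)) {
    b <- blocks[i, ]
    if (b$qstart == cur$qend + 1L && b$tstart == cur$tend + 1L) {
      cur$qend <- b$qend
      cur$tend <- b$tend
      cur$qrow <- paste0(cur$qrow, b$qrow)
      cur$trow <- paste0(cur$trow, b$trow)
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- b
    }
  }
  out[[length(out) + 1L]] <- cur
  do.call(rbind, out)
}

.nFraction <- function(x) {
  if (!nzchar(x)) return(0)
  ch <- .chars(x)
  mean(!(ch %in% DNA_BASES4))
}

# Walk outward from a gap-run edge collecting aligned columns; small gap
# runs are skipped without breaking the flank, large ones end it. Gap runs
# in the event's own direction break at the indel-event threshold
# (another candidate indel); opposite-direction runs break only above the
# filler-size scale (an excision's filler sits right next to its gap and
# must not disqualify the event). The flank passes when flank_bp aligned
# columns are collected with a match fraction strictly above min_identity.
.flankSideOK <- function(anycol, mat, edge, step, flank_bp, min_identity,
                         small_gap_max = 50L, own_gap = NULL,
                         other_gap = NULL, other_gap_max = 150L) {
  n <- length(anycol)
  i <- edge + step
  collected <- 0L
  matched <- 0L
  while (i >= 1L && i <= n && collected < flank_bp) {
    if (anycol[i]) {
      run <- 0L
      own <- 0L
      while (i >= 1L && i <= n && anycol[i]) {
        run <- run + 1L
        if (!is.null(own_gap) && own_gap[i]) own <- own + 1L
        i <- i + step
      }
      lim <- if (is.null(own_gap)) small_gap_max
      else if (own > 0L) small_gap_max else other_gap_max
      if (run > lim) break
    } else {
      collected <- collected + 1L
      matched <- matched + mat[i]
      i <- i + step
    }
  }
  collected >= flank_bp && matched / collected > min_identity
}

.flankQualityOK <- function(anycol, mat, c1, c2, flank_bp, min_identity,
                            own_gap = NULL, other_gap = NULL) {
  .flankSideOK(anycol, mat, c1, -1L, flank_bp, min_identity,
               own_gap = own_gap, other_gap = other_gap) &&
    .flankSideOK(anycol, mat, c2, +1L, flank_bp, min_identity,
                 own_gap = own_gap, other_gap = other_gap)
}

# nearest fully aligned column at distance >= |offset| from the run edge
.ctxColumn <- function(anycol, edge, offset) {
  n <- length(anycol)
  if (offset < 0) {
    i <- edge + offset
    while (i >= 1L && anycol[i]) i <- i - 1L
    if (i < 1L) NA_integer_ else i
  } else {
    i <- edge + offset
    while (i <= n && anycol[i]) i <- i + 1L
    if (i > n) NA_integer_ else i
  }
}

#' Merge adjacent indel events
#'
#' Chains of same-direction events separated by fewer than
#' \code{max_separation} aligned columns are fused into one event spanning
#' the union; the fused extra sequence includes the intervening spacer
#' bases of the bearing genome. Events of opposite bearing species are
#' never merged. The operation is idempotent.
#'
#' @param events \code{DataFrame} from \code{\link{scanIndels}}.
#' @param query_seq,target_seq chromosome sequences (for the fused extra
#'   sequence).
#' @param max_separation strict upper bound on the aligned-column
#'   separation (default 4).
#' @return merged \code{DataFrame}.
#' @export
mergeAdjacentIndels <- function(events, query_seq, target_seq,
                                max_separation = 4L) {
  if (nrow(events) < 2L) return(events)
  events <- events[order(events$block, events$col_start), ]
  out <- list()
  cur <- events[1L, ]
  for (i in 2L:nrow(events)) {
    e <- events[i, ]
    sep <- e$col_start - cur$col_end - 1L
    if (e$block == cur$block && e$bearing == cur$bearing &&
        sep < max_separation && sep >= 0L) {
      bseq <- if (cur$bearing == "query") query_seq else target_seq
      cur$col_end <- e$col_end
      cur$bear_end <- e$bear_end
      cur$extra <- substr(bseq, cur$bear_start, cur$bear_end)
      cur$length <- cur$bear_end - cur$bear_start + 1L
      cur$n_fraction <- .nFraction(cur$extra)
      cur$flank_quality <- cur$flank_quality && e$flank_quality
      cur$bctx1 <- e$bctx1
      cur$ectx1 <- e$ectx1
      cur$bear_down <- e$bear_down
      cur$empty_down <- e$empty_down
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- e
    }
  }
  out[[length(out) + 1L]] <- cur
  res <- do.call(rbind, out)
  res$event_id <- seq_len(nrow(res))
  res
}

#' Discard events bordering assembly gaps (N runs)
#'
#' Events whose extra sequence contains Ns, or whose immediate flanks
#' (within \code{window} bp in either genome) touch an N run, are removed.
#' Removed events are retained in a side channel for the hidden-TE
#' extrapolation.
#'
#' @param events \code{DataFrame} of indel events.
#' @param window adjacency distance in bp (default 10).
#' @return list with \code{kept} and \code{dropped}.
#' @export
dropGapAdjacent <- function(events, window = 10L) {
  if (!nrow(events))
    return(list(kept = events, dropped = events))
  touches <- vapply(seq_len(nrow(events)), function(i) {
    e <- events[i, ]
    hasN <- function(s) grepl("N", s, fixed = TRUE)
    near <- function(up, down) {
      u <- substr(up, max(1L, nchar(up) - window + 1L), nchar(up))
      d <- substr(down, 1L, window)
      hasN(u) || hasN(d)
    }
    hasN(e$extra) || near(e$bear_up, e$bear_down) ||
      near(e$empty_up, e$empty_down)
  }, logical(1))
  list(kept = events[!touches, ], dropped = events[touches, ])
}

#' Flag events composed mostly of Ns
#'
#' TRUE when the event's N fraction strictly exceeds \code{threshold};
#' such events are excluded from classification but counted for the
#' hidden-TE extrapolation.
#'
#' @param events \code{DataFrame} of indel events (or a single event row).
#' @param threshold N-content threshold (default 0.80, strict).
#' @return logical vector.
#' @export
classifyNContent <- function(events, threshold = 0.80) {
  events$n_fraction > threshold
}
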