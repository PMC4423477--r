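# Whole-genome anchoring by 5-kb fragments, 12-kb window alignment with
# affine gap penalties, per-window quality filtering, and per-chromosome
# assembly of the window alignments.

#' Anchor query fragments on a target genome
#'
#' Splits each query chromosome into \code{fragment_bp} fragments (the short
#' tail fragment is kept) and locates each fragment's best target hit by
#' k-mer seed voting followed by a banded local alignment. Anchors are
#' dropped unless the best hit is on the majority chromosome, in forward
#' orientation, with identity of at least \code{min_identity}. Identity is
#' computed per matched segment (alignment-gap runs longer than 50 bp are
#' excluded from the columns), so a large insertion inside a fragment does
#' not destroy its anchor. Fragments violating collinearity (not on the
#' longest strictly increasing target chain) are unanchored.
#'
#' @param query,target \code{DNAStringSet} genomes.
#' @param fragment_bp fragment grid size (default 5000).
#' @param min_identity anchoring identity threshold (default 0.96).
#' @param k seed length for candidate location.
#' @return \code{data.frame} with one row per fragment: \code{qchrom},
#'   \code{qstart}, \code{qend}, \code{tchrom}, \code{tpos} (target
#'   position orthologous to the fragment start), \code{strand},
#'   \code{identity}, \code{anchored}.
#' @export
fragmentAndAnchor <- function(query, target, fragment_bp = 5000L,
                              min_identity = 0.96, k = 14L) {
  query <- Biostrings::DNAStringSet(query)
  target <- Biostrings::DNAStringSet(target)
  tseqs <- as.character(target)
  rows <- list()
  for (qc in seq_along(query)) {
    qseq <- as.character(query[[qc]])
    qlen <- nchar(qseq)
    starts <- seq(1L, qlen, by = fragment_bp)
    frags <- substring(qseq, starts, pmin(starts + fragment_bp - 1L, qlen))
    cand <- lapply(seq_along(tseqs), function(tc)
      cpp_anchor_candidates(frags, tseqs[tc], k = k))
    votes <- vapply(cand, function(m) m[, "votes"], numeric(length(frags)))
    votes <- matrix(votes, nrow = length(frags))
    best_tc <- apply(votes, 1L, which.max)
    # majority chromosome rule: all anchors must agree on one target chrom
    maj <- as.integer(names(which.max(table(best_tc))))
    for (i in seq_along(frags)) {
      row <- data.frame(qchrom = names(query)[qc] %||% as.character(qc),
                        qstart = starts[i],
                        qend = min(starts[i] + fragment_bp - 1L, qlen),
                        tchrom = NA_character_, tpos = NA_integer_,
                        strand = NA_character_, identity = NA_real_,
                        anchored = FALSE, stringsAsFactors = FALSE)
      m <- cand[[maj]][i, ]
      if (best_tc[i] == maj && m["strand"] == 1L && m["votes"] >= 5L) {
        tlen <- nchar(tseqs[maj])
        slo <- max(1L, m[["tlo"]] - m[["qlo"]] - 200L)
        shi <- min(tlen, m[["thi"]] + (nchar(frags[i]) - m[["qhi"]]) + 200L)
        slice <- substr(tseqs[maj], slo, shi)
        band <- .bandFromSeeds(frags[i], slice, k = k)
        r <- .swLocal(frags[i], slice, band = band)
        if (r$columns > 0L) {
          ident <- .alnIdentity(r$a_row, r$b_row, exclude_gap_runs_over = 50L)
          if (ident >= min_identity) {
            row$tchrom <- names(target)[maj] %||% as.character(maj)
            row$tpos <- slo + r$b_start - 1L - (r$a_start - 1L)
            row$strand <- "+"
            row$identity <- ident
            row$anchored <- TRUE
          }
        }
      } else if (m["strand"] == -1L && m["votes"] >= 5L) {
        row$strand <- "-"   # best hit on the opposite strand: no anchor
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  # collinearity: longest strictly increasing chain of target positions
  anch <- which(out$anchored)
  if (length(anch) > 1L) {
    keep <- anch[.lisIndices(out$tpos[anch])]
    out$anchored[setdiff(anch, keep)] <- FALSE
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Align a pair of 12-kb windows with affine gap penalties
#'
#' Optimal local (Smith-Waterman) alignment under an affine gap model where
#' a gap of length L costs \code{gap_open + gap_ext * L}; the default
#' penalties (30 and 0.1) favour few large gaps over many small ones, so a
#' transposon-sized insertion appears as a single long gap. Ns score as
#' mismatch against everything. With \code{band = "auto"} the DP is
#' restricted to a diagonal band derived from chained k-mer seeds (exact
#' within the band); \code{band = NULL} runs the full quadratic DP.
#'
#' @param query_win,target_win nucleotide strings.
#' @param gap_open,gap_ext,match,mismatch scoring parameters.
#' @param band \code{"auto"}, \code{NULL}, or \code{c(dlo, dhi)} diagonal
#'   limits.
#' @return list with \code{score}, 1-based \code{qstart}/\code{qend}/
#'   \code{tstart}/\code{tend} of the aligned subsequences, gapped rows
#'   \code{qrow}/\code{trow}, and \code{identity} (matches over columns).
#'   An unalignable window (e.g. all Ns) yields score 0 and empty rows.
#' @export
alignWindow <- function(query_win, target_win, gap_open = 30, gap_ext = 0.1,
                        match = 5, mismatch = -4, band = NULL) {
  stopifnot(nzchar(query_win), nzchar(target_win))
  if (identical(band, "auto")) {
    band <- .bandFromSeeds(query_win, target_win)
    if (is.null(band))
      return(list(score = 0, qstart = 0L, qend = -1L, tstart = 0L,
                  tend = -1L, qrow = "", trow = "", identity = 0))
  }
  r <- .swLocal(query_win, target_win, match = match, mismatch = mismatch,
                gap_open = gap_open, gap_ext = gap_ext, band = band)
  list(score = r$score, qstart = r$a_start, qend = r$a_end,
       tstart = r$b_start, tend = r$b_end, qrow = r$a_row, trow = r$b_row,
       identity = r$identity)
}

#' Window alignment quality filter
#'
#' A window alignment passes when every candidate indel region (gap run
#' longer than \code{min_indel}) is embedded between at least
#' \code{flank_bp} aligned columns on both sides containing more than
#' \code{min_flank_identity} perfect matches. Gap runs no longer than
#' \code{min_indel} (below the indel-event threshold, e.g. small background
#' indels) do not interrupt a flank but do not count towards it either.
#' Alignments without candidate indels pass when they contain at least
#' \code{flank_bp} such aligned columns in one stretch.
#'
#' @param wa a window alignment as returned by \code{\link{alignWindow}}.
#' @param flank_bp required aligned flank (default 200).
#' @param min_flank_identity required match fraction in the flank
#'   (default 0.90, strict inequality).
#' @param min_indel gap runs longer than this are candidate indels
#'   (default 50).
#' @return logical flag.
#' @export
passesQuality <- function(wa, flank_bp = 200L, min_flank_identity = 0.90,
                          min_indel = 50L) {
  if (!nzchar(wa$qrow)) return(FALSE)
  qv <- .chars(wa$qrow); tv <- .chars(wa$trow)
  gap <- qv == "-" | tv == "-"
  mat <- qv == tv & !gap & qv %in% DNA_BASES4
  runs <- .runsOf(ifelse(gap, "G", "M"), "G")
  runs <- runs[runs$length > min_indel, , drop = FALSE]
  if (!nrow(runs)) {
    aligned_runs <- .runsOf(ifelse(gap, "G", "M"), "M")
    for (i in seq_len(nrow(aligned_runs))) {
      if (aligned_runs$length[i] >= flank_bp) {
        sel <- aligned_runs$start[i]:aligned_runs$end[i]
        if (mean(mat[sel]) > min_flank_identity) return(TRUE)
      }
    }
    return(FALSE)
  }
  for (i in seq_len(nrow(runs))) {
    if (!.flankSideOK(gap, mat, runs$start[i], -1L, flank_bp,
                      min_flank_identity, min_indel) ||
        !.flankSideOK(gap, mat, runs$end[i], +1L, flank_bp,
                      min_flank_identity, min_indel))
      return(FALSE)
  }
  TRUE
}

# column index of the last column whose query coordinate equals q
# (query coordinates are absolute; block must contain q)
.qposColumn <- function(qv_nogap_cum, qstart, q) {
  # qv_nogap_cum: cumsum of non-gap indicator over columns
  idx <- which(qv_nogap_cum == (q - qstart + 1L))
  if (!length(idx)) return(NA_integer_)
  idx[1L]
}

.trimBlockToQuery <- function(blk, qfrom, qto) {
  qv <- .chars(blk$qrow); tv <- .chars(blk$trow)
  qpos <- blk$qstart - 1L + cumsum(qv != "-")
  keep <- qpos >= qfrom & qpos <= qto & !(qv == "-" & qpos < qfrom)
  # a query-gap column carries the qpos of the preceding base; drop leading
  # query-gap columns whose anchor base is outside the range
  if (!any(keep)) return(NULL)
  sel <- which(keep)
  qv <- qv[sel]; tv <- tv[sel]
  tpos <- blk$tstart - 1L + cumsum(.chars(blk$trow) != "-")
  list(qstart = min(qpos[sel][qv != "-"]), qend = max(qpos[sel][qv != "-"]),
       tstart = min(tpos[sel][tv != "-"]), tend = max(tpos[sel][tv != "-"]),
       qrow = paste(qv, collapse = ""), trow = paste(tv, collapse = ""),
       identity = blk$identity, window = blk$window)
}

#' Assemble passing window alignments into a chromosome alignment
#'
#' Consecutive 12-kb windows overlap by construction; each query position
#' must be covered once. In an overlap the window with the higher overall
#' identity keeps its alignment and the other is cut back, with the cut
#' placed at a query position where both windows align cleanly (gap-free
#' in a small neighbourhood). Windows whose target intervals disagree by
#' more than \code{max_disagreement} in an overlap are truncated to their
#' non-overlapping cores and the conflict is logged.
#'
#' @param windows list of window alignments with absolute coordinates
#'   (fields \code{qstart}, \code{qend}, \code{tstart}, \code{tend},
#'   \code{qrow}, \code{trow}, \code{identity}, \code{window}).
#' @param queryName,targetName chromosome names.
#' @param max_disagreement target disagreement treated as irreconcilable
#'   (default 10 kb).
#' @return a \linkS4class{ChromosomeAlignment}.
#' @export
assembleChromosome <- function(windows, queryName = "query",
                               targetName = "target",
                               max_disagreement = 10000L) {
  windows <- windows[order(vapply(windows, `[[`, numeric(1), "qstart"))]
  blocks <- list()
  conflicts <- list()
  for (w in windows) {
    if (is.null(w) || !nzchar(w$qrow)) next
    if (!length(blocks)) { blocks[[1L]] <- w; next }
    prev <- blocks[[length(blocks)]]
    qcursor <- prev$qend
    if (w$qend <= qcursor) next          # fully covered already
    if (w$qstart > qcursor) {            # no overlap: append (hole kept)
      blocks[[length(blocks) + 1L]] <- w
      next
    }
    # earliest admissible cut: cannot rewind beyond the previous block's
    # interior, cannot start before the new window
    b_min <- max(w$qstart, prev$qstart + 1L)
    tdis <- abs((w$tstart - w$qstart) - (prev$tend - prev$qend))
    if (tdis > max_disagreement) {
      conflicts[[length(conflicts) + 1L]] <-
        data.frame(qstart = w$qstart, qend = qcursor, disagreement = tdis)
      b <- min(qcursor, max(b_min, w$qstart))
    } else {
      b <- .chooseCut(prev, w, b_min = b_min, b_max = qcursor)
    }
    prev2 <- .trimBlockToQuery(prev, prev$qstart, b - 1L)
    w2 <- .trimBlockToQuery(w, b, w$qend)
    if (!is.null(prev2)) blocks[[length(blocks)]] <- prev2
    if (!is.null(w2)) blocks[[length(blocks) + 1L]] <- w2
  }
  # enforce strict target monotonicity; drop blocks that break it
  keep <- list()
  for (b in blocks) {
    if (is.null(b)) next
    if (length(keep) && b$tstart <= keep[[length(keep)]]$tend) {
      conflicts[[length(conflicts) + 1L]] <-
        data.frame(qstart = b$qstart, qend = b$qend, disagreement = NA_real_)
      next
    }
    keep[[length(keep) + 1L]] <- b
  }
  bl <- if (length(keep)) do.call(rbind, lapply(keep, function(b)
    data.frame(qstart = b$qstart, qend = b$qend, tstart = b$tstart,
               tend = b$tend, qrow = b$qrow, trow = b$trow,
               window = b$window, stringsAsFactors = FALSE)))
  else data.frame(qstart = integer(0), qend = integer(0),
                  tstart = integer(0), tend = integer(0),
                  qrow = character(0), trow = character(0),
                  window = integer(0))
  cf <- if (length(conflicts)) do.call(rbind, conflicts)
  else data.frame(qstart = integer(0), qend = integer(0),
                  disagreement = numeric(0))
  new("ChromosomeAlignment", queryName = queryName, targetName = targetName,
      blocks = bl, conflicts = cf)
}

# pick a cut position in the query overlap of two blocks: prefer the
# higher-identity block's side, and place the cut where both blocks are
# locally gap-free so no indel is split
.chooseCut <- function(prev, cur, b_min, b_max, pad = 10L) {
  lo <- max(b_min, cur$qstart); hi <- b_max
  if (hi - lo < 2L * pad + 2L) return(lo)
  prev_wins <- isTRUE(prev$identity >= cur$identity)
  candidates <- if (prev_wins) seq(hi - pad, lo + pad, by = -25L)
  else seq(lo + pad, hi - pad, by = 25L)
  prep <- function(blk) {
    qv <- .chars(blk$qrow)
    gap <- qv == "-" | .chars(blk$trow) == "-"
    qpos <- blk$qstart - 1L + cumsum(qv != "-")
    list(gap = gap, qpos = qpos)
  }
  pp <- prep(prev); pc <- prep(cur)
  cleanAt <- function(p, q) {
    sel <- p$qpos >= q - pad & p$qpos <= q + pad
    any(sel) && !any(p$gap[sel])
  }
  for (q in candidates) {
    if (cleanAt(pp, q) && cleanAt(pc, q)) return(q)
  }
  lo
}

#' Align two genomes chromosome by chromosome
#'
#' Runs the full anchoring + windowed-alignment + assembly pipeline:
#' 5-kb fragments of the query are anchored on the target, each anchored
#' fragment seeds a 12-kb window pair (fragment + adjacent 3' sequence, so
#' consecutive windows overlap by 7 kb), windows are aligned with
#' \code{\link{alignWindow}} and assembled with
#' \code{\link{assembleChromosome}}.
#'
#' @param query,target \code{DNAStringSet} genomes.
#' @param fragment_bp,window_bp fragment and window sizes.
#' @param min_anchor_identity anchoring identity threshold.
#' @param gap_open,gap_ext,match,mismatch alignment scoring.
#' @param quality_flank_bp,quality_identity parameters of
#'   \code{\link{passesQuality}}, recorded per window.
#' @return named list of \linkS4class{ChromosomeAlignment} (one per query
#'   chromosome), each with the per-window quality flags retained in the
#'   block table's provenance.
#' @export
alignGenomes <- function(query, target, fragment_bp = 5000L,
                         window_bp = 12000L, min_anchor_identity = 0.96,
                         gap_open = 30, gap_ext = 0.1, match = 5,
                         mismatch = -4, quality_flank_bp = 200L,
                         quality_identity = 0.90) {
  query <- Biostrings::DNAStringSet(query)
  target <- Biostrings::DNAStringSet(target)
  anchors <- fragmentAndAnchor(query, target, fragment_bp,
                               min_anchor_identity)
  out <- list()
  for (qc in unique(anchors$qchrom)) {
    a <- anchors[anchors$qchrom == qc & anchors$anchored, , drop = FALSE]
    if (!nrow(a)) next
    tc <- a$tchrom[1L]
    qseq <- as.character(query[[match(qc, names(query) %||%
                                        as.character(seq_along(query)))]])
    tseq <- as.character(target[[match(tc, names(target) %||%
                                         as.character(seq_along(target)))]])
    wins <- vector("list", nrow(a))
    for (i in seq_len(nrow(a))) {
      q0 <- a$qstart[i]
      q1 <- min(nchar(qseq), q0 + window_bp - 1L)
      # the target homolog of a 12-kb query window can be substantially
      # longer when the target carries insertions; leave generous slack so
      # a window never ends inside an unaligned insert
      t0 <- max(1L, a$tpos[i] - 500L)
      t1 <- min(nchar(tseq), a$tpos[i] + window_bp - 1L + 3500L)
      wa <- alignWindow(substr(qseq, q0, q1), substr(tseq, t0, t1),
                        gap_open = gap_open, gap_ext = gap_ext,
                        match = match, mismatch = mismatch, band = "auto")
      if (wa$score <= 0) next
      wins[[i]] <- list(qstart = q0 + wa$qstart - 1L,
                        qend = q0 + wa$qend - 1L,
                        tstart = t0 + wa$tstart - 1L,
                        tend = t0 + wa$tend - 1L,
                        qrow = wa$qrow, trow = wa$trow,
                        identity = wa$identity, window = i)
    }
    wins <- Filter(Negate(is.null), wins)
    if (!length(wins)) next
    out[[qc]] <- assembleChromosome(wins, queryName = qc, targetName = tc)
  }
  out
}
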