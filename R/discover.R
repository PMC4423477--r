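# Iterative de novo discovery of TIR element families from unassigned
# polymorphic segments, and consensus border refinement from hit+flank
# multiple alignments.

# ---- center-star progressive multiple alignment -------------------------
# The rows being aligned are near-identical genomic copies of one element
# (>= 85% pairwise identity), for which a center-star alignment is adequate.
# Pairwise steps use Biostrings' global aligner.

.centerStarMSA <- function(seqs) {
  stopifnot(length(seqs) >= 2L)
  center <- seqs[[which.max(nchar(seqs))]]
  n <- nchar(center)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2,
                                                     mismatch = -3)
  pas <- lapply(seqs, function(s) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(s), Biostrings::DNAString(center),
      type = "global", substitutionMatrix = submat,
      gapOpening = 8, gapExtension = 2)
    list(s = as.character(Biostrings::alignedPattern(pa)),
         c = as.character(Biostrings::alignedSubject(pa)))
  })
  # per-alignment insertion lengths before each center position (0..n)
  inslen <- lapply(pas, function(p) {
    cv <- .chars(p$c)
    ins <- integer(n + 1L)
    ci <- 0L
    run <- 0L
    for (ch in cv) {
      if (ch == "-") run <- run + 1L
      else { ins[ci + 1L] <- run; run <- 0L; ci <- ci + 1L }
    }
    ins[n + 1L] <- run
    ins
  })
  master <- do.call(pmax, inslen)
  rows <- vapply(seq_along(pas), function(k) {
    sv <- .chars(pas[[k]]$s); cv <- .chars(pas[[k]]$c)
    out <- character(0)
    ci <- 0L; buf <- character(0)
    flush <- function(slot, buf) {
      pad <- master[slot] - length(buf)
      c(buf, rep("-", pad))
    }
    for (i in seq_along(cv)) {
      if (cv[i] == "-") buf <- c(buf, sv[i])
      else {
        out <- c(out, flush(ci + 1L, buf), sv[i])
        buf <- character(0)
        ci <- ci + 1L
      }
    }
    out <- c(out, flush(n + 1L, buf))
    paste(out, collapse = "")
  }, character(1))
  rows
}

# strict per-column majority over non-gap characters, ties alphabetical
.columnConsensus <- function(mat) {
  apply(mat, 2L, function(col) {
    col <- col[col != "-"]
    if (!length(col)) return("-")
    tab <- sort(table(col), decreasing = TRUE)
    cands <- names(tab)[tab == max(tab)]
    sort(cands)[1L]
  })
}

#' Refine element borders from a hit-plus-flank multiple alignment
#'
#' Given a multiple alignment of genomic copies of a putative element, each
#' extracted with flanking sequence, determines the element core as the
#' maximal column interval where at least 50\% of rows are non-gap and the
#' rows agree (columns derived from the unrelated flanks diverge), and
#' returns the majority consensus of that interval. Terminal inverted
#' repeats are reported when \code{\link{matchTIR}} succeeds at both ends
#' for any superfamily profile.
#'
#' @param msa character vector of equal-length gapped rows (>= 3 rows).
#' @param min_core minimum core length in bp (default 50).
#' @param min_consistency minimal fraction of agreeing non-gap characters
#'   for a column to count as conserved (default 0.7).
#' @return a list with \code{failed} (logical), and when successful
#'   \code{consensus}, \code{core_start}/\code{core_end} (column interval),
#'   \code{tir} (a \code{\link{matchTIR}} hit or \code{NULL}) and
#'   \code{superfamily} (from the TIR hit, else \code{NA}).
#' @export
refineConsensusBorders <- function(msa, min_core = 50L,
                                   min_consistency = 0.7) {
  stopifnot(length(msa) >= 3L, length(unique(nchar(msa))) == 1L)
  mat <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  nr <- nrow(mat); nc <- ncol(mat)
  nongap <- colSums(mat != "-")
  consist <- apply(mat, 2L, function(col) {
    col <- col[col != "-"]
    if (!length(col)) return(0)
    max(table(col)) / length(col)
  })
  core <- nongap >= 0.5 * nr & consist >= min_consistency
  runs <- .runsOf(ifelse(core, "1", "0"), "1")
  fail <- list(failed = TRUE, consensus = NULL)
  if (!nrow(runs)) return(fail)
  best <- runs[which.max(runs$length), ]
  if (best$start == 1L && best$end == nc)
    return(fail)  # no flank divergence signal: borders indeterminable
  cons <- .columnConsensus(mat[, best$start:best$end, drop = FALSE])
  cons <- paste(cons[cons != "-"], collapse = "")
  if (nchar(cons) < min_core) return(fail)
  # conserved target-site bases (shared TSD motifs) can survive at the
  # core edges; scan small symmetric offsets for a TIR match and trim the
  # consensus to the element proper
  tir <- NULL; code <- NA_character_
  for (o in 0:3) {
    sub <- substr(cons, 1L + o, nchar(cons) - o)
    for (p in superfamilyProfiles()) {
      hit <- matchTIR(sub, p, max_mismatch = 0)
      if (!is.null(hit)) { tir <- hit; code <- p@code; cons <- sub; break }
    }
    if (!is.null(tir)) break
  }
  list(failed = FALSE, consensus = cons, core_start = best$start,
       core_end = best$end, tir = tir, superfamily = code)
}

#' Discover new TE families from unassigned segments
#'
#' Implements the iterative family-discovery loop: each segment without
#' library homology is searched against the genome; segments with at least
#' \code{min_copies} near-full-length hits at \code{min_identity} or better
#' are treated as putative TEs. The top 15 hits (plus \code{flank_bp} of
#' flanking sequence) are multiply aligned, element borders are refined via
#' \code{\link{refineConsensusBorders}}, and the resulting consensus joins
#' the library. Segments are processed longest-first and the loop repeats
#' until a full pass adds no family (fixed point).
#'
#' @param unassigned_segments character vector of nucleotide strings.
#' @param genome \code{DNAStringSet} (or single string) to search.
#' @param library optional \linkS4class{TELibrary}; segments already
#'   annotated by it (coverage >= 50\%) are skipped.
#' @param min_copies minimum genome copy number (default 15).
#' @param min_identity minimum hit identity (default 0.85).
#' @param flank_bp flanking sequence extracted around each hit (default 300).
#' @param top_n number of hits used for the consensus alignment (default 15).
#' @return list with \code{discovered} (a \linkS4class{TELibrary} of new
#'   families, possibly empty) and \code{library} (input library expanded by
#'   the discoveries).
#' @export
discoverFamilies <- function(unassigned_segments, genome, library = NULL,
                             min_copies = 15L, min_identity = 0.85,
                             flank_bp = 300L, top_n = 15L) {
  if (is.null(library))
    library <- new("TELibrary", consensus = Biostrings::DNAStringSet(),
                   info = S4Vectors::DataFrame(family = character(0),
                                               superfamily = character(0),
                                               source = character(0)))
  gseq <- if (is(genome, "DNAStringSet")) as.character(genome) else
    as.character(genome)
  segs <- unassigned_segments[order(-nchar(unassigned_segments))]
  discovered <- character(0)
  disc_code <- character(0)
  n_new <- 0L
  repeat {
    added <- FALSE
    remaining <- character(0)
    for (seg in segs) {
      if (length(library)) {
        ann <- annotateSegment(seg, library)
        cov <- if (nrow(ann)) sum(ann$end - ann$start + 1L) else 0L
        if (cov >= 0.5 * nchar(seg)) next
      }
      hits <- do.call(rbind, lapply(seq_along(gseq), function(ci) {
        h <- .searchGenome(seg, gseq[ci], min_len = 0.8 * nchar(seg),
                           min_identity = min_identity)
        if (nrow(h)) h$chrom <- ci
        h
      }))
      qcov <- if (!is.null(hits) && nrow(hits))
        (hits$qend - hits$qstart + 1L) >= 0.8 * nchar(seg) else logical(0)
      hits <- hits[qcov, , drop = FALSE]
      if (is.null(hits) || nrow(hits) < min_copies) {
        remaining <- c(remaining, seg)
        next
      }
      hits <- hits[order(-hits$score), , drop = FALSE]
      hits <- hits[seq_len(min(top_n, nrow(hits))), , drop = FALSE]
      copies <- vapply(seq_len(nrow(hits)), function(i) {
        g <- gseq[hits$chrom[i]]
        lo <- max(1L, hits$tstart[i] - flank_bp)
        hi <- min(nchar(g), hits$tend[i] + flank_bp)
        s <- substr(g, lo, hi)
        if (hits$strand[i] == "-") .revcomp(s) else s
      }, character(1))
      ref <- refineConsensusBorders(.centerStarMSA(copies))
      if (ref$failed) {
        remaining <- c(remaining, seg)
        next
      }
      n_new <- n_new + 1L
      code <- if (!is.na(ref$superfamily)) ref$superfamily else "DTM"
      fam <- sprintf("%s_NOV%d", code, n_new)
      cons <- ref$consensus
      names(cons) <- fam
      library <- .appendFamilies(library, cons, code)
      discovered <- c(discovered, stats::setNames(cons, fam))
      disc_code <- c(disc_code, code)
      added <- TRUE
    }
    segs <- remaining
    if (!added || !length(segs)) break
  }
  disc <- if (length(discovered))
    TELibrary(discovered, disc_code, source = "discovered")
  else
    new("TELibrary", consensus = Biostrings::DNAStringSet(),
        info = S4Vectors::DataFrame(family = character(0),
                                    superfamily = character(0),
                                    source = character(0)))
  list(discovered = disc, library = library)
}
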