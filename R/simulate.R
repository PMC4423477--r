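# Synthetic diverged genome pairs with planted TE copies, insertion and
# excision events with calibrated excision footprints, internal TE
# deletions, background indels and assembly gaps, plus a ground-truth log.
#
# All randomness flows from R's RNG; simulateGenomePair() seeds it once from
# config$seed so fixtures are byte-identical for a fixed seed.

# ---- low-level edit machinery ------------------------------------------
# An edit replaces the inclusive span [start, end] with `repl`; a pure
# insertion before position p is encoded start = p, end = p - 1. Edits are
# expressed in the coordinates of the unedited sequence and must not
# overlap; they are applied in one left-to-right pass.

.applyEdits <- function(seq, edits) {
  if (is.null(edits) || !nrow(edits)) return(seq)
  edits <- edits[order(edits$start, edits$end), , drop = FALSE]
  if (nrow(edits) > 1L && any(edits$start[-1L] <= edits$end[-nrow(edits)]))
    .stopf("overlapping edits")
  pieces <- character(2L * nrow(edits) + 1L)
  prev <- 1L
  for (i in seq_len(nrow(edits))) {
    pieces[2L * i - 1L] <- if (edits$start[i] > prev)
      substr(seq, prev, edits$start[i] - 1L) else ""
    pieces[2L * i] <- edits$repl[i]
    prev <- edits$end[i] + 1L
  }
  pieces[2L * nrow(edits) + 1L] <- substr(seq, prev, nchar(seq))
  paste(pieces, collapse = "")
}

# map positions in unedited coordinates to edited coordinates (positions
# must not lie inside a replaced span)
.mapCoord <- function(p, edits) {
  if (is.null(edits) || !nrow(edits)) return(p)
  edits <- edits[order(edits$start), , drop = FALSE]
  delta <- nchar(edits$repl) - (edits$end - edits$start + 1L)
  cum <- cumsum(delta)
  idx <- findInterval(p - 0.5, edits$end)  # edits fully left of p
  p + ifelse(idx > 0L, cum[pmax(idx, 1L)], 0L)
}

.applySubstitutions <- function(seq, positions) {
  if (!length(positions)) return(seq)
  r <- charToRaw(seq)
  bases <- charToRaw("ACGT")
  cur <- r[positions]
  repl <- vapply(cur, function(b) sample(bases[bases != b], 1L), raw(1))
  r[positions] <- repl
  rawToChar(r)
}

# sample n non-overlapping positions in [lo, hi], each reserving
# [p - halo, p + width + halo] against `reserved` (2-col matrix) and each
# other
.samplePositions <- function(n, lo, hi, width = 0L, reserved = NULL,
                             halo = 100L, max_try = 10000L) {
  res <- if (is.null(reserved)) matrix(numeric(0), ncol = 2L) else reserved
  out <- integer(0)
  tries <- 0L
  while (length(out) < n && tries < max_try) {
    tries <- tries + 1L
    p <- sample.int(hi - lo + 1L, 1L) + lo - 1L
    a <- p - halo; b <- p + width + halo
    if (nrow(res) && any(res[, 1L] <= b & res[, 2L] >= a)) next
    out <- c(out, p)
    res <- rbind(res, c(a, b))
  }
  if (length(out) < n)
    .stopf("could not place %d non-overlapping loci (placed %d)", n,
           length(out))
  list(positions = out, reserved = res)
}

# nearest occurrence of any motif in `motifs` starting at or after/before
# `pos` within max_dist; NA if none
.nearestMotif <- function(seq, pos, motifs, max_dist = 1000L) {
  lo <- max(1L, pos - max_dist)
  hi <- min(nchar(seq), pos + max_dist + max(nchar(motifs)))
  windowseq <- substr(seq, lo, hi)
  best <- NA_integer_
  for (m in motifs) {
    occ <- gregexpr(m, windowseq, fixed = TRUE)[[1L]]
    if (occ[1L] == -1L) next
    occ <- occ + lo - 1L
    cand <- occ[which.min(abs(occ - pos))]
    if (is.na(best) || abs(cand - pos) < abs(best - pos)) best <- cand
  }
  best
}

.tsdMotifs <- function(profile) {
  if (identical(profile@tsdMotif, "variable")) NULL
  else strsplit(profile@tsdMotif, "/", fixed = TRUE)[[1L]]
}

# ---- public constructors ------------------------------------------------

#' Excision footprint parameters
#'
#' Defaults are calibrated to the observed repair outcome mix at excision
#' sites: 8/94 perfect excisions, 9/94 with both a flanking deletion and a
#' filler segment, and the remaining mass split between deletion-only and
#' filler-only outcomes in proportion 34:49. Flanking deletions are
#' geometric with mean \code{deletion_length_mean} (18 bp) with a rare
#' extreme component (multi-kb, probability \code{extreme_deletion_prob});
#' filler segments are geometric with mean 13 bp, clipped to 1-123 bp.
#'
#' @param p_perfect,p_deletion,p_filler,p_both outcome probabilities
#'   (must sum to 1).
#' @param deletion_length_mean mean flanking deletion (bp).
#' @param extreme_deletion_prob probability a deletion is drawn from the
#'   extreme component instead.
#' @param extreme_deletion_range bp interval of the extreme component.
#' @param filler_length_mean,filler_length_range mean and admissible range
#'   of filler lengths (bp).
#' @param two_sided if TRUE, deletions are split over both sides; default
#'   one-sided (side chosen uniformly).
#' @return named list of parameters.
#' @export
footprintParams <- function(p_perfect = 8 / 94,
                            p_deletion = (77 / 94) * (34 / 83),
                            p_filler = (77 / 94) * (49 / 83),
                            p_both = 9 / 94,
                            deletion_length_mean = 18,
                            extreme_deletion_prob = 0.01,
                            extreme_deletion_range = c(1000, 3000),
                            filler_length_mean = 13,
                            filler_length_range = c(1, 123),
                            two_sided = FALSE) {
  p <- c(p_perfect, p_deletion, p_filler, p_both)
  if (abs(sum(p) - 1) > 1e-9) .stopf("footprint probabilities must sum to 1")
  if (any(p < 0)) .stopf("footprint probabilities must be non-negative")
  list(p_perfect = p_perfect, p_deletion = p_deletion, p_filler = p_filler,
       p_both = p_both, deletion_length_mean = deletion_length_mean,
       extreme_deletion_prob = extreme_deletion_prob,
       extreme_deletion_range = extreme_deletion_range,
       filler_length_mean = filler_length_mean,
       filler_length_range = filler_length_range, two_sided = two_sided)
}

#' Simulation configuration
#'
#' Default values encode the study conditions the simulator emulates: two
#' genomes at ~0.7\% pairwise substitution divergence (0.35\% per branch)
#' with small background indels, five planted TE families (one per
#' superfamily), 150 post-divergence insertions and 50 excisions with the
#' default footprint mix, a handful of internal TE deletions unrelated to
#' transposition, and 20 assembly gaps (runs of > 50 Ns), a quarter of them
#' over planted TE copies.
#'
#' @param genome_length ancestor length in bp.
#' @param gc GC fraction of the ancestor.
#' @param substitution_rate per-bp substitution rate applied to each branch.
#' @param background_indel_rate per-bp rate of small (1-10 bp) indels per
#'   branch.
#' @param n_planted_per_family ancestral (shared) copies planted per family.
#' @param n_insertions,n_excisions,n_precise,n_internal_deletions
#'   post-divergence event counts.
#' @param footprint a \code{\link{footprintParams}} list.
#' @param n_gaps,gap_length_range,gap_te_fraction assembly-gap model for
#'   genome B (lengths must exceed 50).
#' @param seed mandatory RNG seed.
#' @param margin event-free margin at the chromosome ends (bp).
#' @param min_locus_spacing minimum spacing between planted/event loci (bp).
#' @return named list.
#' @export
simulationConfig <- function(genome_length = 2e6, gc = 0.44,
                             substitution_rate = 0.0035,
                             background_indel_rate = 5e-5,
                             n_planted_per_family = 20L,
                             n_insertions = 150L, n_excisions = 50L,
                             n_precise = 0L, n_internal_deletions = 10L,
                             footprint = footprintParams(),
                             n_gaps = 20L, gap_length_range = c(60L, 2000L),
                             gap_te_fraction = 0.25, seed,
                             margin = 15000L, min_locus_spacing = 5000L) {
  if (missing(seed)) .stopf("seed is mandatory")
  if (gc < 0 || gc > 1) .stopf("gc must be in [0, 1]")
  if (substitution_rate < 0 || substitution_rate > 0.1 ||
      background_indel_rate < 0 || background_indel_rate > 0.1)
    .stopf("rates must lie in [0, 0.1]")
  if (gap_length_range[1L] <= 50L)
    .stopf("gap lengths must exceed 50 (N-run definition)")
  as.list(environment())
}

#' Generate a random ancestor sequence
#'
#' @param length sequence length (>= 1).
#' @param gc expected GC fraction.
#' @param seed optional seed (set for reproducibility).
#' @return nucleotide string.
#' @export
makeAncestor <- function(length, gc = 0.44, seed = NULL) {
  if (length < 1) .stopf("length must be >= 1")
  if (gc < 0 || gc > 1) .stopf("gc must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  .randDNA(length, gc)
}

#' Generate a synthetic TE consensus library
#'
#' Builds one (or more) consensus per superfamily with the superfamily's
#' TIR consensus at the 5' end and its reverse complement at the 3' end,
#' and a random interior. Element lengths reflect the dominance of
#' non-autonomous elements (a few hundred bp) with larger CACTA/Mutator
#' consensus sequences.
#'
#' @param n_per_superfamily families per superfamily.
#' @param lengths named vector of element lengths per superfamily code.
#' @param gc interior GC fraction.
#' @param seed optional seed.
#' @return a \linkS4class{TELibrary} (source "library").
#' @export
makeTELibrary <- function(n_per_superfamily = 1L,
                          lengths = c(DTT = 250L, DTH = 430L, DTM = 800L,
                                      DTC = 1200L, DTA = 550L),
                          gc = 0.44, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  profs <- superfamilyProfiles()
  seqs <- character(0)
  codes <- character(0)
  for (code in names(profs)) {
    tir5 <- .expandMotif(profs[[code]]@tirConsensus)[1L]
    for (i in seq_len(n_per_superfamily)) {
      len <- lengths[[code]]
      interior <- .randDNA(len - 2L * nchar(tir5), gc)
      s <- paste0(tir5, interior, .revcomp(tir5))
      fam <- sprintf("%s_SIM%d", code, i)
      seqs[fam] <- s
      codes <- c(codes, code)
    }
  }
  TELibrary(seqs, codes, source = "library")
}

#' Diverge two copies of an ancestor
#'
#' Applies independent substitutions and small (1-10 bp) background indels
#' to two copies of the ancestor; background indels never exceed 50 bp so
#' they cannot mimic a TE presence/absence polymorphism.
#'
#' @param ancestor nucleotide string.
#' @param substitution_rate,background_indel_rate per-bp, per-branch rates.
#' @param indel_len_range inclusive bp range of background indels.
#' @return list with \code{genomeA}, \code{genomeB} and \code{events}
#'   (a \code{data.frame} of logged background indels).
#' @export
divergeGenomes <- function(ancestor, substitution_rate = 0.0035,
                           background_indel_rate = 5e-5,
                           indel_len_range = c(1L, 10L)) {
  stopifnot(substitution_rate <= 0.1, background_indel_rate <= 0.1,
            indel_len_range[2L] <= 50L)
  n <- nchar(ancestor)
  out <- list()
  events <- list()
  for (sp in c("A", "B")) {
    nsub <- stats::rbinom(1L, n, substitution_rate)
    g <- .applySubstitutions(ancestor, sample.int(n, nsub))
    nind <- stats::rbinom(1L, n, background_indel_rate)
    edits <- NULL
    if (nind > 0L) {
      pos <- sort(.samplePositions(nind, 20L, n - 20L, width = 12L,
                                   halo = 15L)$positions)
      lens <- sample(seq(indel_len_range[1L], indel_len_range[2L]), nind,
                     replace = TRUE)
      isins <- sample(c(TRUE, FALSE), nind, replace = TRUE)
      edits <- data.frame(
        start = pos,
        end = ifelse(isins, pos - 1L, pos + lens - 1L),
        repl = ifelse(isins,
                      vapply(lens, function(l) .randDNA(l, 0.5),
                             character(1)), ""),
        stringsAsFactors = FALSE)
      events[[sp]] <- data.frame(kind = "background-indel", species = sp,
                                 position = pos, length = lens,
                                 insertion = isins)
    }
    out[[sp]] <- .applyEdits(g, edits)
  }
  list(genomeA = out$A, genomeB = out$B,
       events = if (length(events)) do.call(rbind, events) else
         data.frame(kind = character(0), species = character(0),
                    position = integer(0), length = integer(0),
                    insertion = logical(0)))
}

#' Insert a TE at a position, creating a target-site duplication
#'
#' The target site (of the profile's TSD length) is duplicated so the locus
#' becomes flank-TSD-TE-TSD-flank; genome length grows by
#' \code{nchar(te) + tsd_length}. For fixed-motif superfamilies the
#' insertion is relocated to the nearest motif occurrence (within 1 kb).
#'
#' @param genome nucleotide string.
#' @param te TE sequence (non-empty).
#' @param position requested insertion site (start of the target site).
#' @param profile a \linkS4class{SuperfamilyProfile}.
#' @return list with \code{genome} (mutated) and \code{event} (a list:
#'   kind, site, tsd, te_length; the bearing interval is
#'   \code{[site, site + 2 * tsd_length + te_length - 1]}).
#' @export
applyInsertion <- function(genome, te, position, profile) {
  if (!nzchar(te)) .stopf("cannot insert a zero-length TE")
  L <- profile@tsdLength
  motifs <- .tsdMotifs(profile)
  site <- position
  if (!is.null(motifs)) {
    site <- .nearestMotif(genome, position, motifs)
    if (is.na(site))
      .stopf("no %s target-site motif within 1 kb of position %d",
             profile@tsdMotif, position)
  }
  if (site < 1L || site + L - 1L > nchar(genome))
    .stopf("insertion site out of range")
  tsd <- substr(genome, site, site + L - 1L)
  g <- paste0(substr(genome, 1L, site + L - 1L), te, tsd,
              substr(genome, site + L, nchar(genome)))
  list(genome = g,
       event = list(kind = "insertion", site = site, tsd = tsd,
                    tsd_length = L, te_length = nchar(te)))
}

# draw one excision footprint from FootprintParams
.drawFootprint <- function(params) {
  kind <- sample(c("perfect", "deletion", "filler", "both"), 1L,
                 prob = c(params$p_perfect, params$p_deletion,
                          params$p_filler, params$p_both))
  del <- 0L; side <- NA_character_; filler_len <- 0L
  if (kind %in% c("deletion", "both")) {
    if (stats::runif(1L) < params$extreme_deletion_prob) {
      del <- sample(seq(params$extreme_deletion_range[1L],
                        params$extreme_deletion_range[2L]), 1L)
    } else {
      del <- 1L + stats::rgeom(1L, prob = 1 / params$deletion_length_mean)
    }
    side <- sample(c("left", "right"), 1L)
  }
  if (kind %in% c("filler", "both")) {
    repeat {
      filler_len <- 1L + stats::rgeom(1L,
                                      prob = 1 / params$filler_length_mean)
      if (filler_len >= params$filler_length_range[1L] &&
          filler_len <= params$filler_length_range[2L]) break
    }
  }
  list(kind = kind, side = side, deleted_bp = as.integer(del),
       filler_bp = as.integer(filler_len))
}

#' Excise a TE, drawing a double-strand-break repair footprint
#'
#' Removes the element at \code{te_locus} and applies one of four repair
#' outcomes: perfect (both TSD copies left as a tandem footprint), flanking
#' deletion (the TE, the TSD on the deleted side and a geometric number of
#' flanking bp are lost), filler (the TE is replaced by a segment copied
#' from a random donor locus of the same genome), or both.
#'
#' @param genome nucleotide string.
#' @param te_locus list with \code{tsd_start} (start of the 5' TSD),
#'   \code{te_start}, \code{te_end}, \code{tsd_length} and \code{is_te =
#'   TRUE} (loci not flagged as TEs are rejected).
#' @param params a \code{\link{footprintParams}} list.
#' @param footprint optional pre-drawn footprint (as from the internal
#'   draw); if NULL one is drawn.
#' @return list with \code{genome} and \code{event} (kind
#'   excision-perfect/-deletion/-filler/-both, deleted_bp, filler_bp,
#'   filler_seq, side).
#' @export
applyExcision <- function(genome, te_locus, params = footprintParams(),
                          footprint = NULL) {
  if (!isTRUE(te_locus$is_te))
    .stopf("refusing to excise a locus not flagged as a TE")
  L <- te_locus$tsd_length
  s <- te_locus$te_start; e <- te_locus$te_end
  if (is.null(footprint)) footprint <- .drawFootprint(params)
  fs <- ""
  if (footprint$filler_bp > 0L) {
    donor <- sample.int(nchar(genome) - footprint$filler_bp, 1L)
    fs <- substr(genome, donor, donor + footprint$filler_bp - 1L)
  }
  del <- footprint$deleted_bp
  if (footprint$kind == "perfect") {
    start <- s; end <- e
  } else if (footprint$kind == "filler") {
    start <- s; end <- e
  } else if (identical(footprint$side, "left")) {
    start <- max(1L, s - L - del); end <- e
    del <- s - L - start  # actual deleted flank if clipped at the edge
  } else {
    start <- s; end <- min(nchar(genome), e + L + del)
    del <- end - e - L
  }
  g <- paste0(substr(genome, 1L, start - 1L), fs,
              substr(genome, end + 1L, nchar(genome)))
  kind <- switch(footprint$kind, perfect = "excision-perfect",
                 deletion = "excision-deletion", filler = "excision-filler",
                 both = "excision-both")
  list(genome = g,
       event = list(kind = kind, deleted_bp = as.integer(
         if (footprint$kind %in% c("deletion", "both")) del else 0L),
         filler_bp = nchar(fs), filler_seq = fs,
         side = footprint$side, removed_start = start, removed_end = end))
}

#' Replace segments of a genome with assembly gaps (N runs)
#'
#' @param genome nucleotide string.
#' @param n_gaps number of gaps.
#' @param length_range inclusive bp range (minimum must exceed 50).
#' @param te_intervals optional 2-column matrix of planted TE intervals; a
#'   fraction \code{frac_over_te} of gaps is centred on these.
#' @param frac_over_te fraction of gaps placed over TE copies.
#' @param avoid optional 2-column matrix of intervals gaps must not touch.
#' @return list with \code{genome} and \code{gaps}
#'   (\code{data.frame(start, end, length, over_te)}).
#' @export
addAssemblyGaps <- function(genome, n_gaps, length_range = c(60L, 2000L),
                            te_intervals = NULL, frac_over_te = 0.25,
                            avoid = NULL) {
  if (length_range[1L] <= 50L) .stopf("gap length minimum must exceed 50")
  if (n_gaps == 0L)
    return(list(genome = genome,
                gaps = data.frame(start = integer(0), end = integer(0),
                                  length = integer(0),
                                  over_te = logical(0))))
  n <- nchar(genome)
  reserved <- if (is.null(avoid)) matrix(numeric(0), ncol = 2L) else avoid
  rows <- list()
  g <- genome
  want_te <- !is.null(te_intervals) && nrow(te_intervals) > 0L
  for (i in seq_len(n_gaps)) {
    len <- sample(seq(length_range[1L], length_range[2L]), 1L)
    placed <- FALSE
    for (try in seq_len(1000L)) {
      over_te <- want_te && stats::runif(1L) < frac_over_te
      if (over_te) {
        ti <- te_intervals[sample.int(nrow(te_intervals), 1L), ]
        mid <- floor((ti[1L] + ti[2L]) / 2)
        start <- max(1L, as.integer(mid - floor(len / 2)))
      } else {
        start <- sample.int(n - len, 1L)
      }
      end <- start + len - 1L
      if (end > n) next
      if (nrow(reserved) &&
          any(reserved[, 1L] <= end + 10L & reserved[, 2L] >= start - 10L))
        next
      substr(g, start, end) <- strrep("N", len)
      reserved <- rbind(reserved, c(start - 10L, end + 10L))
      rows[[length(rows) + 1L]] <-
        data.frame(start = start, end = end, length = len,
                   over_te = over_te)
      placed <- TRUE
      break
    }
    if (!placed) .stopf("could not place gap %d without overlap", i)
  }
  list(genome = g, gaps = do.call(rbind, rows))
}

# ---- full simulator -----------------------------------------------------

#' Simulate a pair of diverged genomes with planted TE activity
#'
#' Builds a random ancestor, plants ancestral TE copies of each library
#' family (with proper TSDs), derives two genomes by independent
#' substitutions and background indels, applies post-divergence insertions,
#' excisions (with drawn footprints), precise excisions and internal TE
#' deletions, and finally masks assembly gaps in genome B. Every planted
#' mutation is logged with its final coordinates in both genomes.
#'
#' Excision footprints are additionally logged in normalized form
#' (\code{norm_deleted_bp}, \code{norm_filler_bp}): boundary placement of a
#' deletion or filler is not always uniquely determined by the realized
#' sequences, so the log also records the maximal-flank-extension
#' normalization that any sequence-based caller can recover (analogous to
#' indel left-alignment in variant calling).
#'
#' @param config a \code{\link{simulationConfig}} list.
#' @param library optional \linkS4class{TELibrary}; generated via
#'   \code{\link{makeTELibrary}} if NULL.
#' @return a \linkS4class{GenomePairSim}.
#' @export
simulateGenomePair <- function(config, library = NULL) {
  set.seed(config$seed)
  if (is.null(library)) library <- makeTELibrary()
  cons <- as.character(library@consensus)
  info <- library@info
  profs <- superfamilyProfiles()
  n0 <- config$genome_length
  anc0 <- .randDNA(n0, config$gc)

  # ---- plant ancestral copies ----
  fams <- rep(seq_along(cons), each = config$n_planted_per_family)
  sp <- .samplePositions(length(fams), config$margin, n0 - config$margin,
                         width = max(nchar(cons)) + 20L,
                         halo = config$min_locus_spacing %/% 2L)
  sites0 <- sp$positions
  plant_edits <- list()
  planted <- list()
  for (i in seq_along(fams)) {
    fi <- fams[i]
    prof <- profs[[info$superfamily[fi]]]
    L <- prof@tsdLength
    site <- sites0[i]
    motifs <- .tsdMotifs(prof)
    if (!is.null(motifs)) {
      site <- .nearestMotif(anc0, site, motifs)
      if (is.na(site)) next
    }
    tsd <- substr(anc0, site, site + L - 1L)
    plant_edits[[length(plant_edits) + 1L]] <-
      data.frame(start = site + L, end = site + L - 1L,
                 repl = paste0(cons[fi], tsd), stringsAsFactors = FALSE)
    planted[[length(planted) + 1L]] <-
      data.frame(fam = fi, site0 = site, tsd = tsd, L = L,
                 te_len = nchar(cons[fi]))
  }
  plant_edits <- do.call(rbind, plant_edits)
  planted <- do.call(rbind, planted)
  o <- order(planted$site0)
  planted <- planted[o, , drop = FALSE]
  plant_edits <- plant_edits[o, , drop = FALSE]
  anc <- .applyEdits(anc0, plant_edits)
  # planted locus coordinates in the planted-ancestor system
  planted$s <- .mapCoord(planted$site0, plant_edits)          # tsd1 start
  planted$te_start <- planted$s + planted$L
  planted$te_end <- planted$te_start + planted$te_len - 1L
  planted$span_end <- planted$te_end + planted$L
  n <- nchar(anc)

  # ---- per-branch substitutions ----
  subs <- lapply(c(A = "A", B = "B"), function(s)
    sample.int(n, stats::rbinom(1L, n, config$substitution_rate)))
  gsub_ <- list(A = .applySubstitutions(anc, subs$A),
                B = .applySubstitutions(anc, subs$B))

  # ---- choose post-divergence events ----
  reserved <- cbind(planted$s - 200L, planted$span_end + 200L)
  n_exc_like <- config$n_excisions + config$n_precise +
    config$n_internal_deletions
  if (n_exc_like > nrow(planted))
    .stopf("not enough planted loci (%d) for %d excision-like events",
           nrow(planted), n_exc_like)
  pick <- sample.int(nrow(planted), n_exc_like)
  exc_idx <- pick[seq_len(config$n_excisions)]
  prec_idx <- if (config$n_precise > 0L)
    pick[config$n_excisions + seq_len(config$n_precise)] else integer(0)
  int_idx <- if (config$n_internal_deletions > 0L)
    pick[config$n_excisions + config$n_precise +
           seq_len(config$n_internal_deletions)] else integer(0)

  ins_fam <- sample.int(length(cons), config$n_insertions, replace = TRUE)
  ip <- .samplePositions(config$n_insertions, config$margin,
                         n - config$margin,
                         width = max(nchar(cons)) + 20L,
                         reserved = reserved,
                         halo = config$min_locus_spacing %/% 2L)
  ins_pos <- ip$positions
  reserved <- ip$reserved

  events <- list()
  edits <- list(A = list(), B = list())
  eid <- 0L

  # insertions
  for (i in seq_len(config$n_insertions)) {
    fi <- ins_fam[i]
    prof <- profs[[info$superfamily[fi]]]
    L <- prof@tsdLength
    species <- sample(c("A", "B"), 1L)
    site <- ins_pos[i]
    motifs <- .tsdMotifs(prof)
    if (!is.null(motifs)) {
      site <- .nearestMotif(gsub_[[species]], site, motifs)
      if (is.na(site)) next
    }
    tsd <- substr(gsub_[[species]], site, site + L - 1L)
    eid <- eid + 1L
    edits[[species]][[length(edits[[species]]) + 1L]] <-
      data.frame(start = site + L, end = site + L - 1L,
                 repl = paste0(cons[fi], tsd), eid = eid,
                 stringsAsFactors = FALSE)
    events[[eid]] <- data.frame(
      event_id = eid, kind = "insertion", species = species,
      family = info$family[fi], superfamily = info$superfamily[fi],
      tsd = tsd, te_length = nchar(cons[fi]), anchor = site,
      span0 = site, span1 = site, rm0 = NA_integer_, rm1 = NA_integer_,
      tsd_length = L, deleted_bp = 0L, filler_bp = 0L, filler_seq = "",
      stringsAsFactors = FALSE)
  }

  # excisions at planted loci
  for (k in seq_along(exc_idx)) {
    p <- planted[exc_idx[k], ]
    species <- sample(c("A", "B"), 1L)   # the excising (empty) species
    fp <- .drawFootprint(config$footprint)
    g <- gsub_[[species]]
    fs <- ""
    if (fp$filler_bp > 0L) {
      donor <- sample.int(nchar(g) - fp$filler_bp, 1L)
      fs <- substr(g, donor, donor + fp$filler_bp - 1L)
    }
    del <- fp$deleted_bp
    if (fp$kind %in% c("perfect", "filler")) {
      start <- p$te_start; end <- p$te_end
    } else if (identical(fp$side, "left")) {
      start <- p$s - del; end <- p$te_end
      # clip the deletion so it cannot reach a neighbouring reserved locus
      lim <- max(c(0L, reserved[reserved[, 2L] < p$s - 300L, 2L])) + 100L
      if (start < lim) { start <- lim; del <- p$s - start }
    } else {
      end <- p$span_end + del; start <- p$te_start
      lim <- min(c(n + 1L, reserved[reserved[, 1L] > p$span_end + 300L,
                                    1L])) - 100L
      if (end > lim) { end <- lim; del <- end - p$span_end }
    }
    eid <- eid + 1L
    edits[[species]][[length(edits[[species]]) + 1L]] <-
      data.frame(start = start, end = end, repl = fs, eid = eid,
                 stringsAsFactors = FALSE)
    kind <- switch(fp$kind, perfect = "excision-perfect",
                   deletion = "excision-deletion",
                   filler = "excision-filler", both = "excision-both")
    events[[eid]] <- data.frame(
      event_id = eid, kind = kind, species = species,
      family = info$family[p$fam], superfamily = info$superfamily[p$fam],
      tsd = p$tsd, te_length = p$te_len, anchor = p$s,
      span0 = p$s, span1 = p$span_end, rm0 = start, rm1 = end,
      tsd_length = p$L,
      deleted_bp = if (fp$kind %in% c("deletion", "both")) del else 0L,
      filler_bp = nchar(fs), filler_seq = fs, stringsAsFactors = FALSE)
  }

  # precise excisions (TE plus one TSD removed; empty site restored)
  for (k in seq_along(prec_idx)) {
    p <- planted[prec_idx[k], ]
    species <- sample(c("A", "B"), 1L)
    eid <- eid + 1L
    edits[[species]][[length(edits[[species]]) + 1L]] <-
      data.frame(start = p$te_start, end = p$span_end, repl = "",
                 eid = eid, stringsAsFactors = FALSE)
    events[[eid]] <- data.frame(
      event_id = eid, kind = "precise-excision", species = species,
      family = info$family[p$fam], superfamily = info$superfamily[p$fam],
      tsd = p$tsd, te_length = p$te_len, anchor = p$s,
      span0 = p$s, span1 = p$span_end, rm0 = p$te_start, rm1 = p$span_end,
      tsd_length = p$L, deleted_bp = 0L, filler_bp = 0L,
      filler_seq = "", stringsAsFactors = FALSE)
  }

  # internal deletions (unrelated to transposition)
  for (k in seq_along(int_idx)) {
    p <- planted[int_idx[k], ]
    if (p$te_len < 200L) next
    species <- sample(c("A", "B"), 1L)
    maxlen <- p$te_len - 80L
    clen <- sample(seq(60L, maxlen), 1L)
    coff <- sample(seq(30L, p$te_len - clen - 30L), 1L)
    c1 <- p$te_start + coff; c2 <- c1 + clen - 1L
    eid <- eid + 1L
    edits[[species]][[length(edits[[species]]) + 1L]] <-
      data.frame(start = c1, end = c2, repl = "", eid = eid,
                 stringsAsFactors = FALSE)
    events[[eid]] <- data.frame(
      event_id = eid, kind = "internal-deletion", species = species,
      family = info$family[p$fam], superfamily = info$superfamily[p$fam],
      tsd = p$tsd, te_length = p$te_len, anchor = c1,
      span0 = c1, span1 = c2, rm0 = c1, rm1 = c2,
      tsd_length = p$L, deleted_bp = clen, filler_bp = 0L,
      filler_seq = "", stringsAsFactors = FALSE)
  }

  # background indels, away from all reserved loci
  for (species in c("A", "B")) {
    nind <- stats::rbinom(1L, n, config$background_indel_rate)
    if (nind > 0L) {
      bp <- .samplePositions(nind, 50L, n - 50L, width = 12L,
                             reserved = reserved, halo = 60L)
      pos <- bp$positions
      lens <- sample(1:10, nind, replace = TRUE)
      isins <- sample(c(TRUE, FALSE), nind, replace = TRUE)
      for (i in seq_len(nind)) {
        eid <- eid + 1L
        edits[[species]][[length(edits[[species]]) + 1L]] <-
          data.frame(start = pos[i],
                     end = if (isins[i]) pos[i] - 1L else pos[i] + lens[i] - 1L,
                     repl = if (isins[i]) .randDNA(lens[i], 0.5) else "",
                     eid = eid, stringsAsFactors = FALSE)
        events[[eid]] <- data.frame(
          event_id = eid, kind = "background-indel", species = species,
          family = "", superfamily = "", tsd = "", te_length = 0L,
          anchor = pos[i], span0 = pos[i], span1 = pos[i],
          rm0 = NA_integer_, rm1 = NA_integer_, tsd_length = 0L,
          deleted_bp = if (isins[i]) 0L else lens[i],
          filler_bp = if (isins[i]) lens[i] else 0L, filler_seq = "",
          stringsAsFactors = FALSE)
      }
    }
  }

  editsA <- if (length(edits$A)) do.call(rbind, edits$A) else NULL
  editsB <- if (length(edits$B)) do.call(rbind, edits$B) else NULL
  gA <- .applyEdits(gsub_$A, editsA)
  gB <- .applyEdits(gsub_$B, editsB)

  truth <- do.call(rbind, events)
  truth$rm_bear0 <- NA_integer_
  truth$rm_bear1 <- NA_integer_
  # final coordinates in both genomes:
  #  - insertions: span [site, site + 2L + te_len - 1] in the acting genome,
  #    point at the orthologous site in the other genome
  #  - removal events: full pre-event span in the bearing genome, junction
  #    point in the acting genome
  ed <- list(A = editsA, B = editsB)
  truth$startA <- .mapCoord(truth$span0, editsA)
  truth$endA <- .mapCoord(truth$span1 + 1L, editsA) - 1L
  truth$startB <- .mapCoord(truth$span0, editsB)
  truth$endB <- .mapCoord(truth$span1 + 1L, editsB) - 1L
  for (i in seq_len(nrow(truth))) {
    sp <- truth$species[i]
    oth <- if (sp == "A") "B" else "A"
    if (truth$kind[i] == "insertion") {
      st <- .mapCoord(truth$anchor[i], ed[[sp]])
      en <- st + 2L * truth$tsd_length[i] + truth$te_length[i] - 1L
      po <- .mapCoord(truth$anchor[i], ed[[oth]])
      if (sp == "A") {
        truth$startA[i] <- st; truth$endA[i] <- en
        truth$startB[i] <- po; truth$endB[i] <- po
      } else {
        truth$startB[i] <- st; truth$endB[i] <- en
        truth$startA[i] <- po; truth$endA[i] <- po
      }
    } else if (!is.na(truth$rm0[i])) {
      po <- .mapCoord(truth$rm0[i], ed[[sp]])
      if (sp == "A") { truth$startA[i] <- po; truth$endA[i] <- po }
      else { truth$startB[i] <- po; truth$endB[i] <- po }
      # removal span in bearing-genome coordinates (for normalization)
      truth$rm_bear0[i] <- .mapCoord(truth$rm0[i], ed[[oth]])
      truth$rm_bear1[i] <- .mapCoord(truth$rm1[i] + 1L, ed[[oth]]) - 1L
    }
  }

  # planted (non-event) TE intervals in final B coordinates, for gap placement
  ev_loci <- c(exc_idx, prec_idx, int_idx)
  surv <- planted[setdiff(seq_len(nrow(planted)), ev_loci), , drop = FALSE]
  te_B <- cbind(.mapCoord(surv$te_start, editsB),
                .mapCoord(surv$te_end, editsB))
  avoid <- cbind(pmin(truth$startB, truth$endB) - 1000L,
                 pmax(truth$startB, truth$endB) + 1000L)
  gp <- addAssemblyGaps(gB, config$n_gaps, config$gap_length_range,
                        te_intervals = te_B,
                        frac_over_te = config$gap_te_fraction,
                        avoid = avoid)
  gB <- gp$genome

  truth <- S4Vectors::DataFrame(truth[, c("event_id", "kind", "species",
                                          "family", "superfamily", "tsd",
                                          "tsd_length", "te_length",
                                          "startA", "endA", "startB",
                                          "endB", "rm_bear0", "rm_bear1",
                                          "deleted_bp",
                                          "filler_bp", "filler_seq")])
  truth <- .normalizeTruth(truth, gA, gB,
                           tolerate = config$substitution_rate > 0)
  cfg <- config
  cfg$gaps_realized <- gp$gaps
  new("GenomePairSim",
      genomeA = Biostrings::DNAStringSet(c(chrA = gA)),
      genomeB = Biostrings::DNAStringSet(c(chrB = gB)),
      truth = truth, library = library, config = cfg)
}

# normalized (sequence-recoverable) footprint quantities for excision rows
.normalizeTruth <- function(truth, gA, gB, tolerate = TRUE, context = 220L) {
  nd <- rep(NA_integer_, nrow(truth))
  nf <- rep(NA_integer_, nrow(truth))
  exc <- which(truth$kind %in% c("excision-perfect", "excision-deletion",
                                 "excision-filler", "excision-both"))
  for (i in exc) {
    ctx <- context + truth$deleted_bp[i]
    if (truth$species[i] == "A") {
      bear <- gB; emp <- gA
      bs <- truth$startB[i]; be <- truth$endB[i]
      ep <- truth$startA[i]
    } else {
      bear <- gA; emp <- gB
      bs <- truth$startA[i]; be <- truth$endA[i]
      ep <- truth$startB[i]
    }
    lo <- max(1L, bs - ctx)
    hi <- min(nchar(bear), be + ctx)
    B <- substr(bear, lo, hi)
    L <- truth$tsd_length[i]
    te_start <- bs - lo + 1L + L
    te_end <- te_start + truth$te_length[i] - 1L
    # the empty-site window must start/end at positions homologous to the
    # B window ends: ep is the first base after the removal junction and
    # rm_bear0/rm_bear1 give the removed span in bearing coordinates
    pre <- truth$rm_bear0[i] - lo
    suf <- hi - truth$rm_bear1[i]
    elo <- max(1L, ep - pre)
    E <- substr(emp, elo,
                min(nchar(emp), ep + truth$filler_bp[i] + suf - 1L))
    r <- .resolveReplacement(B, E, te_start, te_end, L,
                             tolerate_snps = tolerate)
    if (!is.null(r)) {
      nd[i] <- r$deleted_bp
      nf[i] <- nchar(r$filler)
    }
  }
  truth$norm_deleted_bp <- nd
  truth$norm_filler_bp <- nf
  truth
}

# ---- fixture I/O --------------------------------------------------------

#' Write a simulated genome pair to disk
#'
#' Writes \code{genomeA.fasta}, \code{genomeB.fasta} (60-column FASTA),
#' \code{truth.tsv} (one row per ground-truth event) and
#' \code{config.yaml} as a reproducibility record.
#'
#' @param sim a \linkS4class{GenomePairSim}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeFixture <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Biostrings::writeXStringSet(sim@genomeA, file.path(dir, "genomeA.fasta"),
                              width = 60L)
  Biostrings::writeXStringSet(sim@genomeB, file.path(dir, "genomeB.fasta"),
                              width = 60L)
  utils::write.table(as.data.frame(sim@truth),
                     file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- sim@config
  cfg$gaps_realized <- NULL
  cfg$footprint$extreme_deletion_range <-
    as.numeric(cfg$footprint$extreme_deletion_range)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a ground-truth table written by \code{\link{writeFixture}}
#'
#' @param path path to \code{truth.tsv}.
#' @return \code{DataFrame} of ground-truth events.
#' @export
readTruth <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = NA, stringsAsFactors = FALSE,
                          na.strings = "NA", quote = "")
  for (col in c("tsd", "filler_seq", "family", "superfamily"))
    df[[col]][is.na(df[[col]])] <- ""
  S4Vectors::DataFrame(df)
}
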