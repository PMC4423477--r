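# Classification of TE-homologous indel events into insertions, excision
# footprint subtypes, internal deletions or unclear, with TSD detection and
# deletion/filler quantification.
#
# Footprint geometry is measured on homologous context windows B (bearing)
# and E (empty site): B and E start and end at orthologous positions, so
# len(B) - len(E) = removed - filler exactly. The replacement boundary is
# normalized by maximal flank extension (the same convention the simulator
# logs), because boundary placement is not always uniquely determined by
# the sequences.

# Resolve E = prefix(B) + filler + suffix(B): returns the matched prefix
# length i, the suffix start j in B, the filler string, and geometry
# relative to the TE interval [te_start, te_end] (B coordinates) with TSD
# length L. NULL when the removed region does not cover the TE.
.resolveReplacement <- function(B, E, te_start, te_end, L,
                                tolerate_snps = TRUE, slack = 3L) {
  i <- .matchedPrefixLen(B, E, tolerate_snps = tolerate_snps)
  s <- .matchedSuffixLen(B, E, tolerate_snps = tolerate_snps)
  s <- min(s, nchar(E) - i, nchar(B) - i)
  if (s < 0L) s <- 0L
  j <- nchar(B) - s + 1L
  filler <- if (nchar(E) - s >= i + 1L)
    substr(E, i + 1L, nchar(E) - s) else ""
  removed_len <- j - 1L - i
  if (i > te_start - 1L + slack || j < te_end + 1L - slack) return(NULL)
  extras <- removed_len - (te_end - te_start + 1L)
  left_extra <- te_start - 1L - i
  right_extra <- j - 1L - te_end
  deleted <- max(0L, extras - L)
  list(i = i, j = j, filler = filler, removed_len = removed_len,
       extras = extras, left_extra = left_extra,
       right_extra = right_extra, deleted_bp = deleted)
}

# TSD presence in the bearing sequence: compares the L bases flanking the
# TE on both sides; fixed motifs must match the motif set exactly, long
# variable TSDs (>= 8 bp) tolerate one mismatch between the copies.
.bearingTSD <- function(B, te_start, te_end, profile) {
  L <- profile@tsdLength
  if (te_start - L < 1L || te_end + L > nchar(B))
    return(list(found = FALSE, seq = "", mismatches = NA_integer_))
  up <- substr(B, te_start - L, te_start - 1L)
  down <- substr(B, te_end + 1L, te_end + L)
  mm <- .hamming(up, down)
  tol <- if (L >= 8L) 1L else 0L
  found <- mm <= tol
  motifs <- .tsdMotifs(profile)
  if (found && !is.null(motifs)) found <- up %in% motifs
  list(found = found, seq = up, mismatches = mm)
}

#' Detect a target-site duplication for an indel event
#'
#' Tests for the profile-length duplication immediately flanking the TE in
#' the bearing species and reports whether the empty site carries one TSD
#' copy (insertion signature) or two tandem copies (perfect-excision
#' signature). Fixed motifs (TA; TAA/TTA) must match exactly; variable
#' motifs of length >= 8 tolerate \code{max_mismatch_long} mismatches
#' between the two copies.
#'
#' @param event one event row from \code{\link{scanIndels}}.
#' @param te one annotation row from \code{\link{annotateSegment}} run on
#'   the event's extra sequence.
#' @param profile the \linkS4class{SuperfamilyProfile} of the annotated
#'   family.
#' @param border_slack tolerated distance between the TE annotation
#'   borders and the event borders (default 3 bp).
#' @param max_mismatch_long mismatch tolerance for long variable TSDs.
#' @return list: \code{found}, \code{sequence}, \code{length},
#'   \code{sides} ("both", "bearing-only", "none"), \code{mismatches},
#'   \code{empty_copies} (0, 1 or 2) and \code{reason}.
#' @export
detectTSD <- function(event, te, profile, border_slack = 3L,
                      max_mismatch_long = 1L) {
  L <- profile@tsdLength
  lm <- te$start - 1L
  rm_ <- event$length - te$end
  if (lm > L + border_slack && rm_ > L + border_slack)
    return(list(found = FALSE, sequence = "", length = L, sides = "none",
                mismatches = NA_integer_, empty_copies = 0L,
                reason = "internal"))
  geo <- .eventGeometry(event, te, profile)
  if (is.null(geo$res))
    return(list(found = FALSE, sequence = "", length = L, sides = "none",
                mismatches = NA_integer_, empty_copies = 0L,
                reason = "unresolved"))
  bt <- geo$tsd
  r <- geo$res
  # TSD copies at the empty-site junction; small shifts absorb boundary
  # ambiguity (a prefix extension into the element shifts the junction)
  E <- geo$E
  tandem <- 0L
  if (bt$found) {
    tol <- if (L >= 8L) max_mismatch_long else 0L
    copyAt <- function(start) {
      start >= 1L && start + L - 1L <= nchar(E) &&
        .hamming(substr(E, start, start + L - 1L), bt$seq) <= tol
    }
    fl <- nchar(r$filler)
    tandem <- max(vapply(0:3, function(s) {
      sum(copyAt(r$i - s - L + 1L), copyAt(r$i - s + fl + 1L))
    }, integer(1)))
  }
  list(found = bt$found, sequence = bt$seq, length = L,
       sides = if (bt$found) "both" else "none",
       mismatches = bt$mismatches, empty_copies = tandem,
       reason = if (bt$found) "" else "no-duplication")
}

# shared context construction for one event + TE annotation
.eventGeometry <- function(event, te, profile, bearing_seq = NULL,
                           empty_seq = NULL, tolerate_snps = TRUE) {
  bctx0 <- max(event$bctx0, event$bear_start - nchar(event$bear_up))
  bctx1 <- min(event$bctx1, event$bear_end + nchar(event$bear_down))
  ectx0 <- max(event$ectx0, event$empty_pos - nchar(event$empty_up) + 1L)
  ectx1 <- min(event$ectx1, event$empty_pos + nchar(event$empty_down))
  B <- paste0(substr(event$bear_up,
                     nchar(event$bear_up) - (event$bear_start - bctx0) + 1L,
                     nchar(event$bear_up)),
              event$extra,
              substr(event$bear_down, 1L, bctx1 - event$bear_end))
  off <- event$bear_start - bctx0  # bases of B before the extra seq
  E <- paste0(substr(event$empty_up,
                     nchar(event$empty_up) - (event$empty_pos - ectx0),
                     nchar(event$empty_up)),
              substr(event$empty_down, 1L, ectx1 - event$empty_pos))
  # prefer full-length borders inferred from consensus coordinates, but
  # only when the clipped part is small (edge fuzz, not a truncated copy)
  ts <- if (!is.null(te$full_start) && te$start - te$full_start <= 15L)
    te$full_start else te$start
  tn <- if (!is.null(te$full_end) && te$full_end - te$end <= 15L)
    te$full_end else te$end
  te_start <- off + ts
  te_end <- off + tn
  tsd <- .bearingTSD(B, te_start, te_end, profile)
  res <- .resolveReplacement(B, E, te_start, te_end, profile@tsdLength,
                             tolerate_snps = tolerate_snps)
  list(B = B, E = E, te_start = te_start, te_end = te_end, tsd = tsd,
       res = res)
}

#' Measure an excision footprint
#'
#' Quantifies, for an event with a TE annotation, the flanking bases
#' deleted at the empty site (bearing-species flank bases with no
#' counterpart) and the filler bases introduced (empty-site bases aligning
#' to neither the TE nor the bearing flanks).
#'
#' @inheritParams detectTSD
#' @param tolerate_snps absorb isolated substitutions when matching flanks
#'   (set FALSE on divergence-free data for exact measurement).
#' @return list with \code{deleted_bp}, \code{filler_bp},
#'   \code{filler_seq}; NULL geometry yields zeros.
#' @export
measureFootprint <- function(event, te, profile, tolerate_snps = TRUE) {
  geo <- .eventGeometry(event, te, profile, tolerate_snps = tolerate_snps)
  if (is.null(geo$res))
    return(list(deleted_bp = 0L, filler_bp = 0L, filler_seq = ""))
  list(deleted_bp = geo$res$deleted_bp,
       filler_bp = nchar(geo$res$filler), filler_seq = geo$res$filler)
}

#' Classify one TE-homologous indel event
#'
#' Applies the decision tree: (1) TE spanning the event with a TSD in the
#' bearing species, no filler and a removed span of TE + one TSD is an
#' insertion (acting species = bearing); (2) a removed span of exactly the
#' TE is a perfect excision (the empty site retains the tandem TSD); (3)
#' extra removed flank beyond the TE + TSD is an excision with deletion;
#' (4) empty-site sequence absent from the bearing locus is filler; (5)
#' both; (6) a TE annotation extending beyond the event borders on both
#' sides is an internal deletion (not transposition); (7) otherwise
#' unclear.
#'
#' @param event one event row from \code{\link{scanIndels}}.
#' @param annotations annotation \code{data.frame} for the event's extra
#'   sequence (\code{\link{annotateSegment}}); must be non-empty.
#' @param library the \linkS4class{TELibrary} (for flank re-annotation in
#'   the internal-deletion test).
#' @param min_coverage TE coverage of the extra sequence required for a
#'   transposition verdict (default 0.80).
#' @param border_slack tolerance between annotation and event borders.
#' @param tolerate_snps see \code{\link{measureFootprint}}.
#' @return one-row \code{data.frame}: verdict, family, superfamily,
#'   acting_species ("bearing"/"empty"), tsd fields, deleted_bp,
#'   filler_bp, filler_seq.
#' @export
classifyPolymorphism <- function(event, annotations, library,
                                 min_coverage = 0.80, border_slack = 3L,
                                 tolerate_snps = TRUE) {
  if (is.null(annotations) || !nrow(annotations))
    .stopf("classifyPolymorphism requires at least one TE annotation")
  te <- annotations[1L, ]
  profile <- superfamilyProfiles()[[te$superfamily]]
  L <- profile@tsdLength
  out <- data.frame(verdict = "unclear", family = te$family,
                    superfamily = te$superfamily,
                    acting_species = NA_character_, tsd_found = FALSE,
                    tsd_seq = "", deleted_bp = 0L, filler_bp = 0L,
                    filler_seq = "", stringsAsFactors = FALSE)
  cover <- (min(te$end, event$length) - max(te$start, 1L) + 1L) /
    event$length
  # (6) internal deletion: the element continues into both flanks
  ext <- .annotationExtendsBeyond(event, library, te, border_slack)
  if (ext$both) {
    out$verdict <- "internal-deletion"
    out$acting_species <- "empty"
    return(out)
  }
  geo <- .eventGeometry(event, te, profile, tolerate_snps = tolerate_snps)
  if (is.null(geo$res)) return(out)
  r <- geo$res
  tsd <- geo$tsd
  if (cover < min_coverage) {
    # an excision-triggered deletion can dwarf the element itself; admit
    # the excision verdict when the annotation coincides with one event
    # border and the remainder is removed flanking sequence
    abuts <- te$start <= 1L + border_slack ||
      te$end >= event$length - border_slack
    if (abuts && r$extras > L + border_slack) {
      fl0 <- nchar(r$filler)
      out$verdict <- if (fl0 > 2L) "excision-both" else "excision-deletion"
      out$acting_species <- "empty"
      out$deleted_bp <- r$deleted_bp
      out$filler_bp <- if (fl0 > 2L) fl0 else 0L
      out$filler_seq <- if (fl0 > 2L) r$filler else ""
      out$tsd_found <- tsd$found
      out$tsd_seq <- tsd$seq
    }
    return(out)
  }
  out$tsd_found <- tsd$found
  out$tsd_seq <- tsd$seq
  fl <- nchar(r$filler)
  ins_slack <- min(border_slack, L - 1L)
  if (tsd$found && fl <= 2L && abs(r$extras - L) <= ins_slack) {
    out$verdict <- "insertion"
    out$acting_species <- "bearing"
    out$filler_seq <- ""
  } else if (fl == 0L && abs(r$extras) <= border_slack) {
    out$verdict <- "excision-perfect"
    out$acting_species <- "empty"
  } else if (fl == 0L && r$extras > border_slack) {
    out$verdict <- "excision-deletion"
    out$acting_species <- "empty"
    out$deleted_bp <- r$deleted_bp
  } else if (fl > 0L && r$extras <= border_slack) {
    out$verdict <- "excision-filler"
    out$acting_species <- "empty"
    out$filler_bp <- fl
    out$filler_seq <- r$filler
  } else if (fl > 0L) {
    out$verdict <- "excision-both"
    out$acting_species <- "empty"
    out$deleted_bp <- r$deleted_bp
    out$filler_bp <- fl
    out$filler_seq <- r$filler
  }
  out
}

# does the family annotation continue beyond the event borders into the
# bearing flanks? (internal-deletion signature)
.annotationExtendsBeyond <- function(event, library, te, slack,
                                     probe_bp = 60L) {
  idx <- match(te$family, library@info$family)
  cons <- as.character(library@consensus[[idx]])
  up <- substr(event$bear_up, max(1L, nchar(event$bear_up) - probe_bp + 1L),
               nchar(event$bear_up))
  down <- substr(event$bear_down, 1L, probe_bp)
  # the consensus coordinates of the hit say how much of the element is
  # expected to continue into each flank (an interior hit continues on
  # both sides; a full-length hit on neither)
  exp5 <- if (!is.null(te$full_start)) te$start - te$full_start else probe_bp
  exp3 <- if (!is.null(te$full_end)) te$full_end - te$end else probe_bp
  probeHit <- function(flank, expected) {
    want <- min(probe_bp, expected)
    if (want < 20L || nchar(flank) < want) return(FALSE)
    r1 <- .swLocal(flank, cons)
    r2 <- .swLocal(flank, .revcomp(cons))
    r <- if (r1$score >= r2$score) r1 else r2
    r$columns >= 0.6 * want && r$identity >= 0.7
  }
  leftext <- te$start <= 1L + slack && exp5 >= 20L && probeHit(up, exp5)
  rightext <- te$end >= event$length - slack && exp3 >= 20L &&
    probeHit(down, exp3)
  list(both = leftext && rightext, left = leftext, right = rightext)
}

#' Classify all TE-homologous events of an event table
#'
#' Annotates each event's extra sequence against the library and applies
#' \code{\link{classifyPolymorphism}} to those with TE homology. Events
#' without TE homology are returned with verdict "non-TE".
#'
#' @param events \code{DataFrame} of filtered indel events.
#' @param library a \linkS4class{TELibrary}.
#' @param species_names length-2 named character vector mapping
#'   \code{query}/\code{target} to species labels.
#' @param min_len,min_identity annotation admission thresholds.
#' @param tolerate_snps see \code{\link{measureFootprint}}.
#' @return \code{data.frame} of calls, one row per event.
#' @export
callPolymorphisms <- function(events, library,
                              species_names = c(query = "A", target = "B"),
                              min_len = 50L, min_identity = 0.70,
                              tolerate_snps = TRUE) {
  calls <- list()
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    ann <- annotateSegment(e$extra, library, min_len = min_len,
                           min_identity = min_identity)
    bearing_sp <- species_names[[e$bearing]]
    empty_sp <- setdiff(unname(species_names), bearing_sp)
    base <- data.frame(event_id = e$event_id, bearing_species = bearing_sp,
                       bear_start = e$bear_start, bear_end = e$bear_end,
                       empty_pos = e$empty_pos, length = e$length,
                       stringsAsFactors = FALSE)
    if (!nrow(ann)) {
      calls[[i]] <- cbind(base, data.frame(
        verdict = "non-TE", family = NA_character_,
        superfamily = NA_character_, acting_species = NA_character_,
        tsd_found = FALSE, tsd_seq = "", deleted_bp = 0L, filler_bp = 0L,
        filler_seq = "", stringsAsFactors = FALSE))
      next
    }
    cl <- classifyPolymorphism(e, ann, library,
                               tolerate_snps = tolerate_snps)
    cl$acting_species <- if (is.na(cl$acting_species)) NA_character_
    else switch(cl$acting_species, bearing = bearing_sp, empty = empty_sp)
    calls[[i]] <- cbind(base, cl)
  }
  if (!length(calls))
    return(data.frame(event_id = integer(0), bearing_species = character(0),
                      bear_start = integer(0), bear_end = integer(0),
                      empty_pos = integer(0), length = integer(0),
                      verdict = character(0), family = character(0),
                      superfamily = character(0),
                      acting_species = character(0), tsd_found = logical(0),
                      tsd_seq = character(0), deleted_bp = integer(0),
                      filler_bp = integer(0), filler_seq = character(0)))
  do.call(rbind, calls)
}

#' Summarize excision footprints over a call set
#'
#' Returns global and per-superfamily verdict counts, deletion totals and
#' means with and without outliers beyond \code{outlier_threshold}, and
#' filler statistics. Because the denominator of a "mean deletion per
#' excision" is ambiguous, both the mean over deletion-bearing events and
#' the mean over all excisions are reported.
#'
#' @param calls \code{data.frame} of calls.
#' @param outlier_threshold deletions larger than this are excluded from
#'   the "excluding outliers" statistics (default 1000 bp).
#' @return named list of summary statistics.
#' @export
summarizeFootprints <- function(calls, outlier_threshold = 1000L) {
  exc_kinds <- c("excision-perfect", "excision-deletion", "excision-filler",
                 "excision-both")
  verdicts <- c("insertion", exc_kinds, "internal-deletion", "unclear",
                "non-TE")
  counts <- vapply(verdicts, function(v) sum(calls$verdict == v),
                   integer(1))
  exc <- calls[calls$verdict %in% exc_kinds, , drop = FALSE]
  deld <- exc$deleted_bp[exc$deleted_bp > 0L]
  outl <- deld[deld > outlier_threshold]
  dels <- deld[deld <= outlier_threshold]
  fill <- exc$filler_bp[exc$filler_bp > 0L]
  per_sf <- table(factor(calls$superfamily,
                         levels = c("DTT", "DTH", "DTM", "DTC", "DTA")),
                  factor(calls$verdict, levels = verdicts))
  list(counts = counts,
       n_excisions = nrow(exc),
       n_perfect = counts[["excision-perfect"]],
       n_with_deletion = sum(exc$deleted_bp > 0L),
       n_with_filler = sum(exc$filler_bp > 0L),
       n_both = sum(exc$deleted_bp > 0L & exc$filler_bp > 0L),
       total_deleted_bp = sum(deld),
       total_deleted_bp_excl_outliers = sum(dels),
       outlier_deleted_bp = sum(outl),
       mean_deleted_per_deletion_event =
         if (length(dels)) mean(dels) else 0,
       mean_deleted_per_excision =
         if (nrow(exc)) sum(dels) / nrow(exc) else 0,
       total_filler_bp = sum(fill),
       mean_filler_bp = if (length(fill)) mean(fill) else 0,
       min_filler_bp = if (length(fill)) min(fill) else 0,
       max_filler_bp = if (length(fill)) max(fill) else 0,
       per_superfamily = per_sf)
}
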