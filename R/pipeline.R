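# End-to-end orchestration: genomes in, classified polymorphism calls out,
# plus recovery evaluation against a simulator ground-truth log.

#' Run the full polymorphism-calling pipeline on a genome pair
#'
#' Aligns the two genomes (anchoring, 12-kb windows, assembly), scans the
#' assembled alignments for indels larger than 50 bp, merges adjacent
#' events, discards events bordering assembly gaps or failing the
#' 200 bp / 90\% flank-quality rule, flags N-rich events, and classifies
#' the TE-homologous remainder.
#'
#' @param genomeA,genomeB \code{DNAStringSet} genomes (species A is the
#'   alignment query).
#' @param library a \linkS4class{TELibrary}.
#' @param min_indel_len indel size threshold (strictly larger; default 50).
#' @param tolerate_snps passed to the classifier (set FALSE for
#'   divergence-free data).
#' @param ... passed to \code{\link{alignGenomes}}.
#' @return list with \code{alignments}, \code{events_raw}, \code{events}
#'   (filtered), \code{dropped_gap_adjacent}, \code{n_rich} (flags),
#'   \code{calls} and \code{summary}.
#' @export
runPipeline <- function(genomeA, genomeB, library, min_indel_len = 50L,
                        tolerate_snps = TRUE, ...) {
  genomeA <- Biostrings::DNAStringSet(genomeA)
  genomeB <- Biostrings::DNAStringSet(genomeB)
  alns <- alignGenomes(genomeA, genomeB, ...)
  all_events <- list()
  for (qc in names(alns)) {
    ca <- alns[[qc]]
    qseq <- as.character(genomeA[[qc]])
    tseq <- as.character(genomeB[[ca@targetName]])
    ev <- scanIndels(ca, qseq, tseq, min_len = min_indel_len)
    ev <- mergeAdjacentIndels(ev, qseq, tseq)
    if (nrow(ev)) ev$qchrom <- qc
    all_events[[qc]] <- ev
  }
  events_raw <- if (length(all_events)) do.call(rbind, all_events)
  else .emptyEvents()
  gg <- dropGapAdjacent(events_raw)
  kept <- gg$kept
  nrich <- classifyNContent(gg$dropped)
  kept <- kept[kept$flank_quality, ]
  if (nrow(kept)) kept$event_id <- seq_len(nrow(kept))
  calls <- callPolymorphisms(kept, library, tolerate_snps = tolerate_snps)
  list(alignments = alns, events_raw = events_raw, events = kept,
       dropped_gap_adjacent = gg$dropped, n_rich = nrich, calls = calls,
       summary = summarizeFootprints(calls))
}

#' Evaluate pipeline calls against a simulator ground truth
#'
#' Matches each planted transposition event (by bearing-species interval
#' overlap within \code{tol} bp) to a call and scores verdict agreement.
#' Precise excisions are expected to be reported as insertions of the
#' bearing species (they are indistinguishable by comparative analysis),
#' so that forced relabeling counts as the expected verdict.
#'
#' @param calls call \code{data.frame} from the pipeline (species labels
#'   "A"/"B").
#' @param truth ground-truth \code{DataFrame} from
#'   \code{\link{simulateGenomePair}}.
#' @param tol matching tolerance in bp (default 50).
#' @return list with the per-kind table, \code{overall_recovery}
#'   (fraction of planted insertions/excisions with the correct verdict),
#'   \code{insertion_recovery}, \code{perfect_recovery}, and the matched
#'   pairs table.
#' @export
evaluateRecovery <- function(calls, truth, tol = 50L) {
  exp_map <- c(insertion = "insertion",
               "excision-perfect" = "excision-perfect",
               "excision-deletion" = "excision-deletion",
               "excision-filler" = "excision-filler",
               "excision-both" = "excision-both",
               "precise-excision" = "insertion",
               "internal-deletion" = "internal-deletion")
  tt <- truth[truth$kind %in% names(exp_map), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(tt))) {
    tr <- tt[i, ]
    # bearing species: the one carrying the extra sequence
    bearing <- if (tr$kind == "insertion") tr$species
    else if (tr$kind == "precise-excision") setdiff(c("A", "B"), tr$species)
    else setdiff(c("A", "B"), tr$species)
    if (bearing == "A") { lo <- tr$startA; hi <- tr$endA }
    else { lo <- tr$startB; hi <- tr$endB }
    cand <- calls[calls$bearing_species == bearing &
                    calls$bear_start <= hi + tol &
                    calls$bear_end >= lo - tol, , drop = FALSE]
    got <- nrow(cand) > 0L
    verdict <- if (got) cand$verdict[1L] else NA_character_
    deleted <- if (got) cand$deleted_bp[1L] else NA_integer_
    filler <- if (got) cand$filler_bp[1L] else NA_integer_
    rows[[i]] <- data.frame(
      event_id = tr$event_id, kind = tr$kind,
      expected = exp_map[[tr$kind]], detected = got,
      verdict = verdict,
      correct = got && identical(verdict, exp_map[[tr$kind]]),
      true_deleted = tr$deleted_bp, true_filler = tr$filler_bp,
      norm_deleted = tr$norm_deleted_bp, norm_filler = tr$norm_filler_bp,
      called_deleted = deleted, called_filler = filler,
      stringsAsFactors = FALSE)
  }
  m <- do.call(rbind, rows)
  trans <- m$kind %in% c("insertion", "excision-perfect",
                         "excision-deletion", "excision-filler",
                         "excision-both")
  per_kind <- do.call(rbind, lapply(split(m, m$kind), function(d)
    data.frame(kind = d$kind[1L], n = nrow(d), detected = sum(d$detected),
               correct = sum(d$correct))))
  list(matches = m, per_kind = per_kind,
       overall_recovery = mean(m$correct[trans]),
       insertion_recovery = mean(m$correct[m$kind == "insertion"]),
       perfect_recovery =
         if (any(m$kind == "excision-perfect"))
           mean(m$correct[m$kind == "excision-perfect"]) else NA_real_,
       precise_as_insertion =
         if (any(m$kind == "precise-excision"))
           mean(m$correct[m$kind == "precise-excision"]) else NA_real_)
}
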