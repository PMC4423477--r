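# Insertion:excision ratio statistics, activity/abundance groupings,
# fixation-rate arithmetic, hidden-TE gap attribution and gene-context
# classification.

#' Test an insertion:excision ratio against the 2:1 expectation
#'
#' Under the replication-fork proliferation model the expected
#' insertion:excision ratio between two equally active species is 2:1.
#' The primary test is a two-sided exact binomial test of the insertion
#' count against success probability expected/(expected+1) over
#' insertions + excisions trials. A second p-value from an exact 2x2 test
#' (observed counts vs rounded expected counts) is co-reported for
#' transparency; the two constructions can differ.
#'
#' @param insertions,excisions observed counts (sum must be positive).
#' @param expected expected ratio (default 2).
#' @param alpha significance level for the flag (default 0.05).
#' @return list: insertions, excisions, ratio (NA when excisions = 0,
#'   flagged \code{ratio_defined = FALSE}), expected, p_value (binomial),
#'   p_value_fisher, significant.
#' @examples
#' ratioTest(90, 11)$ratio   # 8.18
#' @export
ratioTest <- function(insertions, excisions, expected = 2, alpha = 0.05) {
  n <- insertions + excisions
  if (n <= 0) .stopf("insertions + excisions must be positive")
  p0 <- expected / (expected + 1)
  bt <- stats::binom.test(insertions, n, p = p0,
                          alternative = "two.sided")
  exp_ins <- round(n * p0)
  ft <- stats::fisher.test(cbind(c(insertions, excisions),
                                 c(exp_ins, n - exp_ins)))
  list(insertions = insertions, excisions = excisions,
       ratio = if (excisions > 0) insertions / excisions else NA_real_,
       ratio_defined = excisions > 0, expected = expected,
       p_value = bt$p.value, p_value_fisher = ft$p.value,
       significant = bt$p.value < alpha)
}

#' Ratio tests for a table of superfamily/species counts
#'
#' @param counts \code{data.frame} with columns \code{superfamily},
#'   \code{species}, \code{insertions}, \code{excisions}.
#' @param expected,alpha passed to \code{\link{ratioTest}}.
#' @return \code{data.frame} with ratio and p-value columns appended.
#' @export
ratioTable <- function(counts, expected = 2, alpha = 0.05) {
  res <- lapply(seq_len(nrow(counts)), function(i) {
    r <- ratioTest(counts$insertions[i], counts$excisions[i], expected,
                   alpha)
    data.frame(ratio = r$ratio, p_value = r$p_value,
               p_value_fisher = r$p_value_fisher,
               significant = r$significant)
  })
  cbind(counts, do.call(rbind, res))
}

#' Fixation-rate arithmetic
#'
#' The per-generation fixation rate of transposition events equals the
#' number of fixed events divided by the number of generations since
#' divergence (for neutral events the population size cancels).
#'
#' @param n_events fixed transposition events since divergence.
#' @param generations generations since divergence (> 0).
#' @param digits precision to which the rate is reported; the reciprocal
#'   ("one event per N individuals") is computed from the reported rate,
#'   as such figures are quoted.
#' @return list: \code{rate_raw}, \code{rate} (rounded to \code{digits}),
#'   and \code{one_in_n} (round(1/rate); NA when the rate is 0).
#' @examples
#' fixationRate(2300, 600000)  # rate 0.004, one in 250
#' @export
fixationRate <- function(n_events, generations, digits = 3) {
  if (generations <= 0) .stopf("generations must be positive")
  raw <- n_events / generations
  rate <- round(raw, digits)
  list(rate_raw = raw, rate = rate,
       one_in_n = if (rate > 0) round(1 / rate) else NA_real_)
}

#' Extrapolate transposition counts from a manually inspected subset
#'
#' @param n_confirmed events confirmed as transpositions in the subset.
#' @param n_inspected size of the inspected subset.
#' @param n_total total TE-homologous polymorphisms to extrapolate to
#'   (optional).
#' @return list: \code{yield} (fraction), \code{yield_percent},
#'   \code{extrapolated} (yield * n_total, NA if n_total missing).
#' @export
extrapolatePolymorphisms <- function(n_confirmed, n_inspected,
                                     n_total = NA) {
  y <- n_confirmed / n_inspected
  list(yield = y, yield_percent = 100 * y, extrapolated = y * n_total)
}

#' Gap-attribution arithmetic
#'
#' @param total_gaps all assembly gaps (> 50 Ns).
#' @param mappable_gaps gaps whose both flanks map to the other genome.
#' @param te_positive_gaps mappable gaps whose orthologous segment shows
#'   TE homology.
#' @param n_rich_events N-rich presence polymorphisms to which the TE
#'   fraction is also applied (optional).
#' @return list with \code{te_fraction}, \code{extrapolated_te_gaps}
#'   (te_fraction * total_gaps, unrounded) and
#'   \code{extrapolated_hidden_polymorphisms}.
#' @export
gapAttribution <- function(total_gaps, mappable_gaps, te_positive_gaps,
                           n_rich_events = NA) {
  tf <- if (mappable_gaps > 0) te_positive_gaps / mappable_gaps else 0
  list(total_gaps = total_gaps, mappable_gaps = mappable_gaps,
       te_positive_gaps = te_positive_gaps, te_fraction = tf,
       extrapolated_te_gaps = tf * total_gaps,
       extrapolated_hidden_polymorphisms = tf * n_rich_events)
}

#' Attribute assembly gaps to hidden transposons
#'
#' For each N run longer than 50 bp in \code{gapped_genome}, maps 500 bp
#' of both flanks onto \code{other_genome}; gaps whose flanks both map in
#' the same orientation within \code{max_span} of each other are
#' "mappable", and the intervening segment of the other genome is screened
#' against the TE library. The TE-positive fraction is extrapolated to all
#' gaps (and optionally to N-rich polymorphisms).
#'
#' @param gapped_genome,other_genome single-chromosome sequences (strings
#'   or \code{DNAStringSet} of length 1).
#' @param library a \linkS4class{TELibrary}.
#' @param flank_bp flank length mapped (default 500).
#' @param max_span maximum distance between mapped flanks (default 10 kb).
#' @param min_hit_len,min_hit_id flank mapping thresholds (400 bp, 0.95).
#' @param n_rich_events optional count of N-rich polymorphisms.
#' @return a \code{\link{gapAttribution}} list plus the per-gap table.
#' @export
extrapolateHiddenTeGaps <- function(gapped_genome, other_genome, library,
                                    flank_bp = 500L, max_span = 10000L,
                                    min_hit_len = 400L, min_hit_id = 0.95,
                                    n_rich_events = NA) {
  g <- if (is(gapped_genome, "DNAStringSet"))
    as.character(gapped_genome[[1L]]) else as.character(gapped_genome)
  o <- if (is(other_genome, "DNAStringSet"))
    as.character(other_genome[[1L]]) else as.character(other_genome)
  runs <- .runsOf(.chars(g), "N")
  runs <- runs[runs$length > 50L, , drop = FALSE]
  if (!nrow(runs)) {
    att <- gapAttribution(0L, 0L, 0L, n_rich_events)
    att$per_gap <- data.frame()
    return(att)
  }
  mappable <- 0L; te_pos <- 0L
  rows <- list()
  for (i in seq_len(nrow(runs))) {
    up <- substr(g, max(1L, runs$start[i] - flank_bp), runs$start[i] - 1L)
    down <- substr(g, runs$end[i] + 1L,
                   min(nchar(g), runs$end[i] + flank_bp))
    ok <- FALSE; te <- FALSE
    if (nchar(up) >= min_hit_len && nchar(down) >= min_hit_len) {
      hu <- .searchGenome(up, o, min_len = min_hit_len,
                          min_identity = min_hit_id)
      hd <- .searchGenome(down, o, min_len = min_hit_len,
                          min_identity = min_hit_id)
      if (nrow(hu) && nrow(hd)) {
        hu <- hu[which.max(hu$score), ]
        hd <- hd[which.max(hd$score), ]
        gap0 <- hu$tend; gap1 <- hd$tstart
        if (hu$strand == hd$strand && gap1 > gap0 &&
            (gap1 - gap0) <= max_span) {
          ok <- TRUE
          seg <- substr(o, gap0 + 1L, gap1 - 1L)
          if (nchar(seg) >= 50L) {
            ann <- annotateSegment(seg, library)
            te <- nrow(ann) > 0L
          }
        }
      }
    }
    mappable <- mappable + ok
    te_pos <- te_pos + (ok && te)
    rows[[i]] <- data.frame(start = runs$start[i], end = runs$end[i],
                            mappable = ok, te_positive = ok && te)
  }
  att <- gapAttribution(nrow(runs), mappable, te_pos, n_rich_events)
  att$per_gap <- do.call(rbind, rows)
  att
}

#' Relative activity and abundance of TE families
#'
#' Relative activity is the number of copies of a family that moved
#' divided by its total copy number; relative abundance is the family's
#' copy number divided by the total number of DNA transposons in the
#' genome. Active families are split at the medians of the two quantities:
#' group I (both high), II (active but rare), III (abundant but quiet);
#' families with zero moved copies are "inactive".
#'
#' @param copy_counts \code{data.frame} with columns \code{family},
#'   \code{superfamily}, \code{copies}.
#' @param calls optional call \code{data.frame}; moved copies are counted
#'   as transposition verdicts (insertion or excision) per family.
#' @param moved optional named vector of moved-copy counts per family
#'   (used instead of \code{calls}).
#' @return \code{data.frame} with activity, abundance and group columns.
#' @export
relativeActivityTable <- function(copy_counts, calls = NULL, moved = NULL) {
  if (is.null(moved)) {
    kinds <- c("insertion", "excision-perfect", "excision-deletion",
               "excision-filler", "excision-both")
    tr <- calls[calls$verdict %in% kinds, , drop = FALSE]
    moved <- table(tr$family)
  }
  m <- as.integer(moved[match(copy_counts$family, names(moved))])
  m[is.na(m)] <- 0L
  if (any(m > 0L & copy_counts$copies == 0L))
    .stopf("family with zero copies but moved calls: %s",
           copy_counts$family[m > 0L & copy_counts$copies == 0L][1L])
  act <- ifelse(copy_counts$copies > 0, m / copy_counts$copies, 0)
  abund <- copy_counts$copies / sum(copy_counts$copies)
  active <- m > 0L
  group <- rep("inactive", nrow(copy_counts))
  if (any(active)) {
    medA <- stats::median(act[active])
    medB <- stats::median(abund[active])
    group[active & act >= medA & abund >= medB] <- "I"
    group[active & act >= medA & abund < medB] <- "II"
    group[active & act < medA] <- "III"
  }
  data.frame(copy_counts, moved = m, relative_activity = act,
             relative_abundance = abund, group = group,
             stringsAsFactors = FALSE)
}

#' Gamete-transmission simulation of the expected insertion:excision ratio
#'
#' Under the replication-fork model an element excises from a replicated
#' chromatid and reinserts ahead of the fork, producing two gamete types:
#' one with the donor copy retained plus the new copy, one with the donor
#' site excised plus the new copy. A fixed lineage samples one type per
#' event, so in a cross-species comparison every event contributes one
#' insertion polymorphism and, with probability 1/2, one excision
#' polymorphism: the expected ratio is 2:1. Transpositions outside S phase
#' (probability 1 - \code{p_replicative}) contribute one insertion and one
#' excision.
#'
#' @param n_events transposition events per replicate.
#' @param n_replicates number of replicates.
#' @param p_replicative fraction of events transposing ahead of the fork.
#' @return list with the per-replicate \code{ratios} and their
#'   \code{mean_ratio}.
#' @export
simulateGameteTransmission <- function(n_events = 200L,
                                       n_replicates = 1000L,
                                       p_replicative = 1) {
  n_rep <- stats::rbinom(n_replicates, n_events, p_replicative)
  exc <- stats::rbinom(n_replicates, n_rep, 0.5) + (n_events - n_rep)
  ratios <- ifelse(exc > 0, n_events / exc, NA_real_)
  list(ratios = ratios, mean_ratio = mean(ratios, na.rm = TRUE))
}

#' Classify polymorphism positions relative to gene models
#'
#' Assigns each polymorphism one context: exon, intron, upstream (within
#' \code{upstream_bp} 5' of the coding sequence, strand-aware), downstream
#' (within \code{downstream_bp} 3'), or intergenic, with precedence in
#' that order. When a position falls in the windows of two genes the
#' closest coding sequence wins (ties to the lexicographically smaller
#' gene id). Gene models whose attributes mention "transpos" are removed
#' before classification; gene models lacking strand are skipped with a
#' warning.
#'
#' @param positions \code{GRanges} of polymorphism positions (or a
#'   \code{data.frame} with \code{chrom} and \code{pos}).
#' @param gene_models a GFF3 path or a \code{GRanges} with \code{type}
#'   ("gene", "exon", "CDS"), \code{ID}/\code{Parent} attributes and
#'   strand.
#' @param upstream_bp,downstream_bp context window sizes (1000 / 500).
#' @return list with \code{assignments} (data.frame) and \code{counts}
#'   (named vector over the five contexts).
#' @export
geneContext <- function(positions, gene_models, upstream_bp = 1000L,
                        downstream_bp = 500L) {
  if (is.character(gene_models))
    gene_models <- rtracklayer::import(gene_models)
  gm <- gene_models
  meta <- as.data.frame(S4Vectors::mcols(gm))
  desc <- apply(meta, 1L, function(r)
    paste(unlist(r), collapse = " "))
  drop_te <- grepl("transpos", desc, ignore.case = TRUE)
  gm <- gm[!drop_te]
  meta <- meta[!drop_te, , drop = FALSE]
  if (is(positions, "GRanges")) {
    pos_df <- data.frame(chrom = as.character(GenomicRanges::seqnames(positions)),
                         pos = floor((GenomicRanges::start(positions) +
                                        GenomicRanges::end(positions)) / 2))
  } else {
    pos_df <- data.frame(chrom = as.character(positions$chrom),
                         pos = positions$pos)
  }
  types <- as.character(meta$type)
  ids <- if ("ID" %in% names(meta)) as.character(meta$ID) else
    rep(NA_character_, length(gm))
  parents <- if ("Parent" %in% names(meta))
    vapply(meta$Parent, function(p)
      if (length(unlist(p))) as.character(unlist(p)[1L]) else NA_character_,
      character(1))
  else rep(NA_character_, length(gm))
  gene_idx <- which(types == "gene")
  strands <- as.character(GenomicRanges::strand(gm))
  genes <- list()
  for (k in gene_idx) {
    gid <- ids[k]
    if (strands[k] == "*") {
      warning(sprintf("gene %s lacks strand; skipped", gid))
      next
    }
    kids <- which(parents == gid | (!is.na(parents) &
                                      grepl(paste0("^", gid), parents)))
    cds <- kids[types[kids] == "CDS"]
    ex <- kids[types[kids] == "exon"]
    cds_lo <- if (length(cds)) min(GenomicRanges::start(gm)[cds]) else
      GenomicRanges::start(gm)[k]
    cds_hi <- if (length(cds)) max(GenomicRanges::end(gm)[cds]) else
      GenomicRanges::end(gm)[k]
    genes[[length(genes) + 1L]] <- list(
      id = gid, chrom = as.character(GenomicRanges::seqnames(gm)[k]),
      strand = strands[k],
      lo = GenomicRanges::start(gm)[k], hi = GenomicRanges::end(gm)[k],
      cds_lo = cds_lo, cds_hi = cds_hi,
      exons = cbind(GenomicRanges::start(gm)[ex],
                    GenomicRanges::end(gm)[ex]))
  }
  classify1 <- function(chrom, p) {
    best <- NULL; best_ctx <- "intergenic"; best_d <- Inf
    for (gn in genes) {
      if (gn$chrom != chrom) next
      plus <- gn$strand == "+"
      up_lo <- if (plus) gn$cds_lo - upstream_bp else gn$cds_hi + 1L
      up_hi <- if (plus) gn$cds_lo - 1L else gn$cds_hi + upstream_bp
      dn_lo <- if (plus) gn$cds_hi + 1L else gn$cds_lo - downstream_bp
      dn_hi <- if (plus) gn$cds_hi + downstream_bp else gn$cds_lo - 1L
      ctx <- NULL
      if (nrow(gn$exons) &&
          any(p >= gn$exons[, 1L] & p <= gn$exons[, 2L])) ctx <- "exon"
      else if (p >= gn$lo && p <= gn$hi) ctx <- "intron"
      else if (p >= up_lo && p <= up_hi) ctx <- "upstream"
      else if (p >= dn_lo && p <= dn_hi) ctx <- "downstream"
      if (is.null(ctx)) next
      d <- min(abs(p - gn$cds_lo), abs(p - gn$cds_hi))
      if (d < best_d || (d == best_d && !is.null(best) &&
                         gn$id < best$id)) {
        best <- gn; best_ctx <- ctx; best_d <- d
      }
    }
    best_ctx
  }
  ctx <- vapply(seq_len(nrow(pos_df)), function(i)
    classify1(pos_df$chrom[i], pos_df$pos[i]), character(1))
  counts <- vapply(c("exon", "intron", "upstream", "downstream",
                     "intergenic"), function(k) sum(ctx == k), integer(1))
  list(assignments = data.frame(pos_df, context = ctx,
                                stringsAsFactors = FALSE),
       counts = counts)
}
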