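#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Superfamily target-site and TIR diagnostics
#'
#' One profile per TIR-order DNA transposon superfamily, holding the
#' diagnostic target-site duplication (TSD) motif and length and the
#' 5'-terminal TIR consensus. The five canonical superfamilies are
#' Mariner (DTT), Harbinger (DTH), Mutator (DTM), CACTA (DTC) and hAT (DTA).
#'
#' @slot code 3-letter superfamily code.
#' @slot tsdMotif fixed target-site motif(s), or \code{"variable"}.
#' @slot tsdLength TSD length in bp.
#' @slot tirConsensus 5'-terminal TIR motif; alternatives written
#'   \code{"(A/G)"} at a single position.
#' @exportClass SuperfamilyProfile
setClass("SuperfamilyProfile",
  representation(code = "character", tsdMotif = "character",
                 tsdLength = "integer", tirConsensus = "character"),
  validity = function(object) {
    msg <- NULL
    if (!object@code %in% c("DTT", "DTH", "DTM", "DTC", "DTA"))
      msg <- c(msg, "code must be one of DTT, DTH, DTM, DTC, DTA")
    if (!object@tsdLength %in% c(2L, 3L, 8L, 9L))
      msg <- c(msg, "tsdLength must be one of 2, 3, 8, 9")
    if (identical(object@tsdMotif, "TA") && object@tsdLength != 2L)
      msg <- c(msg, "motif TA pairs with length 2")
    if (identical(object@tsdMotif, "TAA/TTA") && object@tsdLength != 3L)
      msg <- c(msg, "motif TAA/TTA pairs with length 3")
    if (!nzchar(object@tirConsensus) ||
        grepl("[^ACGTRYSWKMBDHVN()/]", object@tirConsensus))
      msg <- c(msg, "tirConsensus must be a non-empty nucleotide motif")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "SuperfamilyProfile", function(object) {
  cat(sprintf("SuperfamilyProfile %s: TSD %s (%d bp), TIR %s\n",
              object@code, object@tsdMotif, object@tsdLength,
              object@tirConsensus))
})

#' A classified library of TE consensus sequences
#'
#' Wraps a \code{DNAStringSet} of family consensus sequences with per-family
#' metadata (superfamily code and provenance). Family names are unique;
#' consensus sequences are at least 50 bp; superfamily codes are restricted
#' to the five TIR-order Class II codes.
#'
#' @slot consensus \code{DNAStringSet}, one entry per family.
#' @slot info \code{DataFrame} with columns \code{family}, \code{superfamily},
#'   \code{source} ("library" or "discovered").
#' @exportClass TELibrary
setClass("TELibrary",
  representation(consensus = "DNAStringSet", info = "DataFrame"),
  validity = function(object) {
    msg <- NULL
    fam <- object@info$family
    if (length(object@consensus) != nrow(object@info))
      msg <- c(msg, "consensus and info must have matching lengths")
    if (anyDuplicated(fam))
      msg <- c(msg, sprintf("duplicate family name: %s",
                            fam[duplicated(fam)][1L]))
    if (length(object@consensus) &&
        any(Biostrings::width(object@consensus) < 50L))
      msg <- c(msg, "all consensus sequences must be >= 50 bp")
    if (!all(object@info$superfamily %in% c("DTT", "DTH", "DTM", "DTC", "DTA")))
      msg <- c(msg, "superfamily codes must be TIR-order Class II codes")
    if (!all(object@info$source %in% c("library", "discovered")))
      msg <- c(msg, "source must be 'library' or 'discovered'")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "TELibrary", function(object) {
  tab <- table(object@info$superfamily)
  cat(sprintf("TELibrary with %d families (%s)\n", length(object@consensus),
              paste(sprintf("%s:%d", names(tab), as.integer(tab)),
                    collapse = ", ")))
})

#' @describeIn TELibrary number of families
#' @param x a \code{TELibrary}
#' @export
setMethod("length", "TELibrary", function(x) length(x@consensus))

#' Assembled pairwise alignment of one chromosome pair
#'
#' Ordered, non-overlapping aligned blocks covering the anchored regions of a
#' query/target chromosome pair. Each block records its query and target
#' intervals (1-based, inclusive), the two gapped rows, and the index of the
#' source 12-kb window it was cut from.
#'
#' @slot queryName,targetName chromosome names.
#' @slot blocks \code{data.frame} with columns \code{qstart}, \code{qend},
#'   \code{tstart}, \code{tend}, \code{qrow}, \code{trow}, \code{window}.
#' @slot conflicts \code{data.frame} log of irreconcilable window overlaps.
#' @exportClass ChromosomeAlignment
setClass("ChromosomeAlignment",
  representation(queryName = "character", targetName = "character",
                 blocks = "data.frame", conflicts = "data.frame"),
  validity = function(object) {
    b <- object@blocks
    if (nrow(b) > 1L && any(diff(b$qstart) <= 0))
      return("block query coordinates must be strictly increasing")
    if (nrow(b) && any(nchar(b$qrow) != nchar(b$trow)))
      return("gapped rows must have equal length within a block")
    TRUE
  })

setMethod("show", "ChromosomeAlignment", function(object) {
  b <- object@blocks
  cov <- if (nrow(b)) sum(b$qend - b$qstart + 1) else 0
  cat(sprintf("ChromosomeAlignment %s ~ %s: %d blocks, %d query bp aligned\n",
              object@queryName, object@targetName, nrow(b), cov))
})

#' A simulated pair of diverged genomes with ground truth
#'
#' @slot genomeA,genomeB \code{DNAStringSet} (single chromosome each).
#' @slot truth \code{DataFrame} of ground-truth events (one row per planted
#'   mutation; see \code{\link{simulateGenomePair}}).
#' @slot library the \code{TELibrary} whose families were planted.
#' @slot config the fully-resolved simulation configuration (named list).
#' @exportClass GenomePairSim
setClass("GenomePairSim",
  representation(genomeA = "DNAStringSet", genomeB = "DNAStringSet",
                 truth = "DataFrame", library = "TELibrary",
                 config = "list"))

setMethod("show", "GenomePairSim", function(object) {
  cat(sprintf(paste0("GenomePairSim: A %d bp, B %d bp, %d truth events ",
                     "(%d families planted)\n"),
              sum(Biostrings::width(object@genomeA)),
              sum(Biostrings::width(object@genomeB)),
              nrow(object@truth), length(object@library)))
})

# ---- plain accessors ----

#' @rdname TELibrary-class
#' @param x a \code{TELibrary}
#' @export
teConsensus <- function(x) x@consensus

#' @rdname TELibrary-class
#' @export
teInfo <- function(x) x@info

#' @rdname ChromosomeAlignment-class
#' @param x a \code{ChromosomeAlignment}
#' @export
alignmentBlocks <- function(x) x@blocks

#' @rdname ChromosomeAlignment-class
#' @export
alignmentConflicts <- function(x) x@conflicts

#' @rdname GenomePairSim-class
#' @param x a \code{GenomePairSim}
#' @export
genomeA <- function(x) x@genomeA

#' @rdname GenomePairSim-class
#' @export
genomeB <- function(x) x@genomeB

#' @rdname GenomePairSim-class
#' @export
groundTruth <- function(x) x@truth

#' @rdname GenomePairSim-class
#' @export
simConfig <- function(x) x@config

#' @rdname GenomePairSim-class
#' @export
simLibrary <- function(x) x@library
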