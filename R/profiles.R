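# Superfamily diagnostics: TSD motifs/lengths and TIR consensus motifs for
# the five TIR-order Class II superfamilies, and terminal TIR matching.

#' Target-site and TIR profiles of the five TIR-order superfamilies
#'
#' Returns the diagnostic profile of each DNA transposon superfamily:
#' the target-site duplication (TSD) motif and length created upon
#' insertion, and the 5'-terminal TIR consensus. Mariner (DTT) elements
#' duplicate a TA dinucleotide, Harbinger (DTH) a TAA/TTA trinucleotide,
#' while Mutator (DTM), CACTA (DTC) and hAT (DTA) duplicate 9, 3 and 8 bp
#' of arbitrary host sequence.
#'
#' @return named list of \linkS4class{SuperfamilyProfile} objects
#'   (names DTT, DTH, DTM, DTC, DTA).
#' @examples
#' superfamilyProfiles()$DTT
#' @export
superfamilyProfiles <- function() {
  mk <- function(code, motif, len, tir)
    new("SuperfamilyProfile", code = code, tsdMotif = motif,
        tsdLength = as.integer(len), tirConsensus = tir)
  list(
    DTT = mk("DTT", "TA", 2L, "CTCCCTC"),
    DTH = mk("DTH", "TAA/TTA", 3L, "GG(G/C)CC"),
    DTM = mk("DTM", "variable", 9L, "GAG"),
    DTC = mk("DTC", "variable", 3L, "CACT(A/G)"),
    DTA = mk("DTA", "variable", 8L, "CA")
  )
}

# expand a motif with single-position parenthesised alternatives, e.g.
# "CACT(A/G)" -> c("CACTA", "CACTG"); "GG(G/C)CC" -> c("GGGCC", "GGCCC")
.expandMotif <- function(motif) {
  out <- ""
  rest <- motif
  while (nzchar(rest)) {
    if (substr(rest, 1L, 1L) == "(") {
      close <- regexpr(")", rest, fixed = TRUE)
      if (close < 0) .stopf("unbalanced parenthesis in motif '%s'", motif)
      alts <- strsplit(substr(rest, 2L, close - 1L), "/", fixed = TRUE)[[1]]
      out <- as.vector(outer(out, alts, paste0))
      rest <- substr(rest, close + 1L, nchar(rest))
    } else {
      out <- paste0(out, substr(rest, 1L, 1L))
      rest <- substr(rest, 2L, nchar(rest))
    }
  }
  out
}

#' Match terminal inverted repeats against a superfamily profile
#'
#' Tests whether the 5' terminus of \code{sequence} matches the profile's
#' TIR consensus and the 3' terminus matches its reverse complement, each
#' with at most \code{max_mismatch} mismatches. Parenthesised alternatives
#' in the consensus (e.g. \code{CACT(A/G)}) are accepted at their position.
#'
#' @param sequence nucleotide string, at least twice the motif length.
#' @param profile a \linkS4class{SuperfamilyProfile}.
#' @param max_mismatch maximum mismatches tolerated at each terminus.
#' @return \code{NULL} if no hit, otherwise a list with the matched
#'   \code{motif}, the mismatch counts \code{mm5}/\code{mm3} and the profile
#'   \code{code}.
#' @examples
#' p <- superfamilyProfiles()$DTC
#' matchTIR(paste0("CACTA", strrep("G", 90), "TAGTG"), p, max_mismatch = 0)
#' @export
matchTIR <- function(sequence, profile, max_mismatch = 1) {
  stopifnot(is(profile, "SuperfamilyProfile"))
  motifs <- .expandMotif(profile@tirConsensus)
  w <- nchar(motifs[1L])
  if (nchar(sequence) < 2L * w)
    .stopf("sequence shorter than twice the TIR motif length")
  head5 <- substr(sequence, 1L, w)
  tail3 <- substr(sequence, nchar(sequence) - w + 1L, nchar(sequence))
  best <- NULL
  for (m in motifs) {
    mm5 <- .hamming(head5, m)
    mm3 <- .hamming(tail3, .revcomp(m))
    if (mm5 <= max_mismatch && mm3 <= max_mismatch) {
      if (is.null(best) || mm5 + mm3 < best$mm5 + best$mm3)
        best <- list(motif = m, mm5 = mm5, mm3 = mm3, code = profile@code)
    }
  }
  best
}
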