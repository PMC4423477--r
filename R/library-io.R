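# Reading and writing classified TE consensus libraries (FASTA).
#
# Header grammar: ">family#CODE free text" (e.g. ">stowaway_like#DTT ...");
# TREP-style headers whose family name begins with the 3-letter superfamily
# code ("DTT_SB", "DTM_MK description") are accepted as well.

#' Construct a TELibrary
#'
#' @param sequences named character vector or \code{DNAStringSet} of family
#'   consensus sequences.
#' @param superfamily character vector of 3-letter codes, recycled if scalar.
#' @param source provenance, \code{"library"} or \code{"discovered"}.
#' @return a \linkS4class{TELibrary}
#' @export
TELibrary <- function(sequences, superfamily, source = "library") {
  seqs <- Biostrings::DNAStringSet(sequences)
  fam <- names(seqs)
  if (is.null(fam)) .stopf("sequences must be named by family")
  if (length(superfamily) == 1L)
    superfamily <- rep(superfamily, length(seqs))
  new("TELibrary", consensus = seqs,
      info = S4Vectors::DataFrame(family = fam, superfamily = superfamily,
                                  source = rep(source, length.out =
                                                 length(seqs))))
}

.parseLibHeader <- function(header) {
  first <- sub("\\s.*$", "", header)
  if (grepl("#", first, fixed = TRUE)) {
    parts <- strsplit(first, "#", fixed = TRUE)[[1]]
    list(family = parts[1L], code = toupper(parts[2L]))
  } else if (grepl("^[A-Za-z]{3}_", first)) {
    list(family = first, code = toupper(substr(first, 1L, 3L)))
  } else {
    NULL
  }
}

#' Load a classified TE consensus library from FASTA
#'
#' Each record header must carry a family name and a 3-letter superfamily
#' code, either as \code{family#CODE} or as a TREP-style name whose first
#' three letters are the code (e.g. \code{DTT_SB}). Only TIR-order Class II
#' codes (DTT, DTH, DTM, DTC, DTA) are admitted; retrotransposon and other
#' codes are rejected.
#'
#' @param path FASTA file path.
#' @return a \linkS4class{TELibrary} keyed by family name.
#' @export
loadTELibrary <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (!length(seqs)) .stopf("empty TE library: %s", path)
  fam <- character(length(seqs))
  code <- character(length(seqs))
  for (i in seq_along(seqs)) {
    p <- .parseLibHeader(names(seqs)[i])
    if (is.null(p))
      .stopf("malformed library header (no family/superfamily code): '%s'",
             names(seqs)[i])
    if (!p$code %in% c("DTT", "DTH", "DTM", "DTC", "DTA"))
      .stopf(paste0("record '%s' carries superfamily code '%s', which is ",
                    "not a TIR-order Class II code"), p$family, p$code)
    fam[i] <- p$family
    code[i] <- p$code
  }
  if (anyDuplicated(fam))
    .stopf("duplicate family name in library: '%s'", fam[duplicated(fam)][1L])
  names(seqs) <- fam
  TELibrary(seqs, code, source = "library")
}

#' Write a TELibrary to FASTA
#'
#' Headers are written as \code{family#CODE source}, so discovered families
#' keep their provenance tag on round trip.
#'
#' @param library a \linkS4class{TELibrary}.
#' @param path output FASTA path.
#' @export
writeTELibrary <- function(library, path) {
  seqs <- library@consensus
  names(seqs) <- sprintf("%s#%s %s", library@info$family,
                         library@info$superfamily, library@info$source)
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

# merge: add families (discovered) to an existing library
.appendFamilies <- function(library, new_seqs, superfamily,
                            source = "discovered") {
  if (!length(new_seqs)) return(library)
  add <- TELibrary(new_seqs, superfamily, source = source)
  new("TELibrary",
      consensus = c(library@consensus, add@consensus),
      info = rbind(library@info, add@info))
}
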