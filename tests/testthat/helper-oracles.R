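# Independent oracles and small constructors shared across the test files.

BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

randSeq <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

revcompStr <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# plain quadratic affine-gap Smith-Waterman, scores only; written
# independently of the package implementation (full matrices, R loops)
swOracle <- function(a, b, match = 5, mismatch = -4, go = 30, ge = 0.1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  FF <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (av[i - 1] == bv[j - 1] && av[i - 1] %in% BASES) match
      else mismatch
      E[i, j] <- max(H[i, j - 1] - go - ge, E[i, j - 1] - ge)
      FF[i, j] <- max(H[i - 1, j] - go - ge, FF[i - 1, j] - ge)
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], FF[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# score an alignment's gapped rows under the affine model (for traceback
# consistency checks)
scoreRows <- function(ra, rb, match = 5, mismatch = -4, go = 30, ge = 0.1) {
  av <- strsplit(ra, "")[[1]]
  bv <- strsplit(rb, "")[[1]]
  sc <- 0
  ingap_a <- FALSE; ingap_b <- FALSE
  for (k in seq_along(av)) {
    if (av[k] == "-") {
      sc <- sc - ge - (if (ingap_a) 0 else go)
      ingap_a <- TRUE; ingap_b <- FALSE
    } else if (bv[k] == "-") {
      sc <- sc - ge - (if (ingap_b) 0 else go)
      ingap_b <- TRUE; ingap_a <- FALSE
    } else {
      sc <- sc + if (av[k] == bv[k] && av[k] %in% BASES) match else mismatch
      ingap_a <- FALSE; ingap_b <- FALSE
    }
  }
  sc
}

# brute-force expansion of a TIR motif with single-position alternatives,
# and position-wise terminal comparison (oracle for matchTIR)
expandMotifOracle <- function(motif) {
  out <- ""
  while (nzchar(motif)) {
    if (substr(motif, 1, 1) == "(") {
      close <- regexpr(")", motif, fixed = TRUE)
      alts <- strsplit(substr(motif, 2, close - 1), "/")[[1]]
      out <- unlist(lapply(out, function(o) paste0(o, alts)))
      motif <- substr(motif, close + 1, nchar(motif))
    } else {
      out <- paste0(out, substr(motif, 1, 1))
      motif <- substr(motif, 2, nchar(motif))
    }
  }
  out
}

matchTIROracle <- function(sequence, profile, max_mismatch = 1) {
  motifs <- expandMotifOracle(profile@tirConsensus)
  w <- nchar(motifs[1])
  head5 <- strsplit(substr(sequence, 1, w), "")[[1]]
  tail3 <- strsplit(substr(sequence, nchar(sequence) - w + 1,
                           nchar(sequence)), "")[[1]]
  for (m in motifs) {
    mv <- strsplit(m, "")[[1]]
    rv <- strsplit(revcompStr(m), "")[[1]]
    if (sum(head5 != mv) <= max_mismatch &&
        sum(tail3 != rv) <= max_mismatch) return(TRUE)
  }
  FALSE
}

# a one-block ChromosomeAlignment from two gapped rows (1-based coords)
blockCA <- function(qrow, trow, qstart = 1L, tstart = 1L) {
  qlen <- nchar(gsub("-", "", qrow))
  tlen <- nchar(gsub("-", "", trow))
  new("ChromosomeAlignment", queryName = "q", targetName = "t",
      blocks = data.frame(qstart = qstart, qend = qstart + qlen - 1L,
                          tstart = tstart, tend = tstart + tlen - 1L,
                          qrow = qrow, trow = trow, window = 1L,
                          stringsAsFactors = FALSE),
      conflicts = data.frame(qstart = integer(0), qend = integer(0),
                             disagreement = numeric(0)))
}

# write a small TE library FASTA and return its path
writeLibFasta <- function(records, path = tempfile(fileext = ".fasta")) {
  lines <- unlist(lapply(names(records), function(h)
    c(paste0(">", h), records[[h]])))
  writeLines(as.character(lines %||% character(0)), path)
  path
}
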