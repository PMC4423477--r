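# Internal string/alignment helpers shared across modules.

DNA_BASES4 <- c("A", "C", "G", "T")

.revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

.randDNA <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES4, n, replace = TRUE, prob = p), collapse = "")
}

.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# identity = matches / alignment columns (gap columns count in the
# denominator). Optionally exclude columns belonging to gap runs longer than
# `exclude_gap_runs_over` (per-HSP style identity used for anchoring).
.alnIdentity <- function(row_a, row_b, exclude_gap_runs_over = NULL) {
  a <- .chars(row_a); b <- .chars(row_b)
  if (!length(a)) return(0)
  keep <- rep(TRUE, length(a))
  if (!is.null(exclude_gap_runs_over)) {
    for (r in list(a, b)) {
      rl <- rle(r == "-")
      ends <- cumsum(rl$lengths)
      starts <- ends - rl$lengths + 1L
      long <- which(rl$values & rl$lengths > exclude_gap_runs_over)
      for (i in long) keep[starts[i]:ends[i]] <- FALSE
    }
  }
  if (!any(keep)) return(0)
  matches <- sum(a[keep] == b[keep] & a[keep] != "-" &
                   a[keep] %in% DNA_BASES4)
  matches / sum(keep)
}

# maximal runs of `ch` in a character vector; data.frame(start, end, length)
.runsOf <- function(chv, ch) {
  rl <- rle(chv == ch)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  i <- which(rl$values)
  data.frame(start = starts[i], end = ends[i], length = rl$lengths[i])
}

# longest strictly increasing subsequence (indices) - collinearity chains
.lisIndices <- function(x) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  tails <- integer(0)      # indices into x of smallest tail per length
  prev <- integer(n)
  for (i in seq_len(n)) {
    lo <- 1L; hi <- length(tails) + 1L
    while (lo < hi) {      # first position with x[tails[pos]] >= x[i]
      mid <- (lo + hi) %/% 2L
      if (x[tails[mid]] < x[i]) lo <- mid + 1L else hi <- mid
    }
    prev[i] <- if (lo > 1L) tails[lo - 1L] else 0L
    tails[lo] <- i
  }
  out <- integer(length(tails))
  k <- tails[length(tails)]
  for (j in rev(seq_along(tails))) { out[j] <- k; k <- prev[k] }
  out
}

# Greedy matched-prefix length between two strings. With tolerate_snps,
# scattered substitutions are absorbed while the following `confirm`-base
# window stays predominantly matching (>= min_confirm matches); past a true
# breakpoint agreement drops to random (~25%) and extension stops.
# Without tolerance, extension is strictly exact. N never matches.
.matchedPrefixLen <- function(a, b, tolerate_snps = FALSE, confirm = 8L,
                              min_confirm = 6L) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- .chars(substr(a, 1L, n)); bv <- .chars(substr(b, 1L, n))
  ok <- av == bv & av %in% DNA_BASES4
  mm <- which(!ok)
  if (!length(mm)) return(n)
  if (!tolerate_snps) return(mm[1L] - 1L)
  for (m in mm) {
    after <- ok[seq.int(m + 1L, length.out = min(confirm, n - m))]
    if (length(after) == confirm && sum(after) >= min_confirm) {
      next  # substitution noise, absorbed
    }
    return(m - 1L)
  }
  n
}

.matchedSuffixLen <- function(a, b, tolerate_snps = FALSE, confirm = 8L) {
  .matchedPrefixLen(.strrev(a), .strrev(b), tolerate_snps, confirm)
}

.strrev <- function(s) {
  paste(rev(.chars(s)), collapse = "")
}

# hamming distance over pmin length; N counts as mismatch
.hamming <- function(a, b) {
  av <- .chars(a); bv <- .chars(b)
  n <- min(length(av), length(bv))
  if (n == 0L) return(0L)
  sum(!(av[seq_len(n)] == bv[seq_len(n)] & av[seq_len(n)] %in% DNA_BASES4))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
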