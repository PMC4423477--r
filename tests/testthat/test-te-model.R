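# TE model: superfamily profiles, TIR matching, library I/O, segment
# annotation, consensus border refinement and family discovery.

test_that("the five superfamily profiles carry the diagnostic TSD/TIR set", {
  p <- superfamilyProfiles()
  expect_named(p, c("DTT", "DTH", "DTM", "DTC", "DTA"))
  expect_equal(vapply(p, function(x) x@tsdLength, integer(1)),
               c(DTT = 2L, DTH = 3L, DTM = 9L, DTC = 3L, DTA = 8L))
  expect_equal(p$DTT@tsdMotif, "TA")
  expect_equal(p$DTH@tsdMotif, "TAA/TTA")
  expect_equal(p$DTC@tirConsensus, "CACT(A/G)")
  for (x in p) expect_true(validObject(x))
})

test_that("matchTIR accepts terminal motifs with alternatives and agrees
          with a brute-force oracle", {
  p <- superfamilyProfiles()
  # CACTA element: starts CACTA, ends with its reverse complement TAGTG
  el <- paste0("CACTA", strrep("G", 90), "TAGTG")
  expect_false(is.null(matchTIR(el, p$DTC, max_mismatch = 0)))
  # hAT element: CA ... TG
  el2 <- paste0("CA", strrep("T", 96), "TG")
  expect_false(is.null(matchTIR(el2, p$DTA, max_mismatch = 0)))
  # oracle equivalence across all profiles on random and planted cases
  set.seed(11)
  for (rep in 1:50) {
    s <- randSeq(100)
    for (prof in p) {
      for (mm in 0:1) {
        got <- !is.null(matchTIR(s, prof, max_mismatch = mm))
        expect_identical(got, matchTIROracle(s, prof, mm),
                         info = sprintf("%s mm=%d seq=%s", prof@code, mm,
                                        substr(s, 1, 12)))
      }
    }
    # planted hit
    prof <- p[[sample(5, 1)]]
    m <- expandMotifOracle(prof@tirConsensus)[1]
    el3 <- paste0(m, randSeq(60), revcompStr(m))
    expect_true(!is.null(matchTIR(el3, prof, max_mismatch = 0)))
    expect_true(matchTIROracle(el3, prof, 0))
  }
})

test_that("loadTELibrary parses classified headers and rejects bad input", {
  set.seed(2)
  path <- writeLibFasta(list(
    "DTT_SB something" = randSeq(120),
    "mk_family#DTM description" = randSeq(200)))
  lib <- loadTELibrary(path)
  expect_s4_class(lib, "TELibrary")
  expect_equal(length(lib), 2L)
  expect_setequal(teInfo(lib)$superfamily, c("DTT", "DTM"))
  # retrotransposon code rejected
  bad <- writeLibFasta(list("RLX_x#RLX retro" = randSeq(100)))
  expect_error(loadTELibrary(bad), "not a TIR-order")
  # duplicate family name
  dup <- writeLibFasta(list("DTT_SB a" = randSeq(100),
                            "DTT_SB b" = randSeq(100)))
  expect_error(loadTELibrary(dup), "duplicate")
  # empty library
  empty <- writeLibFasta(list())
  expect_error(loadTELibrary(empty))
  # round trip preserves families and sequences
  out <- tempfile(fileext = ".fasta")
  writeTELibrary(lib, out)
  lib2 <- loadTELibrary(out)
  expect_equal(as.character(teConsensus(lib2)), as.character(teConsensus(lib)))
})

test_that("annotateSegment enforces the 50 bp / 70% admission thresholds", {
  set.seed(4)
  cons <- randSeq(300)
  lib <- TELibrary(c(FAM1 = cons), "DTT")
  # a 49-bp perfect match is rejected by the length threshold (N flanks
  # keep the local alignment from extending past the planted match)
  seg49 <- paste0(strrep("N", 40), substr(cons, 100, 148), strrep("N", 40))
  expect_equal(nrow(annotateSegment(seg49, lib)), 0L)
  # a 60-bp hit at ~73% identity is retained (mismatches evenly spaced in
  # the interior so the optimal local alignment keeps the full 60 columns)
  core <- strsplit(substr(cons, 100, 159), "")[[1]]
  mut <- round(seq(4, 58, length.out = 16))
  core[mut] <- vapply(core[mut], function(b) sample(setdiff(BASES, b), 1),
                      character(1))
  seg60 <- paste0(randSeq(80), paste(core, collapse = ""), randSeq(80))
  ann <- annotateSegment(seg60, lib)
  expect_gte(nrow(ann), 1L)
  expect_gte(ann$identity[1], 0.70)
  # full self-match at identity 1
  ann2 <- annotateSegment(cons, lib)
  expect_equal(nrow(ann2), 1L)
  expect_equal(ann2$identity, 1.0)
  expect_equal(ann2$length, 300L)
  # all-N segment yields an empty annotation, not an error
  expect_equal(nrow(annotateSegment(strrep("N", 200), lib)), 0L)
  # reverse-strand copies are found
  seg_rc <- paste0(randSeq(50), revcompStr(cons), randSeq(50))
  ann3 <- annotateSegment(seg_rc, lib)
  expect_equal(ann3$strand[1], "-")
  # admission invariant over random segments
  for (r in 1:10) {
    seg <- paste0(randSeq(100), substr(cons, 1, sample(40:200, 1)),
                  randSeq(100))
    a <- annotateSegment(seg, lib)
    if (nrow(a)) {
      expect_true(all(a$length >= 50))
      expect_true(all(a$identity >= 0.70))
    }
  }
})

test_that("refineConsensusBorders trims to the conserved core and flags
          degenerate alignments", {
  set.seed(9)
  core <- paste0("CTCCCTC", randSeq(186), revcompStr("CTCCCTC"))
  rows <- vapply(1:15, function(i)
    paste0(randSeq(300), core, randSeq(300)), character(1))
  ref <- refineConsensusBorders(rows)
  expect_false(ref$failed)
  expect_equal(nchar(ref$consensus), 200L)
  expect_equal(ref$consensus, core)
  expect_equal(ref$superfamily, "DTT")
  expect_false(is.null(ref$tir))
  # identical rows everywhere: borders indeterminable
  same <- rep(paste0(randSeq(100), core, randSeq(100)), 5)
  expect_true(refineConsensusBorders(same)$failed)
  # no conserved core of 50 bp
  noise <- vapply(1:6, function(i) randSeq(400), character(1))
  expect_true(refineConsensusBorders(noise)$failed)
})

test_that("discoverFamilies recovers a planted family and reaches a fixed
          point", {
  set.seed(31)
  g <- makeAncestor(80000, 0.44)
  fam <- paste0("CTCCCTC", randSeq(186), revcompStr("CTCCCTC"))
  pos <- sort(sample(seq(1500, 78000, by = 120), 20))
  prof <- superfamilyProfiles()$DTT
  off <- 0
  for (p in pos) {
    r <- applyInsertion(g, fam, p + off, prof)
    g <- r$genome
    off <- off + nchar(fam) + 2L
  }
  genome <- Biostrings::DNAStringSet(c(chr = g))
  d <- discoverFamilies(fam, genome)
  expect_equal(length(d$discovered), 1L)
  cons <- as.character(teConsensus(d$discovered)[[1]])
  aln <- alignWindow(cons, fam)
  expect_gte(aln$identity, 0.99)
  expect_equal(teInfo(d$discovered)$source, "discovered")
  # idempotence: the expanded library annotates the segment, so a rerun
  # discovers nothing new
  d2 <- discoverFamilies(fam, genome, library = d$library)
  expect_equal(length(d2$discovered), 0L)
  # too few copies: no family
  g2 <- makeAncestor(60000, 0.44)
  off <- 0
  for (p in pos[1:10]) {
    r <- applyInsertion(g2, fam, p + off, prof)
    g2 <- r$genome
    off <- off + nchar(fam) + 2L
  }
  d3 <- discoverFamilies(fam, Biostrings::DNAStringSet(c(chr = g2)))
  expect_equal(length(d3$discovered), 0L)
})
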