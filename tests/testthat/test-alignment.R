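# Windowed Smith-Waterman alignment, anchoring and chromosome assembly.

test_that("alignWindow matches closed forms and is symmetric", {
  set.seed(21)
  s <- randSeq(200)
  r <- alignWindow(s, s)
  expect_equal(r$score, 1000)        # 200 matches x 5
  expect_false(grepl("-", r$qrow, fixed = TRUE))
  # symmetry of the score under swapping the sequences
  a <- randSeq(150); b <- randSeq(150)
  expect_equal(alignWindow(a, b)$score, alignWindow(b, a)$score,
               tolerance = 1e-9)
  # a single 60-bp insertion yields one long gap, not fragments
  ins <- paste0(substr(s, 1, 100), randSeq(60), substr(s, 101, 200))
  r2 <- alignWindow(ins, s)
  gaps <- gregexpr("-+", r2$trow)[[1]]
  expect_equal(length(gaps), 1L)
  expect_equal(attr(gaps, "match.length"), 60L)
  # all-N windows are unalignable
  rn <- alignWindow(strrep("N", 500), strrep("N", 500), band = "auto")
  expect_equal(rn$score, 0)
})

test_that("alignWindow equals the quadratic DP oracle on random pairs", {
  set.seed(22)
  for (i in 1:60) {
    a <- randSeq(sample(10:100, 1))
    b <- randSeq(sample(10:100, 1))
    r <- alignWindow(a, b)
    expect_equal(r$score, swOracle(a, b), tolerance = 1e-6)
    if (r$score > 0) {
      # traceback consistency: rows reproduce the subsequences and re-score
      expect_equal(gsub("-", "", r$qrow), substr(a, r$qstart, r$qend))
      expect_equal(gsub("-", "", r$trow), substr(b, r$tstart, r$tend))
      expect_equal(scoreRows(r$qrow, r$trow), r$score, tolerance = 1e-6)
    }
  }
})

test_that("the seed-banded mode reproduces the full DP on structured pairs", {
  set.seed(23)
  q <- randSeq(6000)
  t2 <- paste0(substr(q, 1, 3000), randSeq(1500), substr(q, 3001, 6000))
  full <- alignWindow(q, t2, band = NULL)
  auto <- alignWindow(q, t2, band = "auto")
  expect_equal(auto$score, full$score, tolerance = 1e-6)
  # deletion case
  t3 <- paste0(substr(q, 1, 2500), substr(q, 4500, 6000))
  expect_equal(alignWindow(q, t3, band = "auto")$score,
               alignWindow(q, t3, band = NULL)$score, tolerance = 1e-6)
})

test_that("fragmentAndAnchor fragments on the 5-kb grid and filters by
          orientation and collinearity", {
  set.seed(24)
  g <- randSeq(12345)
  gs <- Biostrings::DNAStringSet(c(chr = g))
  a <- fragmentAndAnchor(gs, gs)
  expect_equal(nrow(a), 3L)                       # 5000 / 5000 / 2345
  expect_equal(a$qend - a$qstart + 1L, c(5000L, 5000L, 2345L))
  expect_true(all(a$anchored))
  expect_true(all(a$identity == 1))
  expect_equal(a$tpos, a$qstart)                  # self-anchoring
  # opposite strand: best hit on the reverse complement gives no anchor
  rc <- Biostrings::DNAStringSet(c(chr = revcompStr(g)))
  a2 <- fragmentAndAnchor(gs, rc)
  expect_false(any(a2$anchored))
})

test_that("passesQuality applies the 200 bp / 90% embedded-flank rule", {
  set.seed(25)
  mkrows <- function(flank_l, flank_r, gap_len, mut_per_flank = 0) {
    fl <- randSeq(flank_l); fr <- randSeq(flank_r)
    gap <- randSeq(gap_len)
    mutate <- function(s, k) {
      if (k == 0) return(s)
      v <- strsplit(s, "")[[1]]
      idx <- round(seq(4, length(v) - 4, length.out = k))
      v[idx] <- vapply(v[idx], function(b) sample(setdiff(BASES, b), 1), "")
      paste(v, collapse = "")
    }
    list(qrow = paste0(fl, gap, fr),
         trow = paste0(mutate(fl, mut_per_flank), strrep("-", gap_len),
                       mutate(fr, mut_per_flank)),
         score = 1)
  }
  # 250 aligned bp at ~95% identity on both sides: pass
  wa <- mkrows(250, 250, 80, mut_per_flank = 12)
  expect_true(passesQuality(wa))
  # only 150 aligned bp on one side: fail
  wa2 <- mkrows(150, 300, 80)
  expect_false(passesQuality(wa2))
  # flank present but identity at or below 90%: fail (strict >)
  wa3 <- mkrows(200, 300, 80, mut_per_flank = 20)  # exactly 90%
  expect_false(passesQuality(wa3))
  # gap-free perfect alignment passes vacuously
  s <- randSeq(400)
  expect_true(passesQuality(list(qrow = s, trow = s, score = 1)))
  # a gap-free alignment shorter than the flank requirement fails
  s2 <- randSeq(150)
  expect_false(passesQuality(list(qrow = s2, trow = s2, score = 1)))
})

test_that("assembleChromosome fuses agreeing windows and logs conflicts", {
  set.seed(26)
  g <- randSeq(30000)
  mkwin <- function(q0, q1, toff = 0) {
    s <- substr(g, q0, q1)
    list(qstart = q0, qend = q1, tstart = q0 + toff, tend = q1 + toff,
         qrow = s, trow = s, identity = 1, window = q0)
  }
  # two windows agreeing on their overlap: seamless non-overlapping blocks
  ca <- assembleChromosome(list(mkwin(1, 12000), mkwin(5001, 17000)))
  b <- alignmentBlocks(ca)
  expect_equal(nrow(b), 2L)
  expect_equal(b$qstart[2], b$qend[1] + 1L)
  expect_equal(b$tstart[2], b$tend[1] + 1L)
  expect_equal(nrow(alignmentConflicts(ca)), 0L)
  # windows disagreeing by > 10 kb in the target: conflict logged and both
  # truncated to non-overlapping cores
  ca2 <- assembleChromosome(list(mkwin(1, 12000), mkwin(5001, 17000,
                                                        toff = 15000)))
  expect_equal(nrow(alignmentConflicts(ca2)), 1L)
  b2 <- alignmentBlocks(ca2)
  expect_true(all(diff(b2$qstart) > 0))
  # single window: one block identical to it
  ca3 <- assembleChromosome(list(mkwin(101, 9000)))
  expect_equal(alignmentBlocks(ca3)$qstart, 101L)
  expect_equal(alignmentBlocks(ca3)$qend, 9000L)
})

test_that("assembled alignments reproduce the genomic sequence exactly
          (ungapping round-trip) and identical genomes align gap-free", {
  cfg <- simulationConfig(genome_length = 1e5, n_planted_per_family = 2,
                          n_insertions = 4, n_excisions = 2,
                          n_internal_deletions = 0, n_gaps = 0,
                          margin = 8000, min_locus_spacing = 3000,
                          seed = 3)
  sim <- simulateGenomePair(cfg)
  alns <- alignGenomes(genomeA(sim), genomeB(sim))
  qseq <- as.character(genomeA(sim)[[1]])
  tseq <- as.character(genomeB(sim)[[1]])
  b <- alignmentBlocks(alns[[1]])
  expect_gt(nrow(b), 0L)
  for (i in seq_len(nrow(b))) {
    expect_equal(gsub("-", "", b$qrow[i]), substr(qseq, b$qstart[i], b$qend[i]))
    expect_equal(gsub("-", "", b$trow[i]), substr(tseq, b$tstart[i], b$tend[i]))
  }
  # two identical genomes: assembled alignment has no indels at all
  alns2 <- alignGenomes(genomeA(sim), genomeA(sim))
  b2 <- alignmentBlocks(alns2[[1]])
  expect_false(any(grepl("-", b2$qrow, fixed = TRUE)))
  expect_false(any(grepl("-", b2$trow, fixed = TRUE)))
})
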