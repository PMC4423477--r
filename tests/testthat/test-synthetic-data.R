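# Simulator: ancestor generation, divergence, insertion/excision mechanics,
# assembly gaps, fixtures and bookkeeping invariants.

test_that("makeAncestor is seeded, respects GC and boundary compositions", {
  expect_identical(makeAncestor(1000, 0.5, seed = 7),
                   makeAncestor(1000, 0.5, seed = 7))
  expect_false(grepl("[GC]", makeAncestor(500, 0, seed = 1)))
  g <- makeAncestor(1e6, 0.44, seed = 1)
  gc <- sum(strsplit(g, "")[[1]] %in% c("G", "C")) / 1e6
  expect_lt(abs(gc - 0.44), 0.01)   # binomial concentration
  expect_error(makeAncestor(1000, 1.2), "gc")
})

test_that("divergeGenomes applies calibrated substitutions and small indels", {
  set.seed(5)
  anc <- makeAncestor(1e5, 0.44)
  d0 <- divergeGenomes(anc, substitution_rate = 0, background_indel_rate = 0)
  expect_identical(d0$genomeA, anc)
  expect_identical(d0$genomeB, anc)
  d <- divergeGenomes(anc, substitution_rate = 0.005,
                      background_indel_rate = 0)
  for (g in c(d$genomeA, d$genomeB)) {
    mm <- sum(strsplit(g, "")[[1]] != strsplit(anc, "")[[1]])
    # binomial oracle: n p = 500, 3 SD ~ 67
    expect_lt(abs(mm - 500), 3 * sqrt(1e5 * 0.005 * 0.995))
  }
  d2 <- divergeGenomes(anc, substitution_rate = 0,
                       background_indel_rate = 2e-4)
  expect_true(all(d2$events$length <= 10))
  expect_true(all(d2$events$length >= 1))
})

test_that("applyInsertion duplicates the target site per superfamily", {
  set.seed(6)
  profs <- superfamilyProfiles()
  g <- makeAncestor(5000, 0.44)
  te <- randSeq(250)
  # Mariner: TSD is TA, length grows by te + 2
  r <- applyInsertion(g, te, 2500, profs$DTT)
  expect_equal(nchar(r$genome), nchar(g) + 252L)
  expect_equal(r$event$tsd, "TA")
  s <- r$event$site
  expect_equal(substr(r$genome, s, s + 1), "TA")
  expect_equal(substr(r$genome, s + 2, s + 251), te)
  expect_equal(substr(r$genome, s + 252, s + 253), "TA")
  # Mutator: 9 bp of arbitrary host sequence duplicated verbatim
  r2 <- applyInsertion(g, te, 2500, profs$DTM)
  expect_equal(nchar(r2$event$tsd), 9L)
  expect_equal(r2$event$tsd, substr(g, 2500, 2508))
  s2 <- r2$event$site
  expect_equal(substr(r2$genome, s2, s2 + 8),
               substr(r2$genome, s2 + 259, s2 + 267))
  # degenerate input
  expect_error(applyInsertion(g, "", 100, profs$DTT), "zero-length")
  # no motif within 1 kb
  gAT <- strrep("G", 5000)
  expect_error(applyInsertion(gAT, te, 2500, profs$DTT), "motif")
})

test_that("applyExcision draws footprints with the configured geometry", {
  set.seed(8)
  g0 <- makeAncestor(4000, 0.44)
  prof <- superfamilyProfiles()$DTT
  te <- randSeq(300)
  ins <- applyInsertion(g0, te, 2000, prof)
  s <- ins$event$site
  locus <- list(tsd_start = s, te_start = s + 2L, te_end = s + 301L,
                tsd_length = 2L, is_te = TRUE)
  # perfect: tandem TSD remains, net change is -len(TE)
  r <- applyExcision(ins$genome, locus,
                     footprint = list(kind = "perfect", side = NA,
                                      deleted_bp = 0L, filler_bp = 0L))
  expect_equal(nchar(r$genome), nchar(ins$genome) - 300L)
  expect_equal(substr(r$genome, s, s + 3), "TATA")
  expect_equal(r$event$kind, "excision-perfect")
  # deletion with an extreme length is logged as drawn
  r2 <- applyExcision(ins$genome, locus,
                      footprint = list(kind = "deletion", side = "right",
                                       deleted_bp = 1200L, filler_bp = 0L))
  expect_equal(r2$event$deleted_bp, 1200L)
  expect_equal(nchar(r2$genome), nchar(ins$genome) - 300L - 2L - 1200L)
  # unflagged locus is a contract error
  locus_bad <- locus; locus_bad$is_te <- FALSE
  expect_error(applyExcision(ins$genome, locus_bad), "not flagged")
  # filler lengths always within [1, 123] under defaults
  set.seed(9)
  lens <- replicate(400, {
    fp <- TIRpoly:::.drawFootprint(footprintParams())
    fp$filler_bp
  })
  lens <- lens[lens > 0]
  expect_true(all(lens >= 1 & lens <= 123))
})

test_that("sequential insertions and excisions keep exact length books", {
  set.seed(12)
  g <- makeAncestor(20000, 0.44)
  prof <- superfamilyProfiles()$DTM
  expected <- nchar(g)
  loci <- list()
  for (i in 1:8) {
    te <- randSeq(sample(100:400, 1))
    r <- applyInsertion(g, te, sample(2000:18000, 1), prof)
    g <- r$genome
    expected <- expected + nchar(te) + 9L
    expect_equal(nchar(g), expected)
  }
})

test_that("addAssemblyGaps plants disjoint N runs longer than 50", {
  set.seed(13)
  g <- makeAncestor(50000, 0.44)
  r <- addAssemblyGaps(g, 10, c(60L, 500L))
  runs <- rle(strsplit(r$genome, "")[[1]] == "N")
  nruns <- sum(runs$values & runs$lengths > 50)
  expect_equal(nruns, 10L)
  expect_true(all(r$gaps$length > 50))
  expect_identical(addAssemblyGaps(g, 0, c(60L, 500L))$genome, g)
  expect_error(addAssemblyGaps(g, 3, c(40L, 60L)), "exceed 50")
  # fraction placed over TE copies
  te_iv <- cbind(seq(1000, 46000, by = 5000), seq(1500, 46500, by = 5000))
  r2 <- addAssemblyGaps(g, 12, c(60L, 200L), te_intervals = te_iv,
                        frac_over_te = 0.5)
  expect_true(any(r2$gaps$over_te))
})

test_that("fixtures round-trip byte-identically for a fixed seed", {
  cfg <- simulationConfig(genome_length = 1.2e5, n_planted_per_family = 3,
                          n_insertions = 6, n_excisions = 3,
                          n_internal_deletions = 1, n_gaps = 2,
                          margin = 8000, min_locus_spacing = 3000,
                          seed = 77)
  sim <- simulateGenomePair(cfg)
  sim2 <- simulateGenomePair(cfg)
  expect_identical(as.character(genomeA(sim)), as.character(genomeA(sim2)))
  expect_identical(as.character(genomeB(sim)), as.character(genomeB(sim2)))
  expect_identical(as.data.frame(groundTruth(sim)),
                   as.data.frame(groundTruth(sim2)))
  dir <- tempfile()
  writeFixture(sim, dir)
  expect_true(file.exists(file.path(dir, "config.yaml")))
  ga <- Biostrings::readDNAStringSet(file.path(dir, "genomeA.fasta"))
  expect_identical(as.character(ga[[1]]), as.character(genomeA(sim)[[1]]))
  tr <- readTruth(file.path(dir, "truth.tsv"))
  expect_equal(nrow(tr), nrow(groundTruth(sim)))
  expect_identical(tr$kind, groundTruth(sim)$kind)
  expect_identical(tr$filler_seq, groundTruth(sim)$filler_seq)
  # gap placement: exactly n_gaps maximal N runs > 50 in genome B
  runs <- rle(strsplit(as.character(genomeB(sim)[[1]]), "")[[1]] == "N")
  expect_equal(sum(runs$values & runs$lengths > 50), 2L)
})

test_that("simulated TSDs obey the superfamily motifs", {
  cfg <- simulationConfig(genome_length = 1.5e5, n_planted_per_family = 3,
                          n_insertions = 15, n_excisions = 4,
                          n_internal_deletions = 0, n_gaps = 0,
                          margin = 8000, min_locus_spacing = 3000,
                          seed = 5)
  tr <- as.data.frame(groundTruth(simulateGenomePair(cfg)))
  tr <- tr[tr$kind != "background-indel", ]
  expect_true(all(tr$tsd[tr$superfamily == "DTT"] == "TA"))
  expect_true(all(tr$tsd[tr$superfamily == "DTH"] %in% c("TAA", "TTA")))
  expect_true(all(nchar(tr$tsd[tr$superfamily == "DTM"]) == 9L))
  expect_true(all(nchar(tr$tsd[tr$superfamily == "DTA"]) == 8L))
})
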