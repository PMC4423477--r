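# Ratio statistics, fixation arithmetic, extrapolations, activity
# groupings, gamete-transmission expectation and gene context.

test_that("ratioTest reproduces the published superfamily ratios", {
  expect_equal(round(ratioTest(59, 21)$ratio, 1), 2.8)
  expect_equal(round(ratioTest(84, 19)$ratio, 2), 4.42)
  expect_equal(round(ratioTest(90, 11)$ratio, 2), 8.18)
  expect_equal(round(ratioTest(26, 3)$ratio, 2), 8.67)
  # a 2n:n split is the null case: ratio exactly 2 and a larger p-value
  # than either neighbouring count
  for (n in c(5, 20, 50)) {
    r <- ratioTest(2 * n, n)
    expect_equal(r$ratio, 2)
    expect_gte(r$p_value, ratioTest(2 * n + 3, n - 3)$p_value)
    expect_gte(r$p_value, ratioTest(2 * n - 3, n + 3)$p_value)
  }
  # zero excisions: undefined ratio, but the test still runs
  r0 <- ratioTest(5, 0)
  expect_false(r0$ratio_defined)
  expect_true(is.finite(r0$p_value))
})

test_that("the exact binomial p-value matches a brute-force tail sum", {
  # two-sided exact test: sum of all outcome probabilities not exceeding
  # the observed one (enumerated directly)
  tailOracle <- function(k, n, p = 2 / 3) {
    d <- dbinom(0:n, n, p)
    sum(d[d <= d[k + 1] * (1 + 1e-7)])
  }
  for (n in c(5L, 17L, 30L, 101L, 120L)) {
    for (k in unique(c(0L, 1L, n %/% 3L, (2L * n) %/% 3L, n - 1L, n))) {
      expect_equal(ratioTest(k, n - k)$p_value, tailOracle(k, n),
                   tolerance = 1e-12, info = sprintf("k=%d n=%d", k, n))
    }
  }
  # monotonicity: at fixed n the p-value decreases as the insertion count
  # moves away from the 2:1 expectation
  n <- 90L
  ks <- 60:89
  ps <- vapply(ks, function(k) ratioTest(k, n - k)$p_value, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("fixationRate reproduces the published arithmetic", {
  f <- fixationRate(2300, 600000)
  expect_equal(f$rate, 0.004, tolerance = 1e-4)
  expect_equal(f$one_in_n, 250)
  f0 <- fixationRate(0, 600000)
  expect_equal(f0$rate, 0)
  expect_true(is.na(f0$one_in_n))
  expect_equal(fixationRate(600000, 600000)$rate, 1.0)
})

test_that("extrapolation arithmetic is exact", {
  e <- extrapolatePolymorphisms(238, 844, 7542)
  expect_equal(round(e$yield_percent), 28)
  g <- gapAttribution(20080, 7301, 1871, n_rich_events = 1745)
  expect_equal(round(100 * g$te_fraction, 1), 25.6)
  # identity: fraction times total equals the extrapolation before rounding
  expect_equal(g$te_fraction * 20080, g$extrapolated_te_gaps)
  expect_equal(round(g$extrapolated_hidden_polymorphisms), 447)
})

test_that("extrapolateHiddenTeGaps maps gap flanks and screens the
          orthologous segment", {
  set.seed(61)
  lib <- makeTELibrary(seed = 62)
  g0 <- makeAncestor(60000, 0.44, seed = 63)
  te <- as.character(teConsensus(lib)[[1]])
  ins <- applyInsertion(g0, te, 30000, superfamilyProfiles()$DTT)
  gOther <- ins$genome
  gGap <- ins$genome
  s <- ins$event$site
  substr(gGap, s + 2, s + 1 + nchar(te)) <- strrep("N", nchar(te))
  att <- extrapolateHiddenTeGaps(gGap, gOther, lib)
  expect_equal(att$total_gaps, 1L)
  expect_equal(att$mappable_gaps, 1L)
  expect_equal(att$te_positive_gaps, 1L)
  expect_equal(att$te_fraction, 1)
  # genome without N runs: all-zero attribution
  att0 <- extrapolateHiddenTeGaps(g0, gOther, lib)
  expect_equal(att0$total_gaps, 0L)
  expect_equal(att0$extrapolated_te_gaps, 0)
})

test_that("relativeActivityTable computes activity/abundance and groups", {
  counts <- data.frame(
    family = c("DTH_TR", "DTT_SB", "DTM_MAD", "DTH_TO", "DTT_X"),
    superfamily = c("DTH", "DTT", "DTM", "DTH", "DTT"),
    copies = c(581L, 3995L, 2L, 3000L, 900L))
  moved <- c(DTH_TR = 18L, DTM_MAD = 1L, DTH_TO = 5L, DTT_X = 1L)
  tab <- relativeActivityTable(counts, moved = moved)
  expect_equal(tab$relative_activity[tab$family == "DTH_TR"], 18 / 581,
               tolerance = 1e-9)
  expect_equal(tab$group[tab$family == "DTT_SB"], "inactive")
  # two copies, one moved: highest relative activity, low abundance
  expect_equal(tab$relative_activity[tab$family == "DTM_MAD"], 0.5)
  expect_equal(tab$group[tab$family == "DTM_MAD"], "II")
  expect_equal(sum(tab$relative_abundance), 1)
  # a family with calls but no copies is inconsistent
  expect_error(relativeActivityTable(
    data.frame(family = "X", superfamily = "DTT", copies = 0L),
    moved = c(X = 2L)), "zero copies")
})

test_that("non-replicative transposition drives the expected ratio to 1:1", {
  set.seed(64)
  r <- simulateGameteTransmission(200, 500, p_replicative = 0)
  expect_equal(r$mean_ratio, 1, tolerance = 1e-9)
})

test_that("geneContext classifies strand-aware windows with precedence", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tt\tgene\t10000\t12000\t.\t+\t.\tID=g1;Name=gstA",
    "chr1\tt\texon\t10000\t10500\t.\t+\t.\tParent=g1",
    "chr1\tt\texon\t11500\t12000\t.\t+\t.\tParent=g1",
    "chr1\tt\tCDS\t10000\t10500\t.\t+\t0\tParent=g1",
    "chr1\tt\tCDS\t11500\t12000\t.\t+\t0\tParent=g1",
    "chr1\tt\tgene\t30000\t31000\t.\t-\t.\tID=g2;Name=putative transposase",
    "chr1\tt\tCDS\t30000\t31000\t.\t-\t0\tParent=g2"), gff)
  pos <- data.frame(chrom = "chr1",
                    pos = c(9200,   # 800 bp 5' of the CDS start: upstream
                            12600,  # 600 bp 3' of the CDS end: intergenic
                            12400,  # 400 bp 3': downstream
                            11700,  # inside exon 2
                            11000,  # between exons: intron
                            30500)) # inside a transposase entry: removed
  gc <- geneContext(pos, gff)
  expect_equal(gc$assignments$context,
               c("upstream", "intergenic", "downstream", "exon", "intron",
                 "intergenic"))
  # context counts partition the calls
  expect_equal(sum(gc$counts), nrow(pos))
  # a strandless gene model is skipped with a warning
  gff2 <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tt\tgene\t100\t500\t.\t.\t.\tID=g3"), gff2)
  expect_warning(geneContext(data.frame(chrom = "chr1", pos = 300), gff2),
                 "strand")
})
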