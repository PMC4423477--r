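# Footprint classification: TSD detection, the verdict decision tree and
# deletion/filler quantification, exercised end to end on constructed
# divergence-free genome pairs where every outcome is known exactly.

# Build a genome pair carrying one constructed event of each class.
# Events are applied at fixed, well-separated positions on a shared
# ancestor; zero divergence so measurements must be exact.
buildConstructedPair <- function() {
  set.seed(51)
  profs <- superfamilyProfiles()
  lib <- makeTELibrary(seed = 52)
  cons <- as.character(teConsensus(lib))
  consOf <- function(code) cons[[match(code, teInfo(lib)$superfamily)]]
  anc <- makeAncestor(165000, 0.44, seed = 53)
  A <- anc; B <- anc
  expected <- list()
  add <- function(rec) expected[[length(expected) + 1L]] <<- rec
  # events applied in ascending ancestor position; all previous edits lie
  # to the left, so the ancestor position p maps to p + (length change so
  # far) in each genome and recorded coordinates stay final
  dA <- function() nchar(A) - nchar(anc)
  dB <- function() nchar(B) - nchar(anc)

  # plant a TE at ancestor position p in both genomes, then excise from B
  plantAndExcise <- function(p, code, kind, del = 0L, filler = "") {
    prof <- profs[[code]]
    L <- prof@tsdLength
    te <- consOf(code)
    rA <- applyInsertion(A, te, p + dA(), prof)
    rB <- applyInsertion(B, te, p + dB(), prof)
    stopifnot(rA$event$site - dA() == rB$event$site - dB())
    A <<- rA$genome
    sB <- rB$event$site
    g <- rB$genome
    te0 <- sB + L; te1 <- sB + L + nchar(te) - 1L
    B <<- switch(kind,
      perfect = paste0(substr(g, 1, te0 - 1),
                       substr(g, te1 + 1, nchar(g))),
      "del-left" = paste0(substr(g, 1, sB - del - 1),
                          substr(g, te1 + 1, nchar(g))),
      "del-right" = paste0(substr(g, 1, te0 - 1),
                           substr(g, te1 + L + del + 1, nchar(g))),
      filler = paste0(substr(g, 1, te0 - 1), filler,
                      substr(g, te1 + 1, nchar(g))),
      "both-left" = paste0(substr(g, 1, sB - del - 1), filler,
                           substr(g, te1 + 1, nchar(g))))
    rA$event$site
  }

  # 1: fresh Mariner insertion in A (the textbook TSD pattern)
  r <- applyInsertion(A, consOf("DTT"), 10000 + dA(), profs$DTT)
  A <- r$genome
  add(list(kind = "insertion", bearing = "A", pos = r$event$site))

  # 2: fresh Mutator insertion in A
  r <- applyInsertion(A, consOf("DTM"), 25000 + dA(), profs$DTM)
  A <- r$genome
  add(list(kind = "insertion", bearing = "A", pos = r$event$site))

  # 3: perfect excision (tandem TSD remains at the empty site)
  s <- plantAndExcise(40000, "DTH", "perfect")
  add(list(kind = "excision-perfect", bearing = "A", pos = s,
           deleted_bp = 0L, filler_bp = 0L))

  # 4: one-sided flanking deletion of 18 bp
  s <- plantAndExcise(55000, "DTA", "del-left", del = 18L)
  add(list(kind = "excision-deletion", bearing = "A", pos = s,
           deleted_bp = 18L, filler_bp = 0L))

  # 5: deletion of 25 bp plus a 12-bp filler (combined outcome)
  s <- plantAndExcise(85000, "DTC", "both-left", del = 25L,
                      filler = randSeq(12))
  add(list(kind = "excision-both", bearing = "A", pos = s,
           deleted_bp = 25L, filler_bp = 12L))

  # 6: extreme one-sided deletion of 2,479 bp at the right border
  s <- plantAndExcise(100000, "DTT", "del-right", del = 2479L)
  add(list(kind = "excision-deletion", bearing = "A", pos = s,
           deleted_bp = 2479L, filler_bp = 0L))

  # 7: maximal observed filler (123 bp); terminal As keep the replacement
  # boundary unambiguous (the DTH element starts G and ends C)
  s <- plantAndExcise(115000, "DTH", "filler",
                      filler = paste0("A", randSeq(121), "A"))
  add(list(kind = "excision-filler", bearing = "A", pos = s,
           filler_bp = 123L, deleted_bp = 0L))

  # 8: internal deletion of the middle 300 bp of a Mutator copy present in
  # both species (not transposition)
  teM <- consOf("DTM")
  r <- applyInsertion(A, teM, 130000 + dA(), profs$DTM)
  sA <- r$event$site
  pAnc <- sA - dA()
  A <- r$genome
  rB <- applyInsertion(B, teM, pAnc + dB(), profs$DTM)
  sB <- rB$event$site
  B <- rB$genome
  c1 <- sB + 9 + 250; c2 <- c1 + 299
  B <- paste0(substr(B, 1, c1 - 1), substr(B, c2 + 1, nchar(B)))
  add(list(kind = "internal-deletion", bearing = "A", pos = sA + 9 + 250))

  list(A = Biostrings::DNAStringSet(c(chr = A)),
       B = Biostrings::DNAStringSet(c(chr = B)),
       lib = lib, expected = expected)
}

constructedCalls <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pair <- buildConstructedPair()
      res <- runPipeline(pair$A, pair$B, pair$lib, tolerate_snps = FALSE)
      cache <<- list(pair = pair, res = res)
    }
    cache
  }
})

test_that("the decision tree reproduces every constructed event class with
          exact deletion and filler lengths", {
  cc <- constructedCalls()
  calls <- cc$res$calls
  for (ex in cc$pair$expected) {
    hit <- calls[calls$bearing_species == ex$bearing &
                   calls$bear_start <= ex$pos + 50 &
                   calls$bear_end >= ex$pos - 50, ]
    expect_equal(nrow(hit), 1L, info = ex$kind)
    expect_equal(hit$verdict, ex$kind, info = ex$kind)
    if (grepl("^excision", ex$kind)) {
      expect_equal(hit$deleted_bp, ex$deleted_bp, info = ex$kind)
      expect_equal(hit$filler_bp, ex$filler_bp, info = ex$kind)
      expect_equal(hit$acting_species, "B", info = ex$kind)
    }
    if (ex$kind == "insertion") {
      expect_equal(hit$acting_species, "A")
      expect_true(hit$tsd_found)
    }
  }
})

test_that("verdicts partition the TE-homologous events", {
  cc <- constructedCalls()
  calls <- cc$res$calls
  counts <- summarizeFootprints(calls)$counts
  expect_equal(sum(counts), nrow(calls))
})

test_that("detectTSD separates insertion and perfect-excision signatures", {
  set.seed(55)
  lib <- TELibrary(c(TE1 = paste0("CTCCCTC", randSeq(236),
                                  revcompStr("CTCCCTC"))), "DTT")
  te <- as.character(teConsensus(lib)[[1]])
  prof <- superfamilyProfiles()$DTT
  fl <- paste0(randSeq(599), "G"); fr <- paste0("C", randSeq(599))
  # insertion pattern: bearing G TA TE TA C, empty G TA C
  qrow <- paste0(fl, "TA", te, "TA", fr)
  trow <- paste0(fl, "TA", strrep("-", nchar(te) + 2), fr)
  ev <- scanIndels(blockCA(qrow, trow), gsub("-", "", qrow),
                   gsub("-", "", trow))
  ann <- annotateSegment(ev$extra[1], lib)
  tsd <- detectTSD(ev[1, ], ann[1, ], prof)
  expect_true(tsd$found)
  expect_equal(tsd$sequence, "TA")
  expect_equal(tsd$empty_copies, 1L)
  # perfect-excision pattern: empty site carries the tandem TSD
  profH <- superfamilyProfiles()$DTH
  libH <- TELibrary(c(TEH = paste0("GGGCC", randSeq(240),
                                   revcompStr("GGGCC"))), "DTH")
  teH <- as.character(teConsensus(libH)[[1]])
  qrow2 <- paste0(fl, "TAA", teH, "TAA", fr)
  trow2 <- paste0(fl, "TAA", strrep("-", nchar(teH)), "TAA", fr)
  ev2 <- scanIndels(blockCA(qrow2, trow2), gsub("-", "", qrow2),
                    gsub("-", "", trow2))
  ann2 <- annotateSegment(ev2$extra[1], libH)
  tsd2 <- detectTSD(ev2[1, ], ann2[1, ], profH)
  expect_true(tsd2$found)
  expect_equal(tsd2$empty_copies, 2L)
  # no duplication at either border: not found
  qrow3 <- paste0(fl, te, fr)
  trow3 <- paste0(fl, strrep("-", nchar(te)), fr)
  ev3 <- scanIndels(blockCA(qrow3, trow3), gsub("-", "", qrow3),
                    gsub("-", "", trow3))
  ann3 <- annotateSegment(ev3$extra[1], lib)
  tsd3 <- detectTSD(ev3[1, ], ann3[1, ], prof)
  expect_false(tsd3$found)
})

test_that("summarizeFootprints reports totals with and without extreme
          deletions", {
  # a call set with the observed outcome mix: 8 perfect, 34 deletion-only,
  # 49 filler-only, 9 both; non-extreme deletions summing 926 bp plus one
  # 2,479-bp case; fillers summing 880 bp in [1, 123]
  dels <- c(rep(22, 41), 24, 2479)   # 43 deletion-bearing events
  stopifnot(sum(dels[dels <= 1000]) == 926)
  fil <- c(rep(13, 40), rep(14, 15), 120, 22, 8)  # 58 fillers, 880 bp
  stopifnot(sum(fil) == 880, length(fil) == 58)
  calls <- data.frame(
    verdict = c(rep("excision-perfect", 8),
                rep("excision-deletion", 34),
                rep("excision-filler", 49),
                rep("excision-both", 9)),
    superfamily = "DTT",
    deleted_bp = c(rep(0, 8), dels[1:34], rep(0, 49), dels[35:43]),
    filler_bp = c(rep(0, 8), rep(0, 34), fil[1:49], fil[50:58]),
    stringsAsFactors = FALSE)
  s <- summarizeFootprints(calls)
  expect_equal(s$n_perfect, 8L)
  expect_equal(s$n_with_deletion, 43L)
  expect_equal(s$n_with_filler, 58L)
  expect_equal(s$n_both, 9L)
  expect_equal(s$total_deleted_bp_excl_outliers, 926)
  expect_equal(s$total_deleted_bp, 926 + 2479)
  expect_equal(s$total_filler_bp, 880)
  expect_true(s$min_filler_bp >= 1 && s$max_filler_bp <= 123)
  # empty call set: all-zero summary
  s0 <- summarizeFootprints(calls[0, ])
  expect_equal(s0$n_excisions, 0L)
  expect_equal(s0$total_deleted_bp, 0)
})
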