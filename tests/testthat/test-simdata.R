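test_that("spike-in design enforces its variant sites and truth", {
  d <- spikeInDesign(seed = 41)
  expect_true(d@gcRef %in% c("G", "C"))
  expect_true(d@atRef %in% c("A", "T"))
  expect_equal(length(d@variants), 6)
  expect_equal(d@insertEnd - d@insertStart, 1000L)
  expect_equal(length(d@reference), 3660)
  # every variant differs from the construct at exactly one position
  cons <- as.character(referenceSequences(d@reference)[[1]])
  for (v in d@variants) {
    diff <- which(strsplit(cons, "")[[1]] != strsplit(v, "")[[1]])
    expect_equal(length(diff), 1)
    expect_true((diff - 1) %in% c(d@gcPos, d@atPos))
  }
  # the designed class totals follow the mixing arithmetic exactly
  expect_equal(designedDeltas(d, 0)$classGC, 0)
  d1 <- designedDeltas(d, 1)
  expect_equal(d1$classGC, (1 / 2) / d@nGCInsert * 1e6)
  d01 <- designedDeltas(d, 0.01)
  expect_equal(d01$classGC, (3 * 0.01 / 6) / 1.01 / d@nGCInsert * 1e6)
  # nominal labels are approximated because insert composition is random
  expect_lt(abs(d1$classGC / 1000 - 1), 0.15)
  expect_lt(abs(d01$classAT / 10 - 1), 0.15)
  # the three substitution types of each class are spiked equally
  expect_equal(unname(d1$perType6[c("C>A", "C>G", "C>T")]),
               rep(d1$classGC / 3, 3))
})

test_that("exposure planting follows the class rates and records truth", {
  g <- tinyGenome(4000, seed = 42)
  # all-zero model leaves the population identical to the reference
  m0 <- uniformExposure(g, setNames(rep(0, 6), subTypes()))
  pop0 <- simulateExposedMolecules(m0, 5, seed = 1)
  expect_true(all(pop0@sequences ==
                    as.character(referenceSequences(g)[[1]])))
  expect_equal(nrow(pop0@truth$events), 0)

  # a single-class model plants only at its reference triplet
  lab <- sub96Labels()
  r96 <- setNames(rep(0, 96), lab); r96["A[C>T]T"] <- 5e-3
  m1 <- methods::new("ExposureModel", reference = g, rate96 = r96,
                     rateNoContext = setNames(rep(0, 6), subTypes()))
  pop1 <- simulateExposedMolecules(m1, 40, seed = 2)
  ev <- pop1@truth$events
  expect_gt(nrow(ev), 0)
  expect_true(all(ev$class == "A[C>T]T"))
  gseq <- as.character(referenceSequences(g)[[1]])
  tri <- substring(gseq, ev$pos, ev$pos + 2)  # 5' base .. 3' base
  expect_true(all(tri %in% c("ACT", "AGT")))  # both strands of the class

  # closed-form expected event count for a uniform C>T rate
  phi <- 1e-3
  m2 <- uniformExposure(g, c("C>T" = phi))
  nmol <- 200
  pop2 <- simulateExposedMolecules(m2, nmol, seed = 3)
  expected <- phi * nGCSites(g) * nmol
  expect_lt(abs(nrow(pop2@truth$events) / expected - 1),
            4 / sqrt(expected))
  # rates above the per-site cap are refused
  expect_error(uniformExposure(g, c("C>T" = 0.02)), "model misuse")
})

test_that("read simulation is seeded, clips fragments and carries truth", {
  g <- tinyGenome(1000, seed = 43)
  pool <- referencePool(g)
  a <- simulateReads(pool, 30, seed = 9)
  b <- simulateReads(pool, 30, seed = 9)
  expect_identical(a@seq1, b@seq1)
  expect_identical(a@qual2, b@qual2)
  f1 <- tempfile(); f2 <- tempfile(); f3 <- tempfile(); f4 <- tempfile()
  writeFastqPairs(a, f1, f2); writeFastqPairs(b, f3, f4)
  expect_identical(readLines(f1), readLines(f3))  # byte-identical output

  # fragment longer than the molecule is clipped
  short <- referenceFromSeq(c(chr = randomDna(80)))
  p <- simulateReads(referencePool(short), 5, readLen = 150,
                     fragLen = 150, seed = 1,
                     profile = uniformErrorProfile(0))
  expect_true(all(nchar(p@seq1) == 80))

  # error-free reference-only reads give a zero mutation table
  p0 <- simulateReads(pool, 200, readLen = 80, fragLen = 80, seed = 2,
                      profile = uniformErrorProfile(0))
  aln <- alignExact(mergePairs(p0), g, method = "scan")
  mft <- countSubstitutions(buildBaseCounts(aln, g), g)
  expect_true(all(mft@freq6 == 0))

  # planted events recorded per read match the variant design
  d <- spikeInDesign(seed = 44)
  pool1 <- makeSpikeInSample(d, 1)
  pr <- simulateReads(pool1, 500, seed = 5,
                      profile = uniformErrorProfile(0))
  tr <- pr@metadata$truth
  cover <- tr$fragStart <= d@gcPos &
    tr$fragStart + tr$fragLen > d@gcPos & tr$molecule %in% 1:3
  expect_equal(sort(unique(tr$events$read[tr$events$pos == d@gcPos])),
               sort(which(cover)))
})

test_that("truth sets round-trip through TSV", {
  g <- tinyGenome(3000, seed = 47)
  m <- uniformExposure(g, c("C>T" = 2e-3))
  pop <- simulateExposedMolecules(m, 30, seed = 4)
  tsv <- tempfile(fileext = ".tsv")
  writeTruthSet(pop, tsv)
  back <- read.delim(tsv)
  expect_equal(nrow(back), nrow(pop@truth$events))
  expect_true(all(back$ref %in% c("C", "G")))

  pr <- simulateReads(m, 300, seed = 5, profile = uniformErrorProfile(0))
  writeTruthSet(pr, tsv)
  back2 <- read.delim(tsv)
  expect_equal(nrow(back2), nrow(pr@metadata$truth$events))
  expect_error(writeTruthSet(referencePool(g), tsv), "no truth")
})

test_that("oxidative artifact is strand-specific and consensus-proof", {
  set.seed(45)
  g <- tinyGenome(2e4, seed = 45)
  prof <- errorProfile(misRates = matrix(0, 4, 4), oxoRate = 5e-3,
                       jitterSdLog = 0, oxoJitterSdLog = 0)
  pr <- simulateReads(referencePool(g), 5000, profile = prof)
  m <- mergePairs(pr)
  # artifact bases agree between mates, so nothing is masked
  expect_equal(sum(nMasked(m)), 0)
  b <- buildBaseCounts(alignExact(m, g), g)
  f <- countSubstitutions(b, g)
  expect_gt(f@counts6[["C>A"]], 0)      # G>T collapses to C>A
  expect_equal(sum(f@counts6[setdiff(subTypes(), "C>A")]), 0)
  d <- strandBiasDiagnostic(b, g)
  expect_equal(d$type[d$flagged], "C>A")
  expect_equal(d$countPyr[d$type == "C>A"], 0)  # purine orientation only
})

test_that("expected deltas of a spectrum exposure match its targets", {
  g <- tinyGenome(3e4, seed = 46)
  target <- c("C>T" = 40, "T>A" = 10)
  m <- spectrumExposure(g, target)
  ed <- expectedDeltas(m)
  byType <- vapply(subTypes(), function(t)
    sum(ed[grepl(paste0("[", t, "]"), names(ed), fixed = TRUE)]),
    numeric(1))
  expect_equal(unname(byType[["C>T"]]), 40, tolerance = 1e-6)
  expect_equal(unname(byType[["T>A"]]), 10, tolerance = 1e-6)
  expect_equal(unname(byType[["C>G"]]), 0)
})
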