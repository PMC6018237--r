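
# build a BaseCountMatrix directly from aligned reads for a small genome
countsFor <- function(aln, genome, qMin = 0) buildBaseCounts(aln, genome,
                                                             qMin = qMin)

test_that("substitution counting and per-million frequencies", {
  g <- referenceFromSeq(c(chr = "TAGTC"))
  # one read pair's worth of coverage with one G>A call at position 2,
  # reference triplet A G T -> pyrimidine class A[C>T]T
  aln <- methods::new("AlignedReads", id = c("r1", "r2"),
                      contig = c("chr", "chr"), start = c(0L, 0L),
                      read1Forward = c(TRUE, TRUE),
                      seq = c("TAGTC", "TAATC"),
                      qual = c("FFFFF", "FFFFF"),
                      olStart = c(0L, 0L), olEnd = c(5L, 5L),
                      cigar = c("", ""), mapq = c(60L, 60L),
                      metadata = list())
  f <- countSubstitutions(countsFor(aln, g), g)
  expect_equal(unname(f@counts6[["C>T"]]), 1)
  expect_equal(sum(f@counts6), 1)
  expect_equal(unname(f@counts96[["A[C>T]T"]]), 1)
  # 4 G:C calls (positions 2 and 4 across both reads, one altered); the
  # altered call still maps to a G:C reference site
  expect_equal(f@denomGC, 4)
  expect_equal(f@denomAT, 6)
  expect_equal(unname(f@freq6[["C>T"]]), 1 / 4 * 1e6)
  expect_equal(unname(f@freq6[["T>G"]]), 0)

  # genome mismatch is refused
  expect_error(countSubstitutions(countsFor(aln, g),
                                  referenceFromSeq(c(chr = "TAGTG"))),
               "different genome")
})

test_that("per-context normalization divides by the class's own sites", {
  g <- referenceFromSeq(c(chr = "TAGTC"))
  aln <- methods::new("AlignedReads", id = c("r1", "r2"),
                      contig = c("chr", "chr"), start = c(0L, 0L),
                      read1Forward = c(TRUE, TRUE),
                      seq = c("TAGTC", "TAATC"),
                      qual = c("FFFFF", "FFFFF"),
                      olStart = c(0L, 0L), olEnd = c(5L, 5L),
                      cigar = c("", ""), mapq = c(60L, 60L),
                      metadata = list())
  b <- buildBaseCounts(aln, g, qMin = 0)
  fClass <- countSubstitutions(b, g)
  fCtx <- countSubstitutions(b, g, normalize96 = "context")
  # counts are identical; only the 96-class denominators change
  expect_equal(fCtx@counts96, fClass@counts96)
  expect_equal(fCtx@freq6, fClass@freq6)
  # the G>A call at position 2: class denominator is all 4 G:C calls,
  # context denominator only the 2 calls at the A-G-T site itself
  expect_equal(unname(fClass@freq96[["A[C>T]T"]]), 1 / 4 * 1e6)
  expect_equal(unname(fCtx@freq96[["A[C>T]T"]]), 1 / 2 * 1e6)
})

test_that("frequencies are scale invariant and class-consistent", {
  set.seed(14)
  g <- tinyGenome(600, seed = 14)
  model <- uniformExposure(g, setNames(rep(2e-3, 6), subTypes()))
  pairs <- simulateReads(model, 400, readLen = 60, fragLen = 60,
                         profile = uniformErrorProfile(0))
  a <- alignExact(mergePairs(pairs), g, method = "scan")
  b <- buildBaseCounts(a, g)
  f1 <- countSubstitutions(b, g)
  b2 <- b
  b2@counts <- b@counts * 2L
  b2@denomGC <- b@denomGC * 2; b2@denomAT <- b@denomAT * 2
  f2 <- countSubstitutions(b2, g)
  expect_equal(f2@freq6, f1@freq6)
  expect_equal(f2@freq96, f1@freq96)
  # each type's count is >= the sum of its 16 context classes
  for (t in subTypes()) {
    in96 <- sum(f1@counts96[grepl(paste0("[", t, "]"), names(f1@counts96),
                                  fixed = TRUE)])
    expect_gte(unname(f1@counts6[[t]]), in96)
  }
  # here every aligned site has context except contig ends
  expect_lte(sum(f1@counts6) - sum(f1@counts96), 2)
})

test_that("background subtraction averages controls, keeps sign", {
  mk <- function(f) {
    x <- methods::new("MutationFrequencyTable", sample = "s", group = "g",
                      dose = NA_real_,
                      counts6 = setNames(rep(0, 6), subTypes()),
                      freq6 = setNames(rep(f, 6), subTypes()),
                      counts96 = setNames(rep(0, 96), sub96Labels()),
                      freq96 = setNames(rep(f / 16, 96), sub96Labels()),
                      denomGC = 1e9, denomAT = 1e9)
    x
  }
  d <- subtractBackground(mk(12), list(mk(2), mk(2), mk(2)))
  expect_equal(unname(d@delta6), rep(10, 6))
  expect_equal(subtractBackground(mk(5), list(mk(5)))@delta6,
               setNames(rep(0, 6), subTypes()))
  d2 <- subtractBackground(mk(1), list(mk(2), mk(3)))
  expect_equal(unname(d2@delta6), rep(-1.5, 6))  # negatives preserved
  expect_error(subtractBackground(mk(1), list()), "at least one control")
})

test_that("planted exposure frequencies are recovered within binomial error", {
  set.seed(15)
  g <- tinyGenome(5e4, seed = 15)
  phi <- 2e-4
  model <- uniformExposure(g, setNames(rep(phi, 6), subTypes()))
  nPairs <- 3e4
  ctrl <- lapply(1:2, function(i) {
    p <- simulateReads(referencePool(g), nPairs,
                       profile = uniformErrorProfile(1e-3))
    a <- alignExact(mergePairs(p), g)
    countSubstitutions(buildBaseCounts(a, g), g)
  })
  p <- simulateReads(model, nPairs, profile = uniformErrorProfile(1e-3))
  a <- alignExact(mergePairs(p), g)
  mft <- countSubstitutions(buildBaseCounts(a, g), g)
  del <- subtractBackground(mft, ctrl)
  for (t in subTypes()) {
    D <- if (substr(t, 1, 1) == "C") mft@denomGC else mft@denomAT
    se <- sqrt(phi / D) * 1.3        # + control-mean noise margin
    expect_lt(abs(del@delta6[[t]] / 1e6 - phi), 4 * se)
  }
})

test_that("strand-bias diagnostic flags only planted asymmetric artifacts", {
  set.seed(16)
  g <- tinyGenome(5e4, seed = 16)
  pool <- referencePool(g)
  base <- uniformErrorProfile(3e-3)
  # symmetric errors: no flags
  p <- simulateReads(pool, 3e4, profile = base)
  pp <- alignExact(mergePairs(p), g)
  b <- buildBaseCounts(pp, g)
  d <- strandBiasDiagnostic(b, g)
  expect_equal(nrow(d), 6)
  expect_false(any(d$flagged))
  deep <- d$countPyr + d$countPur >= 50   # ratio meaningful only with calls
  expect_true(all(abs(log(d$ratio[deep])) < log(2.5)))
  # oxidative mode: exactly the G:C>T:A type flagged, purine orientation
  oxo <- errorProfile(misRates = base@misRates, oxoRate = 2e-4,
                      jitterSdLog = 0, oxoJitterSdLog = 0)
  p2 <- simulateReads(pool, 3e4, profile = oxo)
  b2 <- buildBaseCounts(alignExact(mergePairs(p2), g), g)
  d2 <- strandBiasDiagnostic(b2, g)
  expect_equal(d2$type[d2$flagged], "C>A")
  expect_gt(d2$ratio[d2$type == "C>A"], 3)
  # empty matrix -> empty report
  e <- buildBaseCounts(pp[0], g)
  expect_equal(nrow(strandBiasDiagnostic(e, g)), 0)
})
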