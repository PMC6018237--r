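test_that("SAM reading applies flag, coordinate and clipping rules", {
  g <- referenceFromSeq(c(chr = "ACGTACGTACGTACGTACGT"))
  sam <- tempfile(fileext = ".sam")
  writeSamLines(list(
    c("r1", 0, "chr", 1, 60, "10M", "*", 0, 0, "ACGTACGTAC",
      strrep("I", 10)),
    c("r2", 4, "*", 0, 0, "*", "*", 0, 0, "ACGT", "IIII"),     # unmapped
    c("r3", 256, "chr", 1, 60, "4M", "*", 0, 0, "ACGT", "IIII"),  # secondary
    c("r4", 2048, "chr", 1, 60, "4M", "*", 0, 0, "ACGT", "IIII"),
    c("r5", 16, "chr", 3, 60, "3S7M", "*", 0, 0, "AAAGTACGTA",
      strrep("I", 10))),
    c(chr = 20L), sam)
  a <- readSam(sam, g)
  expect_equal(length(a), 2)            # unmapped/secondary/suppl skipped
  expect_equal(a@start, c(0L, 2L))      # 1-based SAM -> 0-based internal
  expect_equal(a@read1Forward, c(TRUE, FALSE))
  b <- buildBaseCounts(a, g, qMin = 0)
  # r5: soft-clipped first 3 query bases excluded, 7M from position 2
  expect_equal(sum(b@counts), 17)
  expect_equal(unname(rowSums(b@counts)[1:2]), c(1, 1))

  writeSamLines(list(c("r", 0, "nope", 1, 60, "4M", "*", 0, 0, "ACGT",
                       "IIII")), c(chr = 20L), sam)
  expect_error(readSam(sam, g), "absent from reference: nope")
})

test_that("SAM writing round-trips and matches Rsamtools' parsing", {
  set.seed(9)
  g <- tinyGenome(800)
  pairs <- simulateReads(referencePool(g), 80, readLen = 60, fragLen = 60,
                         profile = uniformErrorProfile(5e-3))
  a <- alignExact(mergePairs(pairs), g, method = "scan")
  sam <- tempfile(fileext = ".sam")
  writeSam(a, g, sam)
  back <- readSam(sam, g)
  expect_equal(back@start, a@start)
  expect_equal(back@seq, a@seq)
  expect_equal(back@read1Forward, a@read1Forward)
  expect_equal(back@olStart, a@olStart)
  skip_if_not_installed("Rsamtools")
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  rec <- Rsamtools::scanBam(bam)[[1]]
  expect_equal(sort(as.integer(rec$pos) - 1L), sort(a@start))
  expect_equal(sum(rec$strand == "-"), sum(!a@read1Forward))
})

test_that("duplicate removal keys on coordinates+orientation, keeps best", {
  g <- referenceFromSeq(c(chr = strrep("ACGT", 10)))
  mk <- function(id, start, fwd, qual) {
    s <- substr(strrep("ACGT", 10), start + 1, start + 8)
    methods::new("AlignedReads", id = id, contig = "chr",
                 start = as.integer(start), read1Forward = fwd, seq = s,
                 qual = strrep(intToUtf8(qual + 33), 8), olStart = 0L,
                 olEnd = 8L, cigar = "", mapq = 60L, metadata = list())
  }
  cat2 <- function(...) {
    xs <- list(...)
    methods::new("AlignedReads",
                 id = unlist(lapply(xs, slot, "id")),
                 contig = unlist(lapply(xs, slot, "contig")),
                 start = unlist(lapply(xs, slot, "start")),
                 read1Forward = unlist(lapply(xs, slot, "read1Forward")),
                 seq = unlist(lapply(xs, slot, "seq")),
                 qual = unlist(lapply(xs, slot, "qual")),
                 olStart = unlist(lapply(xs, slot, "olStart")),
                 olEnd = unlist(lapply(xs, slot, "olEnd")),
                 cigar = unlist(lapply(xs, slot, "cigar")),
                 mapq = unlist(lapply(xs, slot, "mapq")),
                 metadata = list())
  }
  two <- cat2(mk("a", 0, TRUE, 30), mk("b", 0, TRUE, 35))
  kept <- removeDuplicates(two)
  expect_equal(length(kept), 1)
  expect_equal(kept@id, "b")            # higher mean quality wins
  expect_equal(kept@metadata$nDuplicates, 1)

  opp <- cat2(mk("a", 0, TRUE, 30), mk("b", 0, FALSE, 30))
  expect_equal(length(removeDuplicates(opp)), 2)  # orientation in key

  # 10 reads in groups of 3/3/4 -> 3 survive; ties keep first encountered
  grp <- do.call(cat2, c(lapply(1:3, function(i) mk(paste0("x", i), 0,
                                                    TRUE, 30)),
                         lapply(1:3, function(i) mk(paste0("y", i), 4,
                                                    TRUE, 30)),
                         lapply(1:4, function(i) mk(paste0("z", i), 8,
                                                    TRUE, 30))))
  kept3 <- removeDuplicates(grp)
  expect_equal(length(kept3), 3)
  expect_equal(kept3@id, c("x1", "y1", "z1"))
})

test_that("base counting obeys overlap, mask and quality filters", {
  g <- tinyGenome(100, seed = 2)
  gseq <- as.character(referenceSequences(g)[[1]])
  pairs <- perfectPairs(g, rep(0, 100), len = 100)
  a <- alignExact(mergePairs(pairs, minOverlap = 50), g, method = "scan")
  b <- buildBaseCounts(a, g, qMin = 0)
  expect_equal(sum(b@counts), 100 * 100)
  expect_true(all(rowSums(b@counts)[1:100] == 100))
  expect_equal(sum(baseCallTotals(b)), 10000)

  # one read carries an alt at a G:C site
  gpos <- regexpr("G", gseq)[1]
  s2 <- gseq; substr(s2, gpos, gpos) <- "A"
  one <- readPairs(s2, 37, rcChr(s2), 37)
  a2 <- alignExact(mergePairs(one, minOverlap = 50), g, method = "scan")
  ball <- buildBaseCounts(methods::new("AlignedReads",
    id = c(a@id, a2@id), contig = c(a@contig, a2@contig),
    start = c(a@start, a2@start),
    read1Forward = c(a@read1Forward, a2@read1Forward),
    seq = c(a@seq, a2@seq), qual = c(a@qual, a2@qual),
    olStart = c(a@olStart, a2@olStart), olEnd = c(a@olEnd, a2@olEnd),
    cigar = c(a@cigar, a2@cigar), mapq = c(a@mapq, a2@mapq),
    metadata = list()), g, qMin = 0)
  expect_equal(unname(ball@counts[gpos, "G_fwd"] +
                        ball@counts[gpos, "G_rev"]), 100)
  expect_equal(unname(ball@counts[gpos, "A_fwd"] +
                        ball@counts[gpos, "A_rev"]), 1)

  # a low-quality base is uncounted and leaves the denominator
  q <- strrep(intToUtf8(37 + 33), 100)
  substr(q, 5, 5) <- intToUtf8(2 + 33)
  lowq <- methods::new("AlignedReads", id = "lq", contig = "chr",
                       start = 0L, read1Forward = TRUE, seq = gseq,
                       qual = q, olStart = 0L, olEnd = 100L, cigar = "",
                       mapq = 60L, metadata = list())
  blq <- buildBaseCounts(lowq, g, qMin = 30)
  expect_equal(sum(blq@counts), 99)
})

test_that("counting agrees with a per-read per-base brute force", {
  set.seed(12)
  g <- tinyGenome(400, seed = 12)
  gseq <- as.character(referenceSequences(g)[[1]])
  pairs <- simulateReads(referencePool(g), 40, readLen = 50, fragLen = 50,
                         profile = uniformErrorProfile(2e-2))
  m <- mergePairs(pairs)
  a <- alignExact(m, g, method = "scan")
  b <- buildBaseCounts(a, g, qMin = 30)
  # oracle: naive loop
  oracle <- matrix(0L, 400, 8)
  for (i in seq_along(a@id)) {
    s <- strsplit(a@seq[i], "")[[1]]
    q <- utf8ToInt(a@qual[i]) - 33
    for (j in seq_along(s)) {
      if (j - 1 < a@olStart[i] || j - 1 >= a@olEnd[i]) next
      if (s[j] == "N" || q[j] < 30) next
      col <- match(s[j], c("A", "C", "G", "T")) +
        if (a@read1Forward[i]) 0 else 4
      pos <- a@start[i] + j
      oracle[pos, col] <- oracle[pos, col] + 1L
    }
  }
  expect_equal(unname(b@counts[1:400, ]), unname(oracle))
  # conservation: totals partition the filtered calls by reference class
  expect_equal(sum(baseCallTotals(b)), sum(oracle))
})

test_that("the fixture aligner places, orients and rejects correctly", {
  g <- tinyGenome(500, seed = 33)
  gseq <- as.character(referenceSequences(g)[[1]])
  mk <- function(s) methods::new("MergedReads", id = "r", seq = s,
                                 qual = strrep("F", nchar(s)),
                                 olStart = 0L,
                                 olEnd = nchar(s), nMasked = 0L,
                                 metadata = list())
  a <- alignExact(mk(substr(gseq, 11, 60)), g, method = "scan")
  expect_equal(a@start, 10L)
  expect_equal(a@read1Forward, TRUE)
  expect_equal(a@seq, substr(gseq, 11, 60))

  ar <- alignExact(mk(rcChr(substr(gseq, 11, 60))), g, method = "scan")
  expect_equal(ar@start, 10L)
  expect_equal(ar@read1Forward, FALSE)
  expect_equal(ar@seq, substr(gseq, 11, 60))  # stored reference-oriented

  # ambiguity: a duplicated segment stays unaligned
  dup <- referenceFromSeq(c(chr = paste0(substr(gseq, 1, 100),
                                         strrep("T", 30),
                                         substr(gseq, 1, 100))))
  amb <- alignExact(mk(substr(gseq, 20, 59)), dup, method = "scan")
  expect_equal(length(amb), 0)
  expect_equal(amb@metadata$nUnaligned, 1)

  # index mode agrees with the exhaustive scan on unique placements
  set.seed(7)
  pairs <- simulateReads(referencePool(g), 60, readLen = 50, fragLen = 50,
                         profile = uniformErrorProfile(5e-3))
  m <- mergePairs(pairs)
  s1 <- alignExact(m, g, method = "scan")
  s2 <- alignExact(m, g, method = "index", index = genomeIndex(g, k = 12))
  expect_equal(s1@start, s2@start)
  expect_equal(s1@read1Forward, s2@read1Forward)
})
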