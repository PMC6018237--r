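test_that("spectrum construction clips, normalizes and rejects zero", {
  lab <- sub96Labels()
  v <- setNames(rep(0, 96), lab)
  v["A[C>T]T"] <- 7
  sp <- buildSpectrum(v)
  expect_equal(unname(spectrumWeights(sp)[["A[C>T]T"]]), 1)
  expect_equal(sum(spectrumWeights(sp)), 1)

  v2 <- v; v2["A[C>T]T"] <- 3; v2["G[C>T]C"] <- 1
  w2 <- spectrumWeights(buildSpectrum(v2))
  expect_equal(unname(w2[c("A[C>T]T", "G[C>T]C")]), c(0.75, 0.25))

  v3 <- v2; v3["T[T>G]T"] <- -5        # clipped before normalization
  w3 <- spectrumWeights(buildSpectrum(v3))
  expect_equal(unname(w3[["T[T>G]T"]]), 0)
  expect_equal(w3[c("A[C>T]T", "G[C>T]C")], w2[c("A[C>T]T", "G[C>T]C")])

  expect_error(buildSpectrum(setNames(rep(-1, 96), lab)),
               "no positive signal")
  # invariance to positive rescaling of the deltas
  expect_equal(spectrumWeights(buildSpectrum(v2 * 37)), w2)
})

test_that("cosine similarity has its hand-checked values and symmetry", {
  a <- c(1, 1, rep(0, 94)); b <- c(1, 0, rep(0, 94))
  expect_equal(cosineSimilarity(a, a), 1)
  expect_equal(cosineSimilarity(b, c(0, 1, rep(0, 94))), 0)
  expect_equal(cosineSimilarity(a, b), 1 / sqrt(2))
  set.seed(30)
  x <- rexp(96); y <- rexp(96)
  expect_equal(cosineSimilarity(x, y), cosineSimilarity(y, x))
  expect_equal(cosineSimilarity(3.7 * x, y), cosineSimilarity(x, y))
  expect_equal(cosineSimilarity(x, 2 * x), 1)
  expect_lt(cosineSimilarity(x, y), 1)
  expect_error(cosineSimilarity(x, rep(0, 96)), "zero vector")
})

test_that("catalogue parsing accepts both dialects and validates", {
  cat21 <- syntheticCatalogue(21)
  tsv <- tempfile(fileext = ".tsv")
  write.table(data.frame(Type = rownames(cat21), cat21,
                         check.names = FALSE),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  set <- loadSignatureCatalogue(tsv)
  expect_equal(length(set), 21)
  expect_equal(unname(colSums(spectrumWeights(set))), rep(1, 21))

  # shuffled rows parse identically (keyed by label)
  perm <- sample(96)
  write.table(data.frame(Type = rownames(cat21)[perm],
                         cat21[perm, , drop = FALSE],
                         check.names = FALSE),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(spectrumWeights(loadSignatureCatalogue(tsv)),
               spectrumWeights(set))

  # triplet-change dialect: ACA>AAA style
  lab <- rownames(cat21)
  tri <- paste0(substr(lab, 1, 1), substr(lab, 3, 3), substr(lab, 7, 7),
                ">", substr(lab, 1, 1), substr(lab, 5, 5),
                substr(lab, 7, 7))
  write.table(data.frame(Type = tri, cat21, check.names = FALSE),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(spectrumWeights(loadSignatureCatalogue(tsv)),
               spectrumWeights(set))

  # a missing class is reported by name
  write.table(data.frame(Type = rownames(cat21)[-96],
                         cat21[-96, , drop = FALSE], check.names = FALSE),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(loadSignatureCatalogue(tsv), "T\\[T>G\\]T")
  # duplicates are reported
  write.table(data.frame(Type = rownames(cat21)[c(1, 1:95)], cat21,
                         check.names = FALSE),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(loadSignatureCatalogue(tsv), "duplicate")
})

test_that("clustering merges identical spectra first and is complete", {
  lab <- sub96Labels()
  set.seed(31)
  base <- setNames(rexp(96), lab)
  twin1 <- buildSpectrum(base, "twin1")
  twin2 <- buildSpectrum(base * 2, "twin2")
  far1 <- buildSpectrum(setNames(c(rep(10, 8), rexp(88, 10)), lab),
                        "far1")
  far2 <- buildSpectrum(setNames(c(rexp(88, 10), rep(10, 8)), lab),
                        "far2")
  cl <- clusterSpectra(spectrumSet(twin1, twin2, far1, far2))
  expect_equal(nrow(cl@tree$merge), 3)   # n - 1 merges
  expect_equal(sort(cl@tree$merge[1, ]), c(-2, -1))
  expect_lt(cl@tree$height[1], 1e-9)
  expect_true(joinsBefore(cl, "twin1", "twin2"))

  # NpCpY-peaked samples cluster with each other before decoys join
  peak <- setNames(rep(0.01, 96), lab)
  peak[grepl("\\[C>T\\][CT]$", lab) | grepl("\\[C>T\\]", lab) &
         grepl("\\][CT]$", lab)] <- 3
  mk <- function(nm) buildSpectrum(peak * runif(96, 0.9, 1.1), nm)
  uniform <- buildSpectrum(setNames(rep(1, 96), lab), "uniform")
  sharpCA <- buildSpectrum(setNames(c(5, rep(0.01, 95)), lab), "sharpCA")
  cl2 <- clusterSpectra(spectrumSet(mk("s1"), mk("s2"), mk("s3"),
                                    uniform, sharpCA))
  expect_true(joinsBefore(cl2, c("s1", "s2"), "s3",
                          c("uniform", "sharpCA")))
  expect_error(clusterSpectra(spectrumSet(twin1)), "at least 2")
})

test_that("NpCpY fraction and Newick export behave", {
  lab <- sub96Labels()
  v <- setNames(rep(0, 96), lab)
  v["A[C>T]C"] <- 3; v["A[C>T]G"] <- 1   # 3' pyrimidine vs purine
  expect_equal(npcyFraction(buildSpectrum(v)), 0.75)
  vT <- setNames(rep(0, 96), lab); vT["A[T>C]A"] <- 1
  expect_true(is.na(npcyFraction(buildSpectrum(vT))))

  set.seed(32)
  sps <- lapply(1:4, function(i)
    buildSpectrum(setNames(rexp(96), lab), paste0("s", i)))
  cl <- clusterSpectra(spectrumSet(sps))
  nwk <- tempfile(fileext = ".nwk")
  writeNewick(cl, nwk)
  tree <- ape::read.tree(nwk)
  expect_setequal(tree$tip.label, paste0("s", 1:4))

  lt <- tempfile(fileext = ".tsv")
  writeLinkageTable(cl, lt)
  back <- read.delim(lt)
  expect_equal(nrow(back), 3)
  expect_equal(back$height, cl@tree$height)
})
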