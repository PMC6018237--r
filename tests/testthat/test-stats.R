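test_that("single-comparison Dunnett equals the pooled two-sample t-test", {
  set.seed(20)
  for (i in 1:5) {
    x <- rnorm(4); y <- rnorm(5, 0.8)
    res <- dunnettTest(x, list(trt = y))
    tt <- t.test(y, x, var.equal = TRUE)
    expect_equal(res@table$p.adj, tt$p.value, tolerance = 2e-3)
    expect_equal(res@table$statistic, unname(tt$statistic),
                 tolerance = 1e-8)
  }
  # one-sided variant
  x <- rnorm(3); y <- rnorm(3, 2)
  res1 <- dunnettTest(x, list(trt = y), alternative = "greater")
  tt1 <- t.test(y, x, var.equal = TRUE, alternative = "greater")
  expect_equal(res1@table$p.adj, tt1$p.value, tolerance = 2e-3)
})

test_that("Dunnett agrees with the multcomp reference implementation", {
  skip_if_not_installed("multcomp")
  set.seed(21)
  for (i in 1:4) {
    dat <- data.frame(
      y = c(rnorm(3), rnorm(3, 1), rnorm(3, 2), rnorm(3)),
      g = factor(rep(c("ctrl", "a", "b", "c"), each = 3),
                 levels = c("ctrl", "a", "b", "c")))
    res <- dunnettTest(dat$y[dat$g == "ctrl"],
                       list(a = dat$y[dat$g == "a"],
                            b = dat$y[dat$g == "b"],
                            c = dat$y[dat$g == "c"]))
    gl <- summary(multcomp::glht(stats::aov(y ~ g, dat),
                                 linfct = multcomp::mcp(g = "Dunnett")))
    expect_equal(res@table$statistic, unname(gl$test$tstat),
                 tolerance = 1e-6)
    expect_equal(res@table$p.adj, unname(as.numeric(gl$test$pvalues)),
                 tolerance = 5e-3)
  }
})

test_that("multiplicity never helps and degenerate input is handled", {
  set.seed(22)
  x <- rnorm(3)
  gs <- list(a = rnorm(3, 1), b = rnorm(3, 0.5), c = rnorm(3))
  res <- dunnettTest(x, gs)
  s <- res@pooledSD; df <- res@df
  for (i in seq_along(gs)) {
    praw <- 2 * pt(-abs(res@table$statistic[i]), df)
    expect_gte(res@table$p.adj[i] + 1e-9, praw)
  }
  expect_error(dunnettTest(x, list(a = 1)), "at least 2 replicates")
  expect_warning(r0 <- dunnettTest(c(1, 1, 1), list(a = c(1, 1, 1))),
                 "equal means")
  expect_equal(r0@table$p.adj, 1)
  expect_warning(r1 <- dunnettTest(c(1, 1, 1), list(a = c(2, 2, 2))),
                 "unequal means")
  expect_equal(r1@table$p.adj, 0)
  # p-values are reproducible (fixed internal integration seed)
  pa <- dunnettTest(c(0.1, -0.2, 0), list(g = c(1, 1.5, 0.8)))@table$p.adj
  pb <- dunnettTest(c(0.1, -0.2, 0), list(g = c(1, 1.5, 0.8)))@table$p.adj
  expect_identical(pa, pb)
})

test_that("decision rule matches the equicoordinate critical value", {
  set.seed(23)
  crit <- dunnettCritical(3, c(3, 3), alpha = 0.05)
  expect_gt(crit, qt(0.975, 6))  # stricter than a single t comparison
  for (i in 1:10) {
    x <- rnorm(3); gs <- list(a = rnorm(3, runif(1, 0, 3)),
                              b = rnorm(3, runif(1, 0, 3)))
    res <- dunnettTest(x, gs)
    rejectP <- any(res@table$p.adj < 0.05)
    rejectC <- max(abs(res@table$statistic)) > crit
    expect_equal(rejectP, rejectC)
  }
})

test_that("subsampling reproduces the full run, is seeded, power grows", {
  set.seed(24)
  g <- tinyGenome(2e4, seed = 24)
  model <- spectrumExposure(g, c("C>T" = 300, "T>C" = 150))
  mkSample <- function(src, nm) mergePairs(
    simulateReads(src, 6000, profile = uniformErrorProfile(1e-3),
                  sampleId = nm))
  samples <- list(c1 = mkSample(referencePool(g), "c1"),
                  c2 = mkSample(referencePool(g), "c2"),
                  e1 = mkSample(model, "e1"),
                  e2 = mkSample(model, "e2"))
  groups <- c(c1 = "control", c2 = "control", e1 = "exposed",
              e2 = "exposed")
  full <- min(vapply(samples, length, integer(1)))
  pcA <- suppressWarnings(
    subsamplePower(samples, groups, g, sizes = full, seed = 5))
  pcB <- suppressWarnings(
    subsamplePower(samples, groups, g, sizes = full, seed = 99))
  # drawing the full data reproduces the unsubsampled run however seeded
  expect_equal(pcA@table$p.adj, pcB@table$p.adj)
  expect_equal(pcA@table$meanDelta, pcB@table$meanDelta)
  # same seed, same curve
  pc1 <- suppressWarnings(subsamplePower(samples, groups, g,
                                         sizes = c(1000, full), seed = 7))
  pc2 <- suppressWarnings(subsamplePower(samples, groups, g,
                                         sizes = c(1000, full), seed = 7))
  expect_identical(pc1@table$p.adj, pc2@table$p.adj)
  expect_error(subsamplePower(samples, groups, g, sizes = full + 1,
                              seed = 1), "exceeds available")
  # average detection of the planted types does not drop with size
  # tiny subsamples legitimately produce degenerate all-zero types,
  # each of which warns
  pcm <- suppressWarnings(
    subsamplePower(samples, groups, g, sizes = c(500, 2000, full),
                   seed = 11, nIter = 5))
  tb <- pcm@table[pcm@table$type %in% c("C>T", "T>C"), ]
  rate <- tapply(tb$detected, tb$size, mean)
  rate <- rate[order(as.numeric(names(rate)))]
  # detection improves with depth on average (small-iteration noise can
  # wiggle adjacent sizes, but the largest must dominate the smallest)
  expect_gte(rate[[length(rate)]], rate[[1]])
  expect_gt(rate[[length(rate)]], 0)
})
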