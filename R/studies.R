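# Self-contained simulation studies: the spike-in validation series, the
# detection-limit sweep, the sub-sampling power analysis and the
# consensus error-suppression and Dunnett calibration checks. These are
# the workflows the package's acceptance checks and vignette run; every
# study is fully seeded.

# one sample through the standard pipeline
.samplePipeline <- function(pairs, genome, qMin = 30, minOverlap = 10,
                            maxMismatchFrac = 0.1, maxMismatches = 7,
                            dedup = TRUE, index = NULL, region = NULL,
                            sample = "sample", group = NA_character_,
                            dose = NA_real_) {
  merged <- mergePairs(pairs, minOverlap, maxMismatchFrac)
  nMerged <- length(merged)
  aligned <- alignExact(merged, genome, maxMismatches = maxMismatches,
                        method = if (is.null(index)) "auto" else "index",
                        index = index)
  rm(merged)
  if (dedup) aligned <- removeDuplicates(aligned)
  bcm <- buildBaseCounts(aligned, genome, qMin = qMin)
  list(nMerged = nMerged, counts = bcm,
       mft = countSubstitutions(bcm, genome, sample = sample,
                                group = group, dose = dose,
                                region = region))
}

#' Spike-in validation: recover designed mutation frequencies
#'
#' Simulates the plasmid spike-in series — control constructs plus samples
#' with the six single-substitution variants mixed at the given ratios —
#' sequences each at `nPairs` pairs, runs the full merge/align/count
#' pipeline (no duplicate removal, as appropriate for a plasmid library),
#' subtracts the control mean, and compares the recovered excess frequency
#' per base-pair class over the insert with the designed value computed
#' exactly from the construct.
#'
#' @param seed study seed.
#' @param nPairs read pairs per sample.
#' @param ratios variant mixing ratios; 1 means the pure variant mix,
#'   nominally 1000 per 1e6 class bp.
#' @param nControls number of control replicates.
#' @param profile [ErrorProfile] for the simulated sequencing.
#' @param qMin base quality threshold.
#' @return list with `table` (ratio, class, designed, recovered, binomial
#'   `se`), the `design`, per-sample frequency tables `mfts` and the
#'   per-ratio [DeltaFrequencyTable]s.
#' @export
runSpikeInValidation <- function(seed = 1, nPairs = 4e5,
                                 ratios = c(0.01, 0.1, 1), nControls = 3,
                                 profile = errorProfile(), qMin = 30) {
  set.seed(seed)
  design <- spikeInDesign()
  genome <- design@reference
  idx <- genomeIndex(genome)
  region <- insertRegion(design)
  run1 <- function(ratio, name) {
    pool <- makeSpikeInSample(design, ratio)
    pairs <- simulateReads(pool, nPairs, profile = profile,
                           sampleId = name)
    .samplePipeline(pairs, genome, qMin = qMin, dedup = FALSE,
                    index = idx, region = region, sample = name,
                    group = if (ratio == 0) "control" else
                      paste0("r", ratio))
  }
  ctrl <- lapply(seq_len(nControls), function(i)
    run1(0, paste0("control", i)))
  expo <- lapply(ratios, function(r) run1(r, paste0("ratio_", r)))
  ctrlM <- lapply(ctrl, `[[`, "mft")
  gcT <- c("C>A", "C>G", "C>T"); atT <- c("T>A", "T>C", "T>G")
  rows <- list(); deltas <- list()
  for (i in seq_along(ratios)) {
    mft <- expo[[i]]$mft
    del <- subtractBackground(mft, ctrlM)
    deltas[[paste0("ratio_", ratios[i])]] <- del
    des <- designedDeltas(design, ratios[i])
    for (cls in c("GC", "AT")) {
      tt <- if (cls == "GC") gcT else atT
      De <- if (cls == "GC") mft@denomGC else mft@denomAT
      rec <- sum(del@delta6[tt])
      fE <- sum(mft@freq6[tt]) / 1e6
      varC <- sum(vapply(ctrlM, function(c) {
        D <- if (cls == "GC") c@denomGC else c@denomAT
        sum(c@freq6[tt]) / 1e6 / D
      }, numeric(1))) / nControls^2
      se <- sqrt(fE / De + varC) * 1e6
      rows[[length(rows) + 1]] <- data.frame(
        ratio = ratios[i], class = cls,
        designed = if (cls == "GC") des$classGC else des$classAT,
        recovered = rec, se = se,
        nMergedPairs = expo[[i]]$nMerged)
    }
  }
  list(table = do.call(rbind, rows), design = design,
       mfts = c(ctrlM, lapply(expo, `[[`, "mft")), deltas = deltas)
}

#' Detection-limit sweep over designed per-type frequencies
#'
#' Simulates control replicates and, for each level, replicates exposed to
#' a context-uniform excess of every substitution type at that per-site
#' frequency, on a synthetic genome under the calibrated error model.
#' Each type is then tested across levels with Dunnett's test; the
#' detection limit is the smallest level at which every type shows a
#' significant positive increase.
#'
#' @param seed study seed.
#' @param levels designed per-type frequencies (per bp).
#' @param nPairs read pairs per sample.
#' @param nReps replicates per group.
#' @param genomeSize synthetic genome length.
#' @param profile [ErrorProfile].
#' @param alpha significance level.
#' @return list with `detected` (type x level logical matrix), `pvalues`,
#'   `limit` (the detection limit, NA if no level detects all types) and
#'   the per-sample frequency matrix.
#' @export
detectionLimitStudy <- function(seed = 1, levels = c(1e-4, 1e-5, 1e-6),
                                nPairs = 2e5, nReps = 3,
                                genomeSize = 1e6,
                                profile = errorProfile(), alpha = 0.05) {
  set.seed(seed)
  genome <- referenceFromSeq(c(chr = randomDna(genomeSize)))
  idx <- genomeIndex(genome)
  levels <- sort(levels, decreasing = TRUE)
  pool0 <- referencePool(genome)
  freqs <- list()
  for (i in seq_len(nReps)) {
    name <- paste0("control", i)
    pr <- simulateReads(pool0, nPairs, profile = profile, sampleId = name)
    freqs[[name]] <- list(group = "control",
                          f = .samplePipeline(pr, genome, dedup = TRUE,
                                              index = idx,
                                              sample = name)$mft@freq6)
  }
  for (lv in levels) {
    model <- uniformExposure(genome, setNames(rep(lv, 6), SUB_TYPES))
    for (i in seq_len(nReps)) {
      name <- paste0("level", lv, "_", i)
      pr <- simulateReads(model, nPairs, profile = profile,
                          sampleId = name)
      freqs[[name]] <- list(group = paste0("level", lv),
                            f = .samplePipeline(pr, genome, dedup = TRUE,
                                                index = idx,
                                                sample = name)$mft@freq6)
    }
  }
  groups <- vapply(freqs, `[[`, "", "group")
  fm <- vapply(freqs, `[[`, numeric(6), "f")
  glab <- paste0("level", levels)
  detected <- matrix(FALSE, 6, length(levels),
                     dimnames = list(SUB_TYPES, as.character(levels)))
  pvals <- detected + NA_real_
  for (t in SUB_TYPES) {
    dt <- dunnettTest(fm[t, groups == "control"],
                      lapply(setNames(glab, glab), function(g)
                        fm[t, groups == g]))
    tb <- dt@table
    detected[t, ] <- tb$p.adj < alpha & tb$diff > 0
    pvals[t, ] <- tb$p.adj
  }
  allDet <- apply(detected, 2, all)
  list(detected = detected, pvalues = pvals,
       limit = if (any(allDet)) min(levels[allDet]) else NA_real_,
       frequencies = fm, groups = groups, alpha = alpha)
}

#' Sub-sampling power analysis at mutagen-scale effect sizes
#'
#' Simulates control and exposed replicates on a synthetic genome — the
#' exposure plants a 3'-pyrimidine-peaked C>T excess plus smaller A:T-type
#' excesses (an alkylating-agent-like pattern) with a lognormal
#' between-replicate biological multiplier — then draws the requested
#' numbers of merged pairs per sample and reruns counting and Dunnett
#' testing at each size ([subsamplePower()]). The exposure is "detected"
#' at a size when every planted type shows a significant positive
#' increase. The recovered 96-class spectrum at full depth is also
#' compared to the planted spectrum by cosine similarity.
#'
#' @param seed study seed.
#' @param sizes merged-pair counts to draw.
#' @param nPairsSim simulated pairs per sample (must leave at least
#'   `max(sizes)` merged pairs).
#' @param nReps replicates per group.
#' @param genomeSize synthetic genome length.
#' @param perTypePerMillion planted excess frequencies per 1e6 class bp.
#' @param bioCV lognormal sdlog of the per-replicate exposure multiplier.
#' @param profile [ErrorProfile].
#' @param alpha significance level.
#' @return list with the [PowerCurve] `power`, `detectedBySize`,
#'   `cosine` (recovered vs planted spectrum), both spectra, and the
#'   planted type set.
#' @export
powerStudy <- function(seed = 1, sizes = c(1e5, 1e6), nPairsSim = 1.05e6,
                       nReps = 3, genomeSize = 2e6,
                       perTypePerMillion = c("C>T" = 47.5, "T>A" = 11,
                                             "T>C" = 11, "T>G" = 0.5),
                       bioCV = 0.15, profile = errorProfile(),
                       alpha = 0.05) {
  set.seed(seed)
  genome <- referenceFromSeq(c(chr = randomDna(genomeSize)))
  idx <- genomeIndex(genome)
  ctx <- .npcyWeights()
  pool0 <- referencePool(genome)
  # samples are handed to subsamplePower as seeded generators so that
  # only one sample's reads are ever materialized at a time
  mkGen <- function(src, nm, simSeed) {
    force(src); force(nm); force(simSeed)
    function() mergePairs(simulateReads(src, nPairsSim,
                                        profile = profile,
                                        sampleId = nm, seed = simSeed))
  }
  samples <- list(); groups <- character()
  models <- list()
  for (i in seq_len(nReps)) {
    nm <- paste0("control", i)
    samples[[nm]] <- mkGen(pool0, nm, sample.int(2^31 - 1, 1))
    groups[nm] <- "control"
  }
  for (i in seq_len(nReps)) {
    nm <- paste0("exposed", i)
    mult <- rlnorm(1, -bioCV^2 / 2, bioCV)
    model <- spectrumExposure(genome, perTypePerMillion * mult, ctx)
    models[[nm]] <- model
    samples[[nm]] <- mkGen(model, nm, sample.int(2^31 - 1, 1))
    groups[nm] <- "exposed"
  }
  pc <- subsamplePower(samples, groups, genome, sizes, seed = seed + 1,
                       dedup = TRUE, alpha = alpha, index = idx)
  tb <- pc@table
  planted <- names(perTypePerMillion)
  detectedBySize <- vapply(sizes, function(s)
    all(tb$detected[tb$size == s & tb$type %in% planted]), logical(1))
  names(detectedBySize) <- as.character(sizes)
  # spectrum recovery at the deepest subsample
  d96 <- attr(tb, "delta96BySize")[[as.character(max(sizes))]]
  recovered <- buildSpectrum(d96, name = "recovered")
  plantedSpec <- buildSpectrum(expectedDeltas(models[[1]]),
                               name = "planted")
  list(power = pc, detectedBySize = detectedBySize,
       cosine = cosineSimilarity(recovered, plantedSpec),
       recoveredSpectrum = recovered, plantedSpectrum = plantedSpec,
       plantedTypes = planted, alpha = alpha)
}

# NpCpY-peaked context weights for C>T: 3'-pyrimidine classes get weight
# 7, others 1 (a sharp alkylating-agent-like peak)
.npcyWeights <- function() {
  lab <- SUB96[grepl("[C>T]", SUB96, fixed = TRUE)]
  setNames(ifelse(grepl("\\][CT]$", lab), 7, 1), lab)
}

#' Expected 96-class excess frequencies of an exposure model
#'
#' The excess frequency per 1e6 class base calls each class is expected to
#' show: rate times strand-resolved site count over the class denominator.
#'
#' @param model an [ExposureModel].
#' @return named numeric vector over the 96 classes (per 1e6 class bp).
#' @export
expectedDeltas <- function(model) {
  genome <- model@reference
  codes <- .genomeCodes(genome)
  tripN <- tabulate(codes$trip + 1L, nbins = 64)
  nSites <- setNames(numeric(96), SUB96)
  for (t in 0:63) {
    if (tripN[t + 1] == 0) next
    for (a in 0:3) {
      ci <- CLASS_LUT[t + 1, a + 1]
      if (!is.na(ci)) nSites[ci] <- nSites[ci] + tripN[t + 1]
    }
  }
  denom <- c(GC = genome@nGC, AT = genome@nAT)[
    rep(c(1, 2), each = 48)]
  model@rate96 * nSites / denom * 1e6
}

#' Consensus error-suppression check against the closed form
#'
#' Simulates error-free templates sequenced with a uniform per-base
#' miscall probability `e`, merges the pairs, and measures the rate of
#' wrong (non-N, non-reference) consensus bases inside the overlap using
#' the known fragment positions. Both mates must miscall a base to the
#' same alternative for the error to survive, so the expected rate is
#' e^2/3.
#'
#' @param seed study seed.
#' @param e total per-base miscall probability.
#' @param nPairs simulated pairs.
#' @param refLen template length.
#' @return list with `observed`, `expected` (= e^2/3), `ratio`,
#'   `nWrong` and `nBases`.
#' @export
consensusErrorStudy <- function(seed = 1, e = 1e-2, nPairs = 1e5,
                                refLen = 5000) {
  set.seed(seed)
  genome <- referenceFromSeq(c(chr = randomDna(refLen)))
  pairs <- simulateReads(referencePool(genome), nPairs,
                         profile = uniformErrorProfile(e))
  merged <- mergePairs(pairs)
  tr <- merged@metadata$truth
  gseq <- as.character(genome@sequences[[1]])
  refFrag <- substring(gseq, tr$fragStart + 1, tr$fragStart + tr$fragLen)
  rev <- !tr$read1Forward
  refFrag[rev] <- revcomp_cpp(refFrag[rev])
  cmp <- mismatch_count_cpp(merged@seq, refFrag)
  nWrong <- sum(cmp$mismatch)
  nBases <- sum(cmp$compared)
  expected <- e^2 / 3
  list(observed = nWrong / nBases, expected = expected,
       ratio = (nWrong / nBases) / expected, nWrong = nWrong,
       nBases = nBases, maskedFraction = sum(merged@nMasked) /
         sum(nchar(merged@seq)))
}

#' Monte-Carlo family-wise type-I error of the Dunnett procedure
#'
#' Simulates null families (all groups drawn from one normal) and applies
#' the implemented test's decision rule — reject when the largest absolute
#' Dunnett statistic exceeds the equicoordinate critical value, which is
#' equivalent to any adjusted p-value falling below alpha.
#'
#' @param seed study seed.
#' @param nSim number of simulated families.
#' @param nGroups dose groups per family.
#' @param nRep replicates per group (and control).
#' @param alpha nominal family-wise level.
#' @return list with `typeI`, the `critical` value and the Monte-Carlo
#'   standard error.
#' @export
dunnettTypeIStudy <- function(seed = 1, nSim = 1e4, nGroups = 2, nRep = 3,
                              alpha = 0.05) {
  set.seed(seed)
  crit <- dunnettCritical(nRep, rep(nRep, nGroups), alpha = alpha)
  k <- nGroups + 1
  x <- array(rnorm(nSim * k * nRep), c(nSim, k, nRep))
  m <- apply(x, c(1, 2), mean)
  ss <- apply(x, c(1, 2), function(v) sum((v - mean(v))^2))
  df <- k * (nRep - 1)
  s2 <- rowSums(ss) / df
  se <- sqrt(s2 * 2 / nRep)
  tmax <- apply(abs(m[, -1, drop = FALSE] - m[, 1]) / se, 1, max)
  rate <- mean(tmax > crit)
  list(typeI = rate, critical = crit,
       mcse = sqrt(rate * (1 - rate) / nSim), nSim = nSim)
}

#' Strand-bias artifact demonstration
#'
#' Simulates a sample with the oxidative G>T artifact enabled and one with
#' it disabled, runs the pipeline, and returns both strand-bias
#' diagnostics; with the artifact on, exactly the C>A type (read-1 purine
#' G>T orientation) should be flagged.
#'
#' @param seed study seed.
#' @param nPairs pairs per sample.
#' @param refLen synthetic reference length.
#' @param oxoRate artifact rate for the artifact-on sample.
#' @param profile base [ErrorProfile]; its oxoRate is overridden.
#' @return list with diagnostics `withArtifact` and `withoutArtifact`.
#' @export
strandBiasStudy <- function(seed = 1, nPairs = 2e5, refLen = 2e5,
                            oxoRate = 3e-5, profile = errorProfile()) {
  set.seed(seed)
  genome <- referenceFromSeq(c(chr = randomDna(refLen)))
  idx <- genomeIndex(genome)
  pool <- referencePool(genome)
  run1 <- function(oxo, nm) {
    pf <- errorProfile(misRates = profile@misRates, oxoRate = oxo,
                       qualPhred = profile@qualPhred,
                       jitterSdLog = profile@jitterSdLog,
                       oxoJitterSdLog = profile@oxoJitterSdLog)
    pr <- simulateReads(pool, nPairs, profile = pf, sampleId = nm)
    pp <- .samplePipeline(pr, genome, dedup = FALSE, index = idx,
                          sample = nm)
    strandBiasDiagnostic(pp$counts, genome)
  }
  list(withArtifact = run1(oxoRate, "oxo"),
       withoutArtifact = run1(0, "clean"))
}
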