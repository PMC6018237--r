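# Synthetic data: spike-in validation constructs, mutagen-exposure models
# and paired-end read simulation with a calibrated error model.

#' Random DNA sequence
#' @param n length in bp.
#' @return a single uppercase sequence string.
#' @export
randomDna <- function(n)
  paste(sample(BASES, n, replace = TRUE), collapse = "")

#' Sequencing error profile
#'
#' Constructs an [ErrorProfile]. The default calibration places the
#' post-consensus residual background (the square of the per-mate miscall
#' rate, since only identical independent miscalls in both mates survive
#' the overlap consensus) between 1e-6 and 1e-5 per bp depending on the
#' substitution type, and adds a fragment-level oxidative G>T artifact
#' (3e-5 on the read-1 strand) that survives the consensus and is therefore
#' visible as a strand-biased G:C>T:A background — the error structure
#' typical of HiSeq libraries of this design. Per-sample lognormal jitter
#' emulates library-to-library rate variability.
#'
#' @param misRates 4x4 per-base miscall rate matrix (true base in rows,
#'   called base in columns, A,C,G,T order), each rate in `[0, 0.01]`.
#' @param oxoRate fragment-level G>T rate on the read-1 strand.
#' @param qualPhred flat base quality for simulated reads.
#' @param jitterSdLog,oxoJitterSdLog sdlog of per-sample rate multipliers.
#' @return an [ErrorProfile].
#' @export
errorProfile <- function(misRates = NULL, oxoRate = 3e-5, qualPhred = 37,
                         jitterSdLog = 0.02, oxoJitterSdLog = 0.05) {
  if (is.null(misRates)) {
    m <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
    set <- function(pyr, rate) {
      r <- substr(pyr, 1, 1); a <- substr(pyr, 3, 3)
      m[r, a] <<- rate
      m[COMPLEMENT[[r]], COMPLEMENT[[a]]] <<- rate
    }
    set("C>T", sqrt(1e-5))   # residual background 1e-5
    set("C>A", sqrt(1e-5))   # plus the oxidative artifact on one strand
    set("C>G", 1e-3)         # residual 1e-6
    set("T>C", sqrt(1e-5))
    set("T>A", sqrt(3e-6))
    set("T>G", 1e-3)
    misRates <- m
  }
  p <- methods::new("ErrorProfile", misRates = misRates, oxoRate = oxoRate,
                    qualPhred = qualPhred, jitterSdLog = jitterSdLog,
                    oxoJitterSdLog = oxoJitterSdLog)
  validObject(p)
  p
}

#' Uniform error profile without artifacts
#'
#' All twelve miscalls share rate `e / 3` (total per-base miscall
#' probability `e`), no oxidative artifact, no jitter. Residual
#' post-consensus errors then occur at the closed-form rate e^2/3.
#'
#' @param e total per-base miscall probability.
#' @inheritParams errorProfile
#' @return an [ErrorProfile].
#' @export
uniformErrorProfile <- function(e, qualPhred = 37) {
  m <- matrix(e / 3, 4, 4, dimnames = list(BASES, BASES))
  diag(m) <- 0
  errorProfile(misRates = m, oxoRate = 0, qualPhred = qualPhred,
               jitterSdLog = 0, oxoJitterSdLog = 0)
}

setMethod("show", "ErrorProfile", function(object) {
  cat("ErrorProfile: total miscall per base",
      signif(max(rowSums(object@misRates)), 3),
      "(max); oxo G>T", object@oxoRate, "; Q", object@qualPhred, "\n")
})

#' Spike-in validation construct design
#'
#' Builds the control construct — a backbone standing in for the cloning
#' vector (its true sequence is proprietary; only base composition matters
#' to frequencies, so a seeded random stand-in is used) with a random
#' insert placed centrally so insert coverage is uniform under
#' fragmentation — plus the six single-substitution variants: the insert's
#' central G:C site and the adjacent A:T site are each replaced by the
#' three alternative base pairs. The insert is regenerated (up to 100
#' seeded tries) until those two sites carry a G:C and an A:T pair.
#'
#' @param insertLen insert length (default 1000).
#' @param backboneLen backbone length (default 2660).
#' @param seed optional RNG seed.
#' @return a [SpikeInDesign].
#' @export
spikeInDesign <- function(insertLen = 1000, backboneLen = 2660,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(insertLen >= 10)
  backbone <- randomDna(backboneLen)
  gcOff <- insertLen %/% 2       # the classic mid-insert G:C site
  atOff <- gcOff + 1L
  insert <- NULL
  for (try in seq_len(100)) {
    cand <- randomDna(insertLen)
    b1 <- substr(cand, gcOff + 1, gcOff + 1)
    b2 <- substr(cand, atOff + 1, atOff + 1)
    if (b1 %in% c("G", "C") && b2 %in% c("A", "T")) { insert <- cand; break }
  }
  if (is.null(insert))
    stop("could not generate an insert with the required base pairs")
  half <- backboneLen %/% 2
  construct <- paste0(substr(backbone, 1, half), insert,
                      substr(backbone, half + 1, backboneLen))
  insertStart <- half
  gcPos <- insertStart + gcOff
  atPos <- insertStart + atOff
  gcRef <- substr(construct, gcPos + 1, gcPos + 1)
  atRef <- substr(construct, atPos + 1, atPos + 1)
  variants <- character()
  for (alt in setdiff(BASES, gcRef)) {
    v <- construct
    substr(v, gcPos + 1, gcPos + 1) <- alt
    variants[paste0("GC_", gcRef, ">", alt)] <- v
  }
  for (alt in setdiff(BASES, atRef)) {
    v <- construct
    substr(v, atPos + 1, atPos + 1) <- alt
    variants[paste0("AT_", atRef, ">", alt)] <- v
  }
  ref <- referenceFromSeq(c(construct = construct))
  insSeq <- substr(construct, insertStart + 1, insertStart + insertLen)
  comp <- table(factor(strsplit(insSeq, "")[[1]], levels = BASES))
  methods::new("SpikeInDesign", reference = ref,
               insertStart = as.integer(insertStart),
               insertEnd = as.integer(insertStart + insertLen),
               gcPos = as.integer(gcPos), atPos = as.integer(atPos),
               gcRef = gcRef, atRef = atRef, variants = variants,
               nGCInsert = unname(comp[["C"]] + comp[["G"]]),
               nATInsert = unname(comp[["A"]] + comp[["T"]]))
}

setMethod("show", "SpikeInDesign", function(object) {
  cat("SpikeInDesign:", length(object@reference), "bp construct, insert [",
      object@insertStart, ",", object@insertEnd, ")\n")
  cat("  variant sites:", object@gcPos, "(", object@gcRef, "),",
      object@atPos, "(", object@atRef, ")\n")
})

#' Reference genome of a spike-in design (the control construct)
#' @param design a [SpikeInDesign].
#' @return a [ReferenceGenome].
#' @export
designReference <- function(design) design@reference

#' Insert region of a spike-in design
#' @param design a [SpikeInDesign].
#' @return region list usable with [countSubstitutions()].
#' @export
insertRegion <- function(design)
  list(contig = "construct", start = design@insertStart,
       end = design@insertEnd)

#' Designed excess frequencies of a spike-in mixture
#'
#' Computed from the actual construct composition (not the nominal rounded
#' labels): with the six variants mixed at total ratio `ratio` against the
#' control (variants only when `ratio >= 1`), the expected excess
#' frequency of each substitution type over the insert is the variant
#' molecule fraction divided by the insert's class site count.
#'
#' @param design a [SpikeInDesign].
#' @param ratio mixing ratio (0, or up to 1 = pure variants).
#' @return list with `perType6` (per 1e6 class bp), `classGC`, `classAT`
#'   (per-class totals) and `per96` (designed 96-class deltas).
#' @export
designedDeltas <- function(design, ratio) {
  stopifnot(ratio >= 0)
  wc <- if (ratio >= 1) 0 else 1
  wv <- if (ratio >= 1) 1 / 6 else ratio / 6
  pVar <- wv / (wc + 6 * wv)          # fraction carrying one given variant
  perType <- setNames(numeric(6), SUB_TYPES)
  per96 <- setNames(numeric(96), SUB96)
  ref <- design@reference
  ctx <- contextAt(ref, "construct", c(design@gcPos, design@atPos))
  for (i in 1:2) {
    refBase <- c(design@gcRef, design@atRef)[i]
    nClass <- c(design@nGCInsert, design@nATInsert)[i]
    for (alt in setdiff(BASES, refBase)) {
      cls <- classifySubstitution(refBase, alt, ctx$left[i], ctx$right[i])
      d <- pVar / nClass * 1e6
      perType[cls$subType] <- perType[cls$subType] + d
      per96[cls$label] <- per96[cls$label] + d
    }
  }
  list(perType6 = perType,
       classGC = sum(perType[c("C>A", "C>G", "C>T")]),
       classAT = sum(perType[c("T>A", "T>C", "T>G")]),
       per96 = per96, ratio = ratio)
}

#' Realize a spike-in sample as a weighted molecule pool
#'
#' @param design a [SpikeInDesign].
#' @param ratio mixing ratio of the variant pool to the control construct;
#'   `ratio >= 1` means the variant mix alone (the highest-frequency
#'   sample of the validation series), `0` the pure control.
#' @return a [MoleculePool]; `truth` holds the [designedDeltas()] output
#'   and the per-molecule variant events.
#' @export
makeSpikeInSample <- function(design, ratio) {
  wc <- if (ratio >= 1) 0 else 1
  wv <- if (ratio >= 1) 1 / 6 else ratio / 6
  seqs <- c(control = as.character(design@reference@sequences[[1]]),
            design@variants)
  weights <- c(wc, rep(wv, 6))
  keep <- weights > 0
  kept <- which(keep)
  # variant vi (1..6): the first three alter the G:C site, the rest the
  # A:T site; molecule indices refer to the kept pool
  ev <- do.call(rbind, lapply(intersect(1:6, kept - 1L), function(vi) {
    pos <- if (vi <= 3) design@gcPos else design@atPos
    refBase <- if (vi <= 3) design@gcRef else design@atRef
    alt <- setdiff(BASES, refBase)[(vi - 1) %% 3 + 1]
    data.frame(molecule = match(vi + 1L, kept), pos = pos,
               ref = refBase, alt = alt)
  }))
  if (is.null(ev))
    ev <- data.frame(molecule = integer(), pos = integer(),
                     ref = character(), alt = character())
  methods::new("MoleculePool", sequences = unname(seqs[keep]),
               weights = weights[keep], reference = design@reference,
               truth = list(designed = designedDeltas(design, ratio),
                            events = ev))
}

setMethod("show", "MoleculePool", function(object) {
  cat("MoleculePool with", length(object@sequences), "molecule species\n")
})

#' Write a simulation truth set as TSV
#'
#' For a [MoleculePool] the per-molecule planted substitutions are
#' written; for [ReadPairs] from [simulateReads()], the per-read planted
#' events. Columns: molecule/read id, 0-based position, ref, alt, and —
#' for molecule pools — the 96 class where context exists.
#'
#' @param x a [MoleculePool] or [ReadPairs] carrying truth metadata.
#' @param path output path.
#' @export
writeTruthSet <- function(x, path) {
  ev <- if (methods::is(x, "MoleculePool")) x@truth$events
        else x@metadata$truth$events
  if (is.null(ev)) stop("no truth events recorded")
  if (!is.null(ev$pos) && nrow(ev) && is.null(ev$class)) {
    ref <- if (methods::is(x, "MoleculePool")) x@reference
           else NULL
    if (!is.null(ref)) {
      ctx <- contextAt(ref, names(ref@sequences)[1], ev$pos)
      ev$class <- NA_character_
      hc <- ctx$hasContext
      if (any(hc))
        ev$class[hc] <- classifySubstitution(ev$ref[hc], ev$alt[hc],
                                             ctx$left[hc],
                                             ctx$right[hc])$label
    }
  }
  write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reference-only molecule pool (no mutations)
#' @param genome a [ReferenceGenome] (single contig).
#' @return a [MoleculePool].
#' @export
referencePool <- function(genome) {
  stopifnot(length(genome@sequences) == 1)
  methods::new("MoleculePool",
               sequences = as.character(genome@sequences[[1]]),
               weights = 1, reference = genome, truth = list())
}

.exposureNew <- function(genome, rate96, rateNoContext) {
  stopifnot(length(genome@sequences) == 1)
  rate96 <- rate96[SUB96]
  names(rate96) <- SUB96
  rate96[is.na(rate96)] <- 0
  rateNoContext <- rateNoContext[SUB_TYPES]
  names(rateNoContext) <- SUB_TYPES
  rateNoContext[is.na(rateNoContext)] <- 0
  if (any(rate96 < 0) || any(rateNoContext < 0))
    stop("rates must be non-negative")
  # per-site total rate must stay small or the independent-event model is
  # being misused
  perSite <- vapply(0:63, function(t) {
    s <- 0
    for (a in 0:3) {
      ci <- CLASS_LUT[t + 1, a + 1]
      if (!is.na(ci)) s <- s + rate96[ci]
    }
    s
  }, numeric(1))
  if (max(perSite, sum(rateNoContext[1:3]), sum(rateNoContext[4:6])) > 0.01)
    stop("per-site mutation rate exceeds 0.01; model misuse")
  methods::new("ExposureModel", reference = genome, rate96 = rate96,
               rateNoContext = rateNoContext)
}

#' Context-uniform exposure model
#'
#' Every site of a type's base-pair class mutates to the type's alternative
#' with the same per-site probability, so the expected excess frequency per
#' class base call equals the per-site rate exactly.
#'
#' @param genome single-contig [ReferenceGenome].
#' @param perTypeRate named per-site rates (per bp per molecule) for the
#'   six types; missing types default to 0.
#' @return an [ExposureModel].
#' @export
uniformExposure <- function(genome, perTypeRate) {
  full <- setNames(numeric(6), SUB_TYPES)
  full[names(perTypeRate)] <- perTypeRate
  lab <- sub96Labels()
  r96 <- setNames(full[sub("^.\\[(.>.)\\].$", "\\1", lab)], lab)
  .exposureNew(genome, r96, full)
}

#' Context-profiled exposure model
#'
#' Distributes each type's target excess frequency across its 16
#' trinucleotide classes proportionally to `contextWeights`, converting
#' class weights to per-site rates using the genome's triplet composition,
#' so the planted 96-class spectrum matches the weights.
#'
#' @param genome single-contig [ReferenceGenome].
#' @param perTypePerMillion named target excess frequencies per 1e6 class
#'   base calls for the six types.
#' @param contextWeights named non-negative weights over (a subset of) the
#'   96 classes; types without entries get uniform per-site rates.
#' @return an [ExposureModel].
#' @export
spectrumExposure <- function(genome, perTypePerMillion,
                             contextWeights = NULL) {
  full <- setNames(numeric(6), SUB_TYPES)
  full[names(perTypePerMillion)] <- perTypePerMillion
  codes <- .genomeCodes(genome)
  tripN <- tabulate(codes$trip + 1L, nbins = 64)
  nSites <- setNames(numeric(96), SUB96)   # strand-resolved site counts
  for (t in 0:63) {
    if (tripN[t + 1] == 0) next
    for (a in 0:3) {
      ci <- CLASS_LUT[t + 1, a + 1]
      if (!is.na(ci)) nSites[ci] <- nSites[ci] + tripN[t + 1]
    }
  }
  nClass <- c(GC = genome@nGC, AT = genome@nAT)
  r96 <- setNames(numeric(96), SUB96)
  for (type in SUB_TYPES) {
    idx <- grepl(paste0("[", type, "]"), SUB96, fixed = TRUE)
    w <- setNames(rep(1, 16), SUB96[idx])
    if (!is.null(contextWeights)) {
      hit <- intersect(names(contextWeights), names(w))
      if (length(hit)) {
        w[] <- 0
        w[hit] <- contextWeights[hit]
      }
    }
    if (is.null(contextWeights) || !length(intersect(names(contextWeights),
                                                     names(w)))) {
      # uniform per-site rate: weight classes by their site counts
      w <- nSites[names(w)]
    }
    if (sum(w) == 0 || full[type] == 0) next
    w <- w / sum(w)
    cls <- if (substr(type, 1, 1) == "C") "GC" else "AT"
    target <- full[type] / 1e6 * w      # per-class delta per class bp
    ok <- nSites[names(w)] > 0
    r96[names(w)[ok]] <- target[ok] * nClass[cls] / nSites[names(w)[ok]]
  }
  .exposureNew(genome, r96, full / 1e6)
}

setMethod("show", "ExposureModel", function(object) {
  tot <- vapply(SUB_TYPES, function(t)
    sum(object@rate96[grepl(paste0("[", t, "]"), SUB96, fixed = TRUE)]),
    numeric(1))
  cat("ExposureModel; summed class rates per type:\n")
  print(signif(tot, 3))
})

#' Materialize a finite exposed molecule population
#'
#' Plants substitutions as independent per-site events with each class's
#' rate across `n` copies of the reference, returning the mutated
#' molecules and the exact truth set.
#'
#' @param model an [ExposureModel].
#' @param n number of molecules.
#' @param seed optional RNG seed.
#' @return a [MoleculePool] whose `truth$events` records every planted
#'   substitution (molecule, 0-based pos, ref, alt, class label).
#' @export
simulateExposedMolecules <- function(model, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genome <- model@reference
  gseq <- as.character(genome@sequences[[1]])
  rates <- .siteAltRates(model)
  ev <- list()
  for (a in 0:3) {
    r <- rates[, a + 1]
    pos <- which(r > 0)
    if (!length(pos)) next
    # independent Bernoulli per (molecule, site)
    for (pgrp in split(pos, r[pos])) {
      rate <- r[pgrp[1]]
      cnt <- rbinom(1, n * length(pgrp), rate)
      if (cnt == 0) next
      mol <- sample.int(n, cnt, replace = TRUE)
      site <- pgrp[sample.int(length(pgrp), cnt, replace = TRUE)]
      ev[[length(ev) + 1]] <- data.frame(molecule = mol, pos = site - 1L,
                                         alt = BASES[a + 1])
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(molecule = integer(), pos = integer(), alt = character())
  if (nrow(events))  # one event per (molecule, site)
    events <- events[!duplicated(events[c("molecule", "pos")]), ,
                     drop = FALSE]
  seqs <- rep(gseq, n)
  if (nrow(events)) {
    events$ref <- substring(gseq, events$pos + 1, events$pos + 1)
    events <- events[events$ref != events$alt, , drop = FALSE]
    ctx <- contextAt(genome, names(genome@sequences)[1], events$pos)
    events$class <- NA_character_
    hc <- ctx$hasContext
    if (any(hc))
      events$class[hc] <- classifySubstitution(events$ref[hc],
                                               events$alt[hc],
                                               ctx$left[hc],
                                               ctx$right[hc])$label
    for (i in seq_len(nrow(events)))
      substr(seqs[events$molecule[i]], events$pos[i] + 1,
             events$pos[i] + 1) <- events$alt[i]
  }
  methods::new("MoleculePool", sequences = seqs,
               weights = rep(1, n), reference = genome,
               truth = list(events = events))
}

# G x 4 per-site per-alt mutation rates for an exposure model
.siteAltRates <- function(model) {
  genome <- model@reference
  codes <- .genomeCodes(genome)
  G <- length(codes$ref)
  rates <- matrix(0, G, 4)
  hasCtx <- codes$trip >= 0
  for (a in 0:3) {
    v <- numeric(G)
    ci <- CLASS_LUT[codes$trip[hasCtx] + 1L, a + 1L]
    v[hasCtx] <- ifelse(is.na(ci), 0, model@rate96[ifelse(is.na(ci), 1, ci)])
    noCtx <- !hasCtx & !is.na(codes$ref) & codes$ref != a
    if (any(noCtx)) {
      ti <- .TYPE_LUT[codes$ref[noCtx] + 1L, a + 1L]
      v[noCtx] <- model@rateNoContext[ti]
    }
    rates[, a + 1] <- v
  }
  rates
}

#' Simulate paired-end reads from a molecule pool or exposure model
#'
#' Draws fragments uniformly from weighted molecules (finite pool) or from
#' the reference with per-fragment event planting (exposure model, an
#' effectively infinite population), assigns each fragment a random read-1
#' strand, applies the fragment-level oxidative artifact to the read-1
#' strand, then sequences both ends with independent per-base miscalls.
#' With the default 150 bp fragments and 2x150 reads each pair overlaps
#' completely.
#'
#' @param source a [MoleculePool] or [ExposureModel].
#' @param nPairs number of read pairs.
#' @param readLen read length (default 150).
#' @param fragLen fragment length: a scalar, or a function of `n` returning
#'   lengths. Fragments longer than the molecule are clipped.
#' @param profile an [ErrorProfile].
#' @param seed optional RNG seed (same seed, same reads).
#' @param sampleId carried into the read ids.
#' @return a [ReadPairs] whose `metadata$truth` records per read the
#'   0-based fragment start, read-1 orientation, source molecule (finite
#'   pools) and all planted substitutions overlapping the fragment
#'   (`events`: read, pos, ref, alt).
#' @export
simulateReads <- function(source, nPairs, readLen = 150, fragLen = 150,
                          profile = errorProfile(), seed = NULL,
                          sampleId = "sim") {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nPairs >= 1)
  multM <- if (profile@jitterSdLog > 0)
    rlnorm(1, -profile@jitterSdLog^2 / 2, profile@jitterSdLog) else 1
  multO <- if (profile@oxoJitterSdLog > 0)
    rlnorm(1, -profile@oxoJitterSdLog^2 / 2, profile@oxoJitterSdLog) else 1
  finite <- methods::is(source, "MoleculePool")
  genome <- source@reference
  gname <- names(genome@sequences)[1]
  fl <- if (is.function(fragLen)) as.integer(round(fragLen(nPairs)))
        else rep(as.integer(fragLen), nPairs)
  if (finite) {
    molLen <- nchar(source@sequences)
    mol <- sample.int(length(source@sequences), nPairs, replace = TRUE,
                      prob = source@weights)
    fl <- pmin(fl, molLen[mol])
    start <- floor(runif(nPairs) * (molLen[mol] - fl + 1))
    frag <- substring(source@sequences[mol], start + 1, start + fl)
    events <- .poolFragmentEvents(source, mol, start, fl)
  } else {
    gseq <- as.character(genome@sequences[[1]])
    L <- nchar(gseq)
    fl <- pmin(fl, L)
    mol <- rep(NA_integer_, nPairs)
    start <- floor(runif(nPairs) * (L - fl + 1))
    frag <- substring(gseq, start + 1, start + fl)
    planted <- .plantFragmentEvents(source, frag, start)
    frag <- planted$frag
    events <- planted$events
  }
  r1fwd <- runif(nPairs) < 0.5
  tmpl <- frag
  if (any(!r1fwd)) tmpl[!r1fwd] <- revcomp_cpp(frag[!r1fwd])
  if (profile@oxoRate > 0) {
    oxo <- matrix(0, 4, 4)
    oxo[3, 4] <- min(profile@oxoRate * multO, 1)   # G -> T
    tmpl <- apply_errors_cpp(tmpl, oxo)
  }
  if (all(fl <= readLen)) {          # reads span the whole fragment
    m1t <- tmpl
    m2t <- revcomp_cpp(tmpl)
  } else {
    m1t <- substr(tmpl, 1, pmin(readLen, fl))
    m2t <- substr(revcomp_cpp(tmpl), 1, pmin(readLen, fl))
  }
  rates <- pmin(profile@misRates * multM, 0.01)
  seq1 <- apply_errors_cpp(m1t, rates)
  seq2 <- apply_errors_cpp(m2t, rates)
  qc <- intToUtf8(round(profile@qualPhred) + 33)
  truth <- list(fragStart = start, fragLen = fl, read1Forward = r1fwd,
                molecule = mol, events = events, contig = gname,
                rateMultiplier = multM)
  readPairs(seq1, strrep(qc, nchar(seq1)), seq2, strrep(qc, nchar(seq2)),
            id = sprintf("%s_%06d", sampleId, seq_len(nPairs)),
            metadata = list(truth = truth, sample = sampleId))
}

# truth events for fragments drawn from a finite pool whose molecules
# carry known substitutions
.poolFragmentEvents <- function(pool, mol, start, fl) {
  ev <- pool@truth$events
  empty <- data.frame(read = integer(), pos = integer(),
                      ref = character(), alt = character())
  if (is.null(ev) || !nrow(ev)) return(empty)
  out <- list()
  for (i in seq_len(nrow(ev))) {
    hit <- which(mol == ev$molecule[i] & start <= ev$pos[i] &
                   start + fl > ev$pos[i])
    if (length(hit))
      out[[length(out) + 1]] <- data.frame(read = hit, pos = ev$pos[i],
                                           ref = ev$ref[i],
                                           alt = ev$alt[i])
  }
  if (length(out)) do.call(rbind, out) else empty
}

# plant per-site events into fragments drawn from an exposure model
.plantFragmentEvents <- function(model, frag, start) {
  rates <- .siteAltRates(model)
  rtot <- rowSums(rates)
  csum <- c(0, cumsum(rtot))
  fl <- nchar(frag)
  lam <- csum[start + fl + 1] - csum[start + 1]
  nev <- rpois(length(frag), lam)
  empty <- data.frame(read = integer(), pos = integer(),
                      ref = character(), alt = character())
  hit <- which(nev > 0)
  if (!length(hit)) return(list(frag = frag, events = empty))
  out <- list()
  for (i in hit) {
    rng <- (start[i] + 1):(start[i] + fl[i])
    w <- rtot[rng]
    k <- min(nev[i], sum(w > 0))
    if (k == 0) next
    sites <- rng[sample.int(length(rng), k, prob = w)]
    for (s in sites) {
      a <- sample.int(4, 1, prob = rates[s, ])
      refb <- substr(frag[i], s - start[i], s - start[i])
      if (refb == BASES[a]) next
      substr(frag[i], s - start[i], s - start[i]) <- BASES[a]
      out[[length(out) + 1]] <- data.frame(read = i, pos = s - 1L,
                                           ref = refb, alt = BASES[a])
    }
  }
  list(frag = frag,
       events = if (length(out)) do.call(rbind, out) else empty)
}
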