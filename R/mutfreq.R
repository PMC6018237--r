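# Substitution enumeration, per-million frequencies, background subtraction
# and the strand-bias artifact diagnostic.

# cache of per-genome position codes (ref base codes, triplet codes),
# keyed by the genome signature
.codeCache <- new.env(parent = emptyenv())

.genomeCodes <- function(genome) {
  sig <- .genomeSig(genome)
  hit <- .codeCache[[sig]]
  if (!is.null(hit)) return(hit)
  trip <- triplet_codes_cpp(genome@concat)
  ref <- match(strsplit(genome@concat, "")[[1]], BASES) - 1L
  val <- list(ref = ref, trip = trip)
  # keep the cache small: at most 4 genomes
  if (length(ls(.codeCache)) >= 4) rm(list = ls(.codeCache),
                                      envir = .codeCache)
  .codeCache[[sig]] <- val
  val
}

# map (refcode 0..3, altcode 0..3) -> index into SUB_TYPES (pyrimidine
# collapse); row = ref + 1, col = alt + 1
.TYPE_LUT <- local({
  m <- matrix(NA_integer_, 4, 4)
  for (r in 0:3) for (a in 0:3) {
    if (r == a) next
    ref <- BASES[r + 1]; alt <- BASES[a + 1]
    if (ref %in% c("G", "A")) {
      ref <- COMPLEMENT[[ref]]; alt <- COMPLEMENT[[alt]]
    }
    m[r + 1, a + 1] <- match(paste0(ref, ">", alt), SUB_TYPES)
  }
  m
})

.regionMask <- function(genome, region) {
  G <- nchar(genome@concat)
  if (is.null(region)) return(rep(TRUE, G))
  off <- genome@offsets[[region$contig]]
  if (is.null(off)) stop("unknown contig in region: ", region$contig)
  mask <- rep(FALSE, G)
  mask[(off + region$start + 1):(off + region$end)] <- TRUE
  mask
}

#' Enumerate substitutions and compute per-million frequencies
#'
#' Every non-reference call at a non-N reference position increments its
#' pyrimidine-collapsed substitution type; calls at positions with defined
#' trinucleotide context also increment their 96 class. Frequencies divide
#' each count by the total filtered base calls over the type's base-pair
#' class (G:C or A:T) and are reported per 1e6 such calls; 96-class
#' frequencies use the same class-wide denominator, so they partition the
#' type's frequency across contexts.
#'
#' @param counts a [BaseCountMatrix].
#' @param genome the [ReferenceGenome] the counts were built from (a
#'   mismatch is an error).
#' @param sample,group,dose sample metadata carried into the result.
#' @param region optional `list(contig=, start=, end=)` (0-based half-open)
#'   restricting counts and denominators to a sub-region, e.g. the random
#'   insert of a spike-in construct.
#' @param normalize96 denominator for the 96-class frequencies: "class"
#'   (default) divides by the type's whole base-pair-class total, so the
#'   96 classes partition each type's frequency; "context" divides each
#'   class by the filtered calls at that trinucleotide's own sites,
#'   giving per-context rates instead.
#' @return a [MutationFrequencyTable].
#' @export
countSubstitutions <- function(counts, genome, sample = "sample",
                               group = NA_character_, dose = NA_real_,
                               region = NULL,
                               normalize96 = c("class", "context")) {
  normalize96 <- match.arg(normalize96)
  if (counts@genomeSig != .genomeSig(genome))
    stop("count matrix was built from a different genome")
  codes <- .genomeCodes(genome)
  mask <- .regionMask(genome, region)
  m <- counts@counts
  counts6 <- setNames(numeric(6), SUB_TYPES)
  counts96 <- setNames(numeric(96), SUB96)
  denom <- c(GC = 0, AT = 0)
  ctxTot <- if (normalize96 == "context") numeric(64) else NULL
  for (r in 0:3) {
    idx <- which(!is.na(codes$ref) & codes$ref == r & mask)
    if (!length(idx)) next
    sub <- m[idx, , drop = FALSE]
    cls <- if (r == 1L || r == 2L) "GC" else "AT"
    denom[cls] <- denom[cls] + sum(sub)
    if (!is.null(ctxTot)) {
      tc <- codes$trip[idx]
      hc <- tc >= 0
      if (any(hc)) {
        add <- rowsum(rowSums(sub)[hc], tc[hc])
        ctxTot[as.integer(rownames(add)) + 1L] <-
          ctxTot[as.integer(rownames(add)) + 1L] + add[, 1]
      }
    }
    for (a in 0:3) {
      if (a == r) next
      v <- sub[, a + 1L] + sub[, a + 5L]
      nz <- which(v > 0)
      if (!length(nz)) next
      t6 <- .TYPE_LUT[r + 1, a + 1]
      counts6[t6] <- counts6[t6] + sum(v[nz])
      tc <- codes$trip[idx[nz]]
      hasCtx <- tc >= 0
      if (any(hasCtx)) {
        cl <- CLASS_LUT[tc[hasCtx] + 1L, a + 1L]
        add <- rowsum(v[nz][hasCtx], cl)
        counts96[as.integer(rownames(add))] <-
          counts96[as.integer(rownames(add))] + add[, 1]
      }
    }
  }
  if (is.null(region)) {
    # totals must match the matrix-level denominators
    stopifnot(denom["GC"] == counts@denomGC, denom["AT"] == counts@denomAT)
  }
  typeDenom <- denom[c(1, 1, 1, 2, 2, 2)]
  freq6 <- ifelse(typeDenom > 0, counts6 / typeDenom * 1e6, 0)
  if (normalize96 == "class") {
    classDenom <- denom[rep(c(1, 2), each = 48)]
  } else {
    # per-context denominators: filtered calls at each class's own
    # (both-strand) trinucleotide sites
    classDenom <- setNames(numeric(96), SUB96)
    for (t in 0:63) {
      for (a in 0:3) {
        ci <- CLASS_LUT[t + 1, a + 1]
        if (!is.na(ci)) classDenom[ci] <- classDenom[ci] + ctxTot[t + 1]
      }
    }
  }
  freq96 <- ifelse(classDenom > 0, counts96 / classDenom * 1e6, 0)
  methods::new("MutationFrequencyTable", sample = sample,
               group = as.character(group), dose = as.numeric(dose),
               counts6 = counts6, freq6 = setNames(freq6, SUB_TYPES),
               counts96 = counts96, freq96 = setNames(freq96, SUB96),
               denomGC = unname(denom["GC"]), denomAT = unname(denom["AT"]))
}

setMethod("show", "MutationFrequencyTable", function(object) {
  cat("MutationFrequencyTable for sample", object@sample, "\n")
  cat("  denominators: G:C", object@denomGC, " A:T", object@denomAT, "\n")
  print(round(object@freq6, 3))
})

#' Six-type frequencies per million class base calls
#' @param x a [MutationFrequencyTable] or [DeltaFrequencyTable].
#' @export
typeFrequencies <- function(x) {
  if (methods::is(x, "DeltaFrequencyTable")) x@delta6 else x@freq6
}

#' 96-class frequencies per million class base calls
#' @param x a [MutationFrequencyTable] or [DeltaFrequencyTable].
#' @export
contextFrequencies <- function(x) {
  if (methods::is(x, "DeltaFrequencyTable")) x@delta96 else x@freq96
}

#' Combine per-sample frequency tables into a data frame
#' @param tables list of [MutationFrequencyTable] objects.
#' @param what "six" or "context" (96-class).
#' @return data frame, one row per sample, one column per type/class plus
#'   metadata columns.
#' @export
frequencyTable <- function(tables, what = c("six", "context")) {
  what <- match.arg(what)
  rows <- lapply(tables, function(t) {
    v <- if (what == "six") t@freq6 else t@freq96
    cbind(data.frame(sample = t@sample, group = t@group, dose = t@dose,
                     denomGC = t@denomGC, denomAT = t@denomAT),
          as.data.frame(as.list(v), check.names = FALSE))
  })
  do.call(rbind, rows)
}

#' Subtract the mean control background
#'
#' The excess frequency of each type (and 96 class) is the exposed-sample
#' frequency minus the mean frequency over the control replicates.
#' Negative values are preserved.
#'
#' @param exposed a [MutationFrequencyTable].
#' @param controls non-empty list of control [MutationFrequencyTable]s.
#' @return a [DeltaFrequencyTable].
#' @export
subtractBackground <- function(exposed, controls) {
  if (methods::is(controls, "MutationFrequencyTable"))
    controls <- list(controls)
  if (!length(controls)) stop("at least one control sample is required")
  cm6 <- rowMeans(vapply(controls, function(x) x@freq6, numeric(6)))
  cm96 <- rowMeans(vapply(controls, function(x) x@freq96, numeric(96)))
  methods::new("DeltaFrequencyTable", sample = exposed@sample,
               delta6 = exposed@freq6 - cm6,
               delta96 = exposed@freq96 - cm96,
               controlMean6 = cm6, controlMean96 = cm96,
               nControls = length(controls))
}

setMethod("show", "DeltaFrequencyTable", function(object) {
  cat("DeltaFrequencyTable for sample", object@sample, "(",
      object@nControls, "controls )\n")
  print(round(object@delta6, 3))
})

#' Strand-bias diagnostic for library-preparation artifacts
#'
#' Oxidative guanine damage during library preparation produces G>T calls
#' only on the strand read by mate 1 where the damaged G lies, so a genuine
#' artifact shows as a large frequency imbalance between the two read-1
#' orientation classes of a substitution. For each pyrimidine type the
#' diagnostic reports the read-1-strand frequency of the pyrimidine form
#' (read 1 saw the C/T) and of the purine form (read 1 saw the G/A), their
#' ratio, and a flag when the ratio (either direction) exceeds `threshold`
#' and enough calls support it.
#'
#' @param counts a [BaseCountMatrix] with orientation-resolved counts.
#' @param genome matching [ReferenceGenome].
#' @param threshold ratio above which a type is flagged (default 3).
#' @param minCalls minimum combined call count for flagging (default 25);
#'   ratios from fewer calls are reported but not flagged, except that a
#'   zero denominator with a non-zero numerator is always flagged as
#'   infinite.
#' @param region optional region restriction as in [countSubstitutions()].
#' @return data frame with one row per substitution type: counts, per-1e6
#'   frequencies for both read-1 orientations, `ratio` (purine / pyrimidine
#'   form) and `flagged`. A matrix with no calls yields zero rows.
#' @export
strandBiasDiagnostic <- function(counts, genome, threshold = 3,
                                 minCalls = 25, region = NULL) {
  codes <- .genomeCodes(genome)
  mask <- .regionMask(genome, region)
  m <- counts@counts
  if (sum(m) == 0)
    return(data.frame(type = character(), countPyr = numeric(),
                      countPur = numeric(), freqPyr = numeric(),
                      freqPur = numeric(), ratio = numeric(),
                      flagged = logical()))
  # calls by (refbase, calledbase, orientation)
  cnt <- array(0, dim = c(4, 4, 2))
  for (r in 0:3) {
    idx <- which(!is.na(codes$ref) & codes$ref == r & mask)
    if (!length(idx)) next
    cs <- colSums(m[idx, , drop = FALSE])
    cnt[r + 1, , 1] <- cs[1:4]
    cnt[r + 1, , 2] <- cs[5:8]
  }
  # read1-strand substitution X>Y: fwd-orientation calls at ref X plus
  # rev-orientation calls at ref comp(X) (both seen as X>Y by read 1)
  comp <- c(4, 3, 2, 1)  # index of complement base
  r1count <- function(x, y)
    cnt[x, y, 1] + cnt[comp[x], comp[y], 2]
  r1denom <- function(x)
    sum(cnt[x, , 1]) + sum(cnt[comp[x], , 2])
  out <- do.call(rbind, lapply(SUB_TYPES, function(t) {
    p <- match(substr(t, 1, 1), BASES)  # pyrimidine ref
    q <- match(substr(t, 3, 3), BASES)
    cPyr <- r1count(p, q)
    cPur <- r1count(comp[p], comp[q])
    dPyr <- r1denom(p)
    dPur <- r1denom(comp[p])
    fPyr <- if (dPyr > 0) cPyr / dPyr * 1e6 else NA_real_
    fPur <- if (dPur > 0) cPur / dPur * 1e6 else NA_real_
    noCover <- (dPyr == 0 && cPur > 0) || (dPur == 0 && cPyr > 0)
    ratio <- if (noCover) Inf
    else if (is.na(fPyr) || is.na(fPur)) NA_real_
    else fPur / fPyr                    # may be Inf (0 pyr, >0 pur)
    flagged <- noCover ||
      (!is.na(ratio) && (cPyr + cPur) >= minCalls &&
         (ratio > threshold || ratio < 1 / threshold))
    data.frame(type = t, countPyr = cPyr, countPur = cPur, freqPyr = fPyr,
               freqPur = fPur, ratio = ratio, flagged = flagged)
  }))
  rownames(out) <- NULL
  out
}

#' Write six-type and 96-class frequency tables as TSV
#'
#' The 96-class table uses the conventional class ordering (type, then 5'
#' base, then 3' base).
#'
#' @param tables list of [MutationFrequencyTable] objects.
#' @param path6,path96 output paths (either may be NULL to skip).
#' @export
writeFrequencyTables <- function(tables, path6 = NULL, path96 = NULL) {
  if (!is.null(path6))
    write.table(frequencyTable(tables, "six"), path6, sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(path96))
    write.table(frequencyTable(tables, "context"), path96, sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
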