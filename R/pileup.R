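# Alignment ingest, duplicate removal and per-position base-call counting.
# Coordinates are 0-based half-open internally; SAM's 1-based coordinates
# are converted at the I/O boundary.

.alignedNew <- function(id, contig, start, read1Forward, seq, qual,
                        olStart, olEnd, cigar, mapq, metadata = list()) {
  methods::new("AlignedReads", id = id, contig = contig,
               start = as.integer(start), read1Forward = read1Forward,
               seq = seq, qual = qual, olStart = as.integer(olStart),
               olEnd = as.integer(olEnd), cigar = cigar,
               mapq = as.integer(mapq), metadata = metadata)
}

setMethod("length", "AlignedReads", function(x) length(x@id))

setMethod("show", "AlignedReads", function(object) {
  cat("AlignedReads with", length(object), "alignments on",
      length(unique(object@contig)), "contig(s)\n")
})

setMethod("[", "AlignedReads", function(x, i, j, ..., drop = TRUE) {
  .alignedNew(x@id[i], x@contig[i], x@start[i], x@read1Forward[i],
              x@seq[i], x@qual[i], x@olStart[i], x@olEnd[i], x@cigar[i],
              x@mapq[i], x@metadata)
})

#' Prebuild a k-mer seed index for [alignExact()]
#'
#' @param genome a [ReferenceGenome].
#' @param k seed length (<= 16).
#' @return an opaque index object reusable across [alignExact()] calls.
#' @export
genomeIndex <- function(genome, k = 16) {
  stopifnot(k >= 4, k <= 16)
  idx <- kmer_index_cpp(genome@concat, as.integer(k))
  idx$sig <- .genomeSig(genome)
  class(idx) <- "popmutscanIndex"
  idx
}

#' Gapless alignment of merged reads to a small reference
#'
#' A test-fixture aligner so the pipeline runs without an external mapper.
#' `method = "scan"` scans every placement on both strands exhaustively and
#' returns the placement with the fewest mismatches when that minimum is at
#' most `maxMismatches` and strictly better than any other placement
#' (ambiguous reads stay unaligned). `method = "index"` restricts the scan
#' to exact k-mer seed candidates, which is equivalent on non-repetitive
#' references and necessary for megabase genomes. N (masked) read bases are
#' ignored when counting mismatches.
#'
#' Minus-strand alignments are reverse-complemented into reference
#' orientation; the alignment strand records the read-1 orientation class
#' used by the strand-bias diagnostic.
#'
#' @param reads a [MergedReads] object.
#' @param genome a [ReferenceGenome].
#' @param maxMismatches maximum mismatches for an accepted placement.
#' @param method "auto" picks scan below 50 kb, index otherwise.
#' @param index optional prebuilt [genomeIndex()] result.
#' @return an [AlignedReads] object (unaligned reads dropped;
#'   `metadata(x)$nUnaligned` records how many).
#' @export
alignExact <- function(reads, genome, maxMismatches = 7,
                       method = c("auto", "scan", "index"), index = NULL) {
  method <- match.arg(method)
  G <- nchar(genome@concat)
  if (method == "auto")
    method <- if (G <= 2e4 && length(reads) * G <= 2e8) "scan" else "index"
  if (method == "scan") {
    res <- align_scan_cpp(reads@seq, genome@concat,
                          as.integer(maxMismatches))
  } else {
    if (is.null(index)) index <- genomeIndex(genome)
    if (index$sig != .genomeSig(genome))
      stop("index was built for a different genome")
    res <- align_index_cpp(reads@seq, genome@concat, index$keys, index$pos,
                           index$k, as.integer(maxMismatches), 12L)
  }
  keep <- which(!is.na(res$start))
  start <- res$start[keep]
  strand <- res$strand[keep]
  # map concatenated coordinates back to contigs
  offs <- genome@offsets
  ci <- findInterval(start, offs)
  contig <- names(offs)[ci]
  lstart <- start - unname(offs[ci])
  seq <- reads@seq[keep]
  qual <- reads@qual[keep]
  olS <- reads@olStart[keep]
  olE <- reads@olEnd[keep]
  L <- nchar(seq)
  rev <- strand == 1L
  if (any(rev)) {
    seq[rev] <- revcomp_cpp(seq[rev])
    qual[rev] <- vapply(strsplit(qual[rev], ""), function(q)
      paste(rev(q), collapse = ""), character(1))
    ns <- L[rev] - olE[rev]
    ne <- L[rev] - olS[rev]
    olS[rev] <- ns
    olE[rev] <- ne
  }
  md <- reads@metadata
  md$nUnaligned <- length(reads) - length(keep)
  .alignedNew(reads@id[keep], contig, lstart, !rev, seq, qual, olS, olE,
              rep("", length(keep)), rep(60L, length(keep)), md)
}

.refSpan <- function(cigar, seqlen) {
  span <- integer(length(cigar))
  plain <- !nzchar(cigar)
  span[plain] <- seqlen[plain]
  for (i in which(!plain)) {
    ops <- gregexpr("[0-9]+[MIDNSHP=X]", cigar[i])[[1]]
    toks <- regmatches(cigar[i], gregexpr("[0-9]+[MIDNSHP=X]", cigar[i]))[[1]]
    len <- as.integer(sub("[A-Z=]$", "", toks))
    op <- sub("^[0-9]+", "", toks)
    span[i] <- sum(len[op %in% c("M", "D", "N", "=", "X")])
  }
  span
}

#' Remove coordinate duplicates
#'
#' Among alignments sharing (contig, start, end, orientation) exactly one
#' read is kept: the one with the highest mean base quality, ties going to
#' the first encountered. Mirrors PCR-duplicate marking for single-end
#' merged reads.
#'
#' @param aln an [AlignedReads] object.
#' @return the deduplicated [AlignedReads]; `metadata(x)$nDuplicates`
#'   records the number removed.
#' @export
removeDuplicates <- function(aln) {
  if (length(aln) == 0) return(aln)
  span <- .refSpan(aln@cigar, nchar(aln@seq))
  # numeric key: (contig, start, span, orientation) fits a double exactly
  key <- (match(aln@contig, unique(aln@contig)) - 1) * 2^44 +
    aln@start * 2^13 + span * 2 + as.numeric(aln@read1Forward)
  mq <- mean_qual_cpp(aln@qual)
  ord <- order(key, -mq)            # stable: ties keep input order
  keep <- sort(ord[!duplicated(key[ord])])
  out <- aln[keep]
  out@metadata$nDuplicates <- length(aln) - length(keep)
  out
}

#' Build the per-position filtered base-call count matrix
#'
#' Counts every base call that lies inside its read's overlap span, is not
#' masked (N) and has quality at least `qMin`, at a non-N reference
#' position, split by read-1 orientation. Totals over G:C and A:T reference
#' sites become the frequency denominators.
#'
#' @param aln an [AlignedReads] object.
#' @param genome the [ReferenceGenome] the reads were aligned to.
#' @param qMin Phred threshold (default 30).
#' @param overlapOnly if FALSE, single-mate bases outside the overlap span
#'   are counted too (default TRUE, overlap-only).
#' @return a [BaseCountMatrix].
#' @export
buildBaseCounts <- function(aln, genome, qMin = 30, overlapOnly = TRUE) {
  stopifnot(qMin >= 0)
  G <- nchar(genome@concat)
  counts <- integer(G * 8L)
  if (length(aln)) {
    miss <- setdiff(unique(aln@contig), names(genome@offsets))
    if (length(miss))
      stop("contig absent from reference: ", paste(miss, collapse = ", "))
    gstart <- aln@start + unname(genome@offsets[aln@contig])
    olS <- aln@olStart
    olE <- aln@olEnd
    if (!overlapOnly) {
      olS <- rep(0L, length(aln))
      olE <- nchar(aln@seq)
    }
    pileup_cpp(counts, G, as.integer(gstart),
               as.integer(!aln@read1Forward), aln@seq, aln@qual,
               as.integer(olS), as.integer(olE), aln@cigar,
               as.integer(qMin))
  }
  dim(counts) <- c(G, 8L)
  colnames(counts) <- paste0(rep(BASES, 2), rep(c("_fwd", "_rev"),
                                                each = 4))
  refcode <- .genomeCodes(genome)$ref
  tot <- rowSums(counts)
  methods::new("BaseCountMatrix", counts = counts,
               offsets = genome@offsets, qMin = qMin,
               overlapOnly = overlapOnly,
               denomGC = sum(tot[!is.na(refcode) & (refcode == 1L |
                                                      refcode == 2L)]),
               denomAT = sum(tot[!is.na(refcode) & (refcode == 0L |
                                                      refcode == 3L)]),
               genomeSig = .genomeSig(genome))
}

setMethod("show", "BaseCountMatrix", function(object) {
  cat("BaseCountMatrix over", nrow(object@counts),
      "positions (qMin =", object@qMin, ")\n")
  cat("  filtered calls at G:C sites:", object@denomGC,
      " at A:T sites:", object@denomAT, "\n")
})

#' Total filtered base calls per denominator class
#' @param counts a [BaseCountMatrix].
#' @return named numeric vector with elements `GC` and `AT`.
#' @export
baseCallTotals <- function(counts)
  c(GC = counts@denomGC, AT = counts@denomAT)

#' Write alignments as SAM
#'
#' Minus-orientation reads are already stored reference-oriented, so SEQ
#' and QUAL are written as stored with FLAG 16. The overlap span is carried
#' in the `ZO:Z:<start>,<end>` auxiliary tag (reference-oriented query
#' coordinates) and the masked-base count in `ZM:i:`.
#'
#' @param aln an [AlignedReads] object.
#' @param genome the matching [ReferenceGenome].
#' @param path output path.
#' @export
writeSam <- function(aln, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- Biostrings::width(genome@sequences)
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               paste0("@SQ\tSN:", names(genome@sequences), "\tLN:", w)),
             con)
  if (length(aln)) {
    cig <- ifelse(nzchar(aln@cigar), aln@cigar,
                  paste0(nchar(aln@seq), "M"))
    flag <- ifelse(aln@read1Forward, 0L, 16L)
    writeLines(paste(aln@id, flag, aln@contig, aln@start + 1L, aln@mapq,
                     cig, "*", 0L, 0L, aln@seq, aln@qual,
                     paste0("ZO:Z:", aln@olStart, ",", aln@olEnd),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read single-end alignments from SAM
#'
#' Unmapped (flag 4), secondary (256) and supplementary (2048) records are
#' skipped; soft-clipped bases are excluded from counting via the CIGAR.
#' The `ZO` overlap tag written by [writeSam()] is honoured; records
#' without it are treated as fully overlapping.
#'
#' @param path SAM path.
#' @param genome the [ReferenceGenome] the file was mapped against; records
#'   on contigs absent from it are an error.
#' @param mapqMin minimum mapping quality (default 0, no filter).
#' @return an [AlignedReads] object.
#' @export
readSam <- function(path, genome, mapqMin = 0) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(.alignedNew(character(), character(), integer(), logical(),
                       character(), character(), integer(), integer(),
                       character(), integer()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 11)) stop("malformed SAM record (fewer than 11 fields)")
  flag <- as.integer(vapply(f, `[[`, "", 2))
  skip <- bitwAnd(flag, 4L) > 0 | bitwAnd(flag, 256L) > 0 |
    bitwAnd(flag, 2048L) > 0
  f <- f[!skip]; flag <- flag[!skip]
  contig <- vapply(f, `[[`, "", 3)
  miss <- setdiff(unique(contig), names(genome@offsets))
  if (length(miss))
    stop("contig absent from reference: ", paste(miss, collapse = ", "))
  mapq <- as.integer(vapply(f, `[[`, "", 5))
  ok <- mapq >= mapqMin
  f <- f[ok]; flag <- flag[ok]; contig <- contig[ok]; mapq <- mapq[ok]
  seq <- toupper(vapply(f, `[[`, "", 10))
  qual <- vapply(f, `[[`, "", 11)
  zo <- vapply(f, function(x) {
    tag <- grep("^ZO:Z:", x[-(1:11)], value = TRUE)
    if (length(tag)) sub("^ZO:Z:", "", tag[1]) else NA_character_
  }, "")
  olS <- rep(0L, length(f))
  olE <- nchar(seq)
  has <- !is.na(zo)
  if (any(has)) {
    parts <- do.call(rbind, strsplit(zo[has], ",", fixed = TRUE))
    olS[has] <- as.integer(parts[, 1])
    olE[has] <- as.integer(parts[, 2])
  }
  .alignedNew(vapply(f, `[[`, "", 1), contig,
              as.integer(vapply(f, `[[`, "", 4)) - 1L,
              bitwAnd(flag, 16L) == 0L, seq, qual, olS, olE,
              vapply(f, function(x) {
                cg <- x[[6]]
                if (cg == "*") "" else cg
              }, ""), mapq)
}
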