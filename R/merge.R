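# Read-pair merging: overlap detection and mate-consistency consensus.
# Only information consistent between the two mates of a pair is trusted;
# disagreements are masked, never resolved by quality. This is the
# error-mitigation stage of the workflow: an independent miscall pair only
# survives the consensus when both mates miscall the same base to the same
# alternative, so a symmetric per-base error rate e leaves residual errors
# at rate e^2/3.

#' Construct a ReadPairs object
#'
#' @param seq1,seq2 mate sequences (mate 2 as sequenced).
#' @param qual1,qual2 Phred+33 quality strings; a single Phred value is
#'   expanded to flat qualities.
#' @param id read identifiers (generated if missing).
#' @param metadata free-form list.
#' @return a [ReadPairs] object.
#' @export
readPairs <- function(seq1, qual1, seq2, qual2, id = NULL,
                      metadata = list()) {
  n <- length(seq1)
  if (is.null(id)) id <- paste0("read", seq_len(n))
  if (is.numeric(qual1)) qual1 <- strrep(intToUtf8(qual1 + 33), nchar(seq1))
  if (is.numeric(qual2)) qual2 <- strrep(intToUtf8(qual2 + 33), nchar(seq2))
  methods::new("ReadPairs", id = id, seq1 = toupper(seq1), qual1 = qual1,
               seq2 = toupper(seq2), qual2 = qual2, metadata = metadata)
}

setMethod("length", "ReadPairs", function(x) length(x@id))

setMethod("show", "ReadPairs", function(object) {
  cat("ReadPairs with", length(object), "pairs\n")
  if (length(object))
    cat("  mate lengths:", nchar(object@seq1[1]), "/",
        nchar(object@seq2[1]), "(first pair)\n")
})

setMethod("[", "ReadPairs", function(x, i, j, ..., drop = TRUE) {
  methods::new("ReadPairs", id = x@id[i], seq1 = x@seq1[i],
               qual1 = x@qual1[i], seq2 = x@seq2[i], qual2 = x@qual2[i],
               metadata = x@metadata)
})

#' Find the best overlap offset of a read pair
#'
#' Reverse-complements mate 2 and scans every non-negative offset (mate 1
#' starting at or before reverse-complemented mate 2, the proper fragment
#' orientation) with overlap at least `minOverlap`, scoring each by
#' matches minus mismatches over the overlap.
#' The maximal-scoring offset is returned if its mismatch fraction is at
#' most `maxMismatchFrac`; ties are broken toward the longest overlap, then
#' the smallest offset.
#'
#' @param pair a [ReadPairs] object (all pairs are scanned).
#' @param minOverlap minimum overlap length (default 10).
#' @param maxMismatchFrac maximum tolerated mismatch fraction within the
#'   overlap (default 0.1; must be < 0.5).
#' @return integer vector of offsets (position of reverse-complemented
#'   mate 2 relative to mate 1), NA where no acceptable overlap exists.
#' @export
findPairOverlap <- function(pair, minOverlap = 10, maxMismatchFrac = 0.1) {
  stopifnot(minOverlap >= 1, maxMismatchFrac >= 0, maxMismatchFrac < 0.5)
  res <- merge_pairs_cpp(pair@seq1, pair@qual1, pair@seq2, pair@qual2,
                         as.integer(minOverlap), maxMismatchFrac)
  res$offset
}

#' Merge read pairs into mate-consistent consensus reads
#'
#' For each pair the best overlap offset is located (see
#' [findPairOverlap()]) and a consensus is built: within the overlap,
#' agreeing bases are kept with the larger of the two qualities and
#' disagreeing bases are masked to N with quality 0; bases covered by only
#' one mate are retained but flagged as outside the overlap span. Pairs with
#' no acceptable overlap are dropped.
#'
#' @inheritParams findPairOverlap
#' @return a [MergedReads] object; `metadata(x)$nInput` and `$nMerged`
#'   record how many pairs went in and merged. Simulation truth carried on
#'   the input pairs is subset to the merged reads.
#' @export
mergePairs <- function(pair, minOverlap = 10, maxMismatchFrac = 0.1) {
  stopifnot(minOverlap >= 1, maxMismatchFrac >= 0, maxMismatchFrac < 0.5)
  res <- merge_pairs_cpp(pair@seq1, pair@qual1, pair@seq2, pair@qual2,
                         as.integer(minOverlap), maxMismatchFrac)
  keep <- which(res$merged)
  md <- pair@metadata
  md$nInput <- length(pair)
  md$nMerged <- length(keep)
  if (!is.null(md$truth))
    md$truth <- .subsetTruth(md$truth, keep, length(pair))
  methods::new("MergedReads", id = pair@id[keep],
               seq = as.character(res$seq[keep]),
               qual = as.character(res$qual[keep]),
               olStart = res$ol_start[keep], olEnd = res$ol_end[keep],
               nMasked = res$n_masked[keep], metadata = md)
}

setMethod("length", "MergedReads", function(x) length(x@id))

setMethod("show", "MergedReads", function(object) {
  cat("MergedReads with", length(object), "consensus reads\n")
  if (length(object))
    cat("  masked positions: total", sum(object@nMasked), "\n")
})

setMethod("[", "MergedReads", function(x, i, j, ..., drop = TRUE) {
  if (is.logical(i)) i <- which(i)
  md <- x@metadata
  if (!is.null(md$truth))
    md$truth <- .subsetTruth(md$truth, i, length(x))
  methods::new("MergedReads", id = x@id[i], seq = x@seq[i], qual = x@qual[i],
               olStart = x@olStart[i], olEnd = x@olEnd[i],
               nMasked = x@nMasked[i], metadata = md)
})

# subset per-read truth bookkeeping: any vector element of read length is
# subset; the event table is re-indexed
.subsetTruth <- function(truth, idx, n) {
  for (nm in names(truth)) {
    el <- truth[[nm]]
    if (is.atomic(el) && length(el) == n && nm != "events")
      truth[[nm]] <- el[idx]
  }
  if (!is.null(truth$events) && nrow(truth$events)) {
    ev <- truth$events[truth$events$read %in% idx, , drop = FALSE]
    ev$read <- match(ev$read, idx)
    truth$events <- ev
  }
  truth
}

#' Number of masked positions per merged read
#' @param x a [MergedReads] object.
#' @export
nMasked <- function(x) x@nMasked

#' Overlap spans of merged reads
#' @param x a [MergedReads] object.
#' @return data frame with 0-based half-open `start`, `end` columns.
#' @export
overlapSpan <- function(x) data.frame(start = x@olStart, end = x@olEnd)

#' Read paired FASTQ files
#'
#' @param path1,path2 mate-1 and mate-2 FASTQ paths (4-line records,
#'   Phred+33).
#' @return a [ReadPairs] object.
#' @export
readFastqPairs <- function(path1, path2) {
  r1 <- Biostrings::readDNAStringSet(path1, format = "fastq",
                                     with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(path2, format = "fastq",
                                     with.qualities = TRUE)
  if (length(r1) != length(r2)) stop("mate files differ in read count")
  readPairs(unname(as.character(r1)),
            unname(as.character(S4Vectors::mcols(r1)$qualities)),
            unname(as.character(r2)),
            unname(as.character(S4Vectors::mcols(r2)$qualities)),
            id = unname(sub("[/ ].*$", "", names(r1))))
}

#' Write paired FASTQ files
#' @param pair a [ReadPairs] object.
#' @param path1,path2 output FASTQ paths.
#' @export
writeFastqPairs <- function(pair, path1, path2) {
  .writeFastq(pair@id, pair@seq1, pair@qual1, path1)
  .writeFastq(pair@id, pair@seq2, pair@qual2, path2)
  invisible(c(path1, path2))
}

.writeFastq <- function(id, seq, qual, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", id, "\n", seq, "\n+\n", qual), con)
  invisible(path)
}

#' Write merged reads as single-end FASTQ
#'
#' The overlap span and masked-base count are carried in the read
#' description (`ol=<start>:<end> masked=<n>`, 0-based half-open) so the
#' merged output is round-trippable.
#'
#' @param x a [MergedReads] object.
#' @param path output FASTQ path.
#' @export
writeMergedFastq <- function(x, path) {
  hdr <- paste0(x@id, " ol=", x@olStart, ":", x@olEnd,
                " masked=", x@nMasked)
  .writeFastq(hdr, x@seq, x@qual, path)
}

#' Read merged reads written by [writeMergedFastq()]
#' @param path FASTQ path.
#' @return a [MergedReads] object.
#' @export
readMergedFastq <- function(path) {
  r <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  nm <- names(r)
  ol <- regmatches(nm, regexpr("ol=[0-9]+:[0-9]+", nm))
  if (length(ol) != length(nm)) stop("missing overlap annotation")
  parts <- do.call(rbind, strsplit(sub("^ol=", "", ol), ":", fixed = TRUE))
  msk <- as.integer(sub(".*masked=([0-9]+).*", "\\1", nm))
  methods::new("MergedReads", id = unname(sub("\\s.*$", "", nm)),
               seq = unname(as.character(r)),
               qual = unname(as.character(S4Vectors::mcols(r)$qualities)),
               olStart = as.integer(parts[, 1]),
               olEnd = as.integer(parts[, 2]), nMasked = msk,
               metadata = list())
}
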