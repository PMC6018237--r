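# Reference handling, strand-collapsed substitution classification and
# trinucleotide context assignment.

#' The six pyrimidine-represented substitution types
#'
#' Purine-reference substitutions are reported as their reverse complement,
#' so C>A stands for the G:C>T:A base-pair change etc.
#' @return character vector of the six type labels.
#' @export
subTypes <- function() SUB_TYPES

#' The 96 trinucleotide class labels in conventional order
#'
#' Classes are ordered by substitution type (C>A, C>G, C>T, T>A, T>C, T>G),
#' then 5' base, then 3' base, each A,C,G,T — the layout used by the human
#' cancer signature catalogues.
#' @return character vector of 96 labels like `"A[C>T]G"`.
#' @export
sub96Labels <- function() {
  unlist(lapply(SUB_TYPES, function(t)
    as.vector(t(outer(BASES, BASES, function(l, r)
      paste0(l, "[", t, "]", r))))), use.names = FALSE)
}

SUB96 <- NULL       # assigned at load via .onLoad
CLASS_LUT <- NULL   # (triplet code, alt) -> class index lookup

.onLoad <- function(libname, pkgname) {
  # class lookup by (triplet code 0..63, alt base 1..4); NA where alt == ref
  lab <- sub96Labels()
  lut <- matrix(NA_integer_, nrow = 64, ncol = 4)
  for (l in 0:3) for (c in 0:3) for (r in 0:3) {
    for (a in 0:3) {
      if (a == c) next
      cls <- .classify1(BASES[c + 1], BASES[a + 1], BASES[l + 1],
                        BASES[r + 1])
      lut[l * 16 + c * 4 + r + 1, a + 1] <- match(cls, lab)
    }
  }
  assign("SUB96", lab, envir = parent.env(environment()))
  assign("CLASS_LUT", lut, envir = parent.env(environment()))
}

#' Reverse complement of plain character sequences
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements (N maps to N).
#' @export
revComp <- function(x) revcomp_cpp(x)

.referenceNew <- function(dss) {
  af <- Biostrings::alphabetFrequency(dss, collapse = TRUE)
  sep <- strrep("N", 50L)
  chr <- as.character(dss)
  concat <- paste(chr, collapse = sep)
  w <- Biostrings::width(dss)
  offs <- cumsum(c(0, head(w + 50L, -1)))
  names(offs) <- names(dss)
  methods::new("ReferenceGenome", sequences = dss,
               nGC = unname(af["C"] + af["G"]),
               nAT = unname(af["A"] + af["T"]),
               nN = unname(af["N"]), concat = concat, offsets = offs)
}

#' Load a reference genome from FASTA
#'
#' Reads a (possibly multi-contig, wrapped, mixed-case) FASTA file,
#' uppercases it and computes the G:C / A:T site counts used as frequency
#' denominators. Ambiguity codes other than N are rejected.
#'
#' @param path path to a FASTA file.
#' @return a [ReferenceGenome].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGT"), fa)
#' g <- loadReference(fa)
#' nGCSites(g)  # 2
#' @export
loadReference <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  dss <- Biostrings::readDNAStringSet(path)
  if (length(dss) == 0) stop("no sequences in FASTA file: ", path)
  dss <- Biostrings::DNAStringSet(toupper(as.character(dss)))
  # keep only the first word of each FASTA header, as aligners do
  names(dss) <- sub("\\s.*$", "", names(dss))
  g <- .referenceNew(dss)
  validObject(g)
  g
}

#' Build a reference genome from in-memory sequences
#'
#' @param seqs named character vector of contig sequences.
#' @return a [ReferenceGenome].
#' @export
referenceFromSeq <- function(seqs) {
  if (is.null(names(seqs))) names(seqs) <- paste0("contig", seq_along(seqs))
  g <- .referenceNew(Biostrings::DNAStringSet(toupper(seqs)))
  validObject(g)
  g
}

#' @describeIn loadReference number of G or C reference positions.
#' @param genome a [ReferenceGenome].
#' @export
nGCSites <- function(genome) genome@nGC

#' @describeIn loadReference number of A or T reference positions.
#' @export
nATSites <- function(genome) genome@nAT

#' @describeIn loadReference contig sequences as a DNAStringSet.
#' @export
referenceSequences <- function(genome) genome@sequences

.genomeSig <- function(genome) {
  # cheap position-weighted checksum so same-composition genomes with
  # different content still get distinct signatures
  x <- utf8ToInt(genome@concat)
  h <- sum(x * (seq_along(x) %% 8191)) %% 2147483647
  paste(paste(names(genome@sequences), collapse = ","),
        sum(Biostrings::width(genome@sequences)), genome@nGC, genome@nAT,
        h, sep = "|")
}

setMethod("show", "ReferenceGenome", function(object) {
  w <- Biostrings::width(object@sequences)
  cat("ReferenceGenome with", length(w), "contig(s),", sum(w), "bp\n")
  cat("  G:C sites:", object@nGC, " A:T sites:", object@nAT,
      " N:", object@nN, "\n")
})

setMethod("length", "ReferenceGenome", function(x)
  sum(Biostrings::width(x@sequences)))

.classify1 <- function(ref, alt, left, right) {
  if (ref %in% c("G", "A")) {
    tmp <- COMPLEMENT[[left]]
    left <- COMPLEMENT[[right]]
    right <- tmp
    ref <- COMPLEMENT[[ref]]
    alt <- COMPLEMENT[[alt]]
  }
  paste0(left, "[", ref, ">", alt, "]", right)
}

#' Classify a substitution into its pyrimidine-represented 96 class
#'
#' Purine reference bases are reverse-complemented together with their
#' flanking bases, so every substitution maps to one of the 96 classes with
#' a C or T reference. The mapping is an exact 2-to-1 surjection from the
#' 192 strand-resolved cases onto the 96 classes.
#'
#' @param ref,alt reference and alternative base (vectors recycle).
#' @param left,right the 5' and 3' neighbouring reference bases.
#' @return data frame with columns `pairGroup` ("GC" or "AT"), `subType`,
#'   `context5`, `context3` and `label`.
#' @examples
#' classifySubstitution("G", "A", "A", "T")$label  # "A[C>T]T"
#' @export
classifySubstitution <- function(ref, alt, left, right) {
  n <- max(length(ref), length(alt), length(left), length(right))
  ref <- rep_len(toupper(ref), n); alt <- rep_len(toupper(alt), n)
  left <- rep_len(toupper(left), n); right <- rep_len(toupper(right), n)
  ok <- c(ref, alt, left, right) %in% BASES
  if (!all(ok)) stop("all bases must be one of A, C, G, T")
  if (any(ref == alt)) stop("ref and alt must differ")
  flip <- ref %in% c("G", "A")
  l2 <- ifelse(flip, unname(COMPLEMENT[right]), left)
  r2 <- ifelse(flip, unname(COMPLEMENT[left]), right)
  ref2 <- ifelse(flip, unname(COMPLEMENT[ref]), ref)
  alt2 <- ifelse(flip, unname(COMPLEMENT[alt]), alt)
  data.frame(pairGroup = ifelse(ref2 == "C", "GC", "AT"),
             subType = paste0(ref2, ">", alt2), context5 = l2,
             context3 = r2,
             label = paste0(l2, "[", ref2, ">", alt2, "]", r2))
}

#' Trinucleotide context at reference positions
#'
#' Returns the 5' base, reference base and 3' base at each position. At
#' contig ends or next to an N the context is undefined (`hasContext` is
#' FALSE); such sites still contribute to six-type tallies but are excluded
#' from 96-class tallies.
#'
#' @param genome a [ReferenceGenome].
#' @param contig contig name.
#' @param pos 0-based position(s).
#' @return data frame with columns `left`, `ref`, `right`, `hasContext`;
#'   `left`/`right` are NA where no context exists.
#' @export
contextAt <- function(genome, contig, pos) {
  seqs <- genome@sequences
  i <- match(contig, names(seqs))
  if (is.na(i)) stop("unknown contig: ", contig)
  L <- Biostrings::width(seqs)[i]
  if (any(pos < 0 | pos >= L)) stop("position outside contig")
  s <- as.character(seqs[[i]])
  ref <- substring(s, pos + 1, pos + 1)
  left <- ifelse(pos >= 1, substring(s, pos, pos), NA_character_)
  right <- ifelse(pos + 2 <= L, substring(s, pos + 2, pos + 2),
                  NA_character_)
  has <- !is.na(left) & !is.na(right) & left %in% BASES &
    right %in% BASES & ref %in% BASES
  left[!has] <- NA_character_
  right[!has] <- NA_character_
  data.frame(left = left, ref = ref, right = right, hasContext = has)
}
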