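# Shared fixture builders; everything is generated in code.

rcChr <- function(x) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(x)))

# a small fixed-seed reference genome
tinyGenome <- function(n = 3000, seed = 11) {
  set.seed(seed)
  referenceFromSeq(c(chr = randomDna(n)))
}

# perfect read pairs from known fragment positions of a genome
perfectPairs <- function(genome, starts, len = 60, qual = 37) {
  gseq <- as.character(referenceSequences(genome)[[1]])
  frag <- substring(gseq, starts + 1, starts + len)
  readPairs(frag, qual, revComp(frag), qual)
}

# write a SAM file from a record list (each a character vector of fields)
writeSamLines <- function(records, contigs, path) {
  hdr <- c("@HD\tVN:1.6",
           paste0("@SQ\tSN:", names(contigs), "\tLN:", contigs))
  writeLines(c(hdr, vapply(records, paste, "", collapse = "\t")), path)
  path
}

# a synthetic signature catalogue matrix (seeded, Dirichlet-ish)
syntheticCatalogue <- function(nSig = 21, seed = 5) {
  set.seed(seed)
  m <- matrix(rexp(96 * nSig), 96, nSig,
              dimnames = list(sub96Labels(), paste0("Signature.", 1:nSig)))
  sweep(m, 2, colSums(m), "/")
}
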