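#' Reference genome with base-composition summaries
#'
#' Holds the reference contigs as a [Biostrings::DNAStringSet] together with
#' counts of G/C, A/T and N positions. Substitution frequencies are expressed
#' per million base calls mapped to G:C or A:T reference sites, so these
#' composition counts define the two denominator classes.
#'
#' @slot sequences [Biostrings::DNAStringSet] of uppercase contig sequences
#'   (alphabet A, C, G, T, N).
#' @slot nGC,nAT,nN numeric totals of G/C, A/T and N reference positions.
#' @slot concat single concatenated sequence used by the compiled kernels;
#'   contigs are joined by runs of N so no alignment or context can span a
#'   contig boundary.
#' @slot offsets named numeric vector of 0-based contig start offsets within
#'   the concatenated sequence.
#' @exportClass ReferenceGenome
setClass("ReferenceGenome",
  representation(sequences = "ANY", nGC = "numeric", nAT = "numeric",
                 nN = "numeric", concat = "character", offsets = "numeric"))

setValidity("ReferenceGenome", function(object) {
  msgs <- character()
  if (!methods::is(object@sequences, "DNAStringSet"))
    msgs <- c(msgs, "sequences must be a DNAStringSet")
  nm <- names(object@sequences)
  if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))
    msgs <- c(msgs, "contig names must be present and unique")
  af <- Biostrings::alphabetFrequency(object@sequences, collapse = TRUE)
  extra <- sum(af) - sum(af[c("A", "C", "G", "T", "N")])
  if (extra > 0)
    msgs <- c(msgs, "sequences may contain only A, C, G, T, N")
  tot <- sum(Biostrings::width(object@sequences))
  if (object@nGC + object@nAT + object@nN != tot)
    msgs <- c(msgs, "composition counts do not sum to total length")
  if (length(msgs)) msgs else TRUE
})

#' Paired-end reads
#'
#' Raw mate sequences and Phred+33 quality strings, mate 2 as sequenced
#' (reverse strand of the fragment).
#'
#' @slot id read identifiers.
#' @slot seq1,qual1,seq2,qual2 per-mate sequence and quality strings.
#' @slot metadata free-form list (e.g. simulation truth records).
#' @exportClass ReadPairs
setClass("ReadPairs",
  representation(id = "character", seq1 = "character", qual1 = "character",
                 seq2 = "character", qual2 = "character",
                 metadata = "list"))

setValidity("ReadPairs", function(object) {
  n <- length(object@id)
  lens <- vapply(list(object@seq1, object@qual1, object@seq2, object@qual2),
                 length, integer(1))
  if (any(lens != n)) return("slot lengths differ")
  if (any(nchar(object@seq1) != nchar(object@qual1)) ||
      any(nchar(object@seq2) != nchar(object@qual2)))
    return("sequence and quality lengths differ within a mate")
  TRUE
})

#' Merged consensus reads
#'
#' One consensus sequence per merged pair, in mate-1 orientation. Within the
#' overlap, mate-disagreeing positions are masked to N with quality 0; bases
#' covered by a single mate are retained but lie outside the overlap span and
#' are excluded downstream when overlap-only counting is on (the default).
#'
#' @slot id read identifiers.
#' @slot seq,qual consensus sequence (possibly containing N) and Phred+33
#'   qualities.
#' @slot olStart,olEnd 0-based half-open overlap span in merged coordinates.
#' @slot nMasked number of masked (disagreeing or undetermined) positions.
#' @slot metadata free-form list; `mergePairs()` records input/merged counts.
#' @exportClass MergedReads
setClass("MergedReads",
  representation(id = "character", seq = "character", qual = "character",
                 olStart = "integer", olEnd = "integer", nMasked = "integer",
                 metadata = "list"))

setValidity("MergedReads", function(object) {
  n <- length(object@id)
  if (length(object@seq) != n || length(object@qual) != n ||
      length(object@olStart) != n || length(object@olEnd) != n ||
      length(object@nMasked) != n) return("slot lengths differ")
  if (any(nchar(object@seq) != nchar(object@qual)))
    return("sequence and quality lengths differ")
  if (any(object@olStart < 0 | object@olEnd > nchar(object@seq) |
          object@olStart > object@olEnd))
    return("overlap span outside merged read")
  TRUE
})

#' Aligned reads (reference-oriented)
#'
#' Gapless or CIGAR alignments of merged reads. Sequences, qualities and
#' overlap spans are stored in reference orientation; `read1Forward` records
#' whether mate 1 of the original pair read the reference forward strand,
#' which is the orientation axis of the strand-bias diagnostic.
#'
#' @slot id read identifiers.
#' @slot contig contig name per read.
#' @slot start 0-based alignment start on the contig.
#' @slot read1Forward logical, read-1 orientation class.
#' @slot seq,qual reference-oriented sequence/quality.
#' @slot olStart,olEnd reference-oriented overlap span (query coordinates).
#' @slot cigar SAM CIGAR string; "" means gapless full-length match.
#' @slot mapq mapping quality.
#' @slot metadata free-form list.
#' @exportClass AlignedReads
setClass("AlignedReads",
  representation(id = "character", contig = "character", start = "integer",
                 read1Forward = "logical", seq = "character",
                 qual = "character", olStart = "integer", olEnd = "integer",
                 cigar = "character", mapq = "integer", metadata = "list"))

#' Per-position filtered base-call counts
#'
#' Counts of A/C/G/T calls passing the overlap, mask and quality filters at
#' every reference position, split by read-1 orientation, plus the total
#' filtered call counts over G:C and over A:T reference sites (the frequency
#' denominators).
#'
#' @slot counts integer matrix, one row per concatenated reference position,
#'   8 columns: A,C,G,T calls from read1-forward alignments then A,C,G,T from
#'   read1-reverse alignments.
#' @slot offsets contig offsets matching the genome used to build the counts.
#' @slot qMin quality threshold applied.
#' @slot overlapOnly whether only overlap-span bases were counted.
#' @slot denomGC,denomAT total filtered calls at G:C / A:T reference sites.
#' @slot genomeSig signature of the genome the counts were built from.
#' @exportClass BaseCountMatrix
setClass("BaseCountMatrix",
  representation(counts = "matrix", offsets = "numeric", qMin = "numeric",
                 overlapOnly = "logical", denomGC = "numeric",
                 denomAT = "numeric", genomeSig = "character"))

setValidity("BaseCountMatrix", function(object) {
  if (ncol(object@counts) != 8) return("counts must have 8 columns")
  if (any(object@counts < 0)) return("counts must be non-negative")
  TRUE
})

#' Per-sample mutation counts and frequencies
#'
#' Substitution counts and frequencies per million class base calls for the
#' six pyrimidine-represented types, and (when context is available) for the
#' 96 trinucleotide classes. 96-class frequencies use the type's whole
#' base-pair-class denominator, so they partition each type's frequency
#' across contexts.
#'
#' @slot sample,group,dose sample metadata.
#' @slot counts6,freq6 named length-6 vectors (C>A ... T>G).
#' @slot counts96,freq96 named length-96 vectors in conventional class order.
#' @slot denomGC,denomAT total filtered base calls over G:C / A:T sites.
#' @exportClass MutationFrequencyTable
setClass("MutationFrequencyTable",
  representation(sample = "character", group = "character", dose = "numeric",
                 counts6 = "numeric", freq6 = "numeric",
                 counts96 = "numeric", freq96 = "numeric",
                 denomGC = "numeric", denomAT = "numeric"))

setValidity("MutationFrequencyTable", function(object) {
  if (length(object@counts6) != 6 || length(object@freq6) != 6)
    return("six-type vectors must have length 6")
  if (length(object@counts96) != 96 || length(object@freq96) != 96)
    return("96-class vectors must have length 96")
  if (any(object@freq6 < 0)) return("frequencies must be non-negative")
  gc <- sum(object@counts6[c("C>A", "C>G", "C>T")])
  at <- sum(object@counts6[c("T>A", "T>C", "T>G")])
  if (gc > object@denomGC || at > object@denomAT)
    return("substitution counts exceed their denominators")
  TRUE
})

#' Control-subtracted excess frequencies
#'
#' Excess frequency of each substitution type (and 96 class) in an exposed
#' sample over the mean of the control replicates. Negative values are
#' retained (sampling noise around a true zero); they are only clipped when
#' spectra are built.
#'
#' @slot sample exposed sample id.
#' @slot delta6,delta96 named excess-frequency vectors (per 1e6 class bp).
#' @slot controlMean6,controlMean96 the subtracted control means.
#' @slot nControls number of control replicates averaged.
#' @exportClass DeltaFrequencyTable
setClass("DeltaFrequencyTable",
  representation(sample = "character", delta6 = "numeric",
                 delta96 = "numeric", controlMean6 = "numeric",
                 controlMean96 = "numeric", nControls = "integer"))

#' Normalized 96-trinucleotide spectrum
#'
#' @slot name spectrum label.
#' @slot weights named non-negative length-96 vector in class order; sums to
#'   1 when `normalized` is TRUE.
#' @slot normalized logical.
#' @exportClass Spectrum96
setClass("Spectrum96",
  representation(name = "character", weights = "numeric",
                 normalized = "logical"))

setValidity("Spectrum96", function(object) {
  if (length(object@weights) != 96) return("weights must have length 96")
  if (any(object@weights < 0)) return("weights must be non-negative")
  if (object@normalized && abs(sum(object@weights) - 1) > 1e-9)
    return("normalized spectrum must sum to 1")
  TRUE
})

#' A set of 96-class spectra
#'
#' Column-per-spectrum matrix used for catalogue comparison and clustering.
#'
#' @slot weights 96 x n numeric matrix, rownames are the class labels,
#'   colnames the spectrum names.
#' @exportClass SpectrumSet
setClass("SpectrumSet", representation(weights = "matrix"))

setValidity("SpectrumSet", function(object) {
  if (nrow(object@weights) != 96) return("96 rows required")
  if (is.null(colnames(object@weights)) ||
      anyDuplicated(colnames(object@weights)))
    return("spectrum names must be present and unique")
  if (any(object@weights < 0)) return("weights must be non-negative")
  TRUE
})

#' Result of Dunnett's many-to-one comparison
#'
#' @slot table data frame with one row per (response, group): group mean,
#'   difference from control, standard error, Dunnett statistic, family-wise
#'   adjusted p-value and significance stars.
#' @slot pooledSD,df pooled within-group standard deviation and its degrees
#'   of freedom (per response when several responses are tested).
#' @slot alternative "two.sided" or "greater".
#' @exportClass DunnettResult
setClass("DunnettResult",
  representation(table = "data.frame", pooledSD = "numeric", df = "numeric",
                 alternative = "character"))

#' Subsampling power curve
#'
#' @slot table data frame with one row per (size, iteration, type):
#'   adjusted p-value, excess frequency and detection indicator.
#' @slot alpha significance level used for the detection indicator.
#' @exportClass PowerCurve
setClass("PowerCurve",
  representation(table = "data.frame", alpha = "numeric"))

#' Hierarchical clustering of spectra
#'
#' Agglomerative clustering on 1 - cosine distances.
#'
#' @slot dist full pairwise distance matrix.
#' @slot tree the [stats::hclust] tree (n - 1 merges).
#' @slot linkage linkage method used.
#' @exportClass SpectrumClustering
setClass("SpectrumClustering",
  representation(dist = "matrix", tree = "ANY", linkage = "character"))

#' Spike-in validation construct design
#'
#' A plasmid-like construct (backbone with a central random insert) plus the
#' six single-substitution variants used to create samples with exactly known
#' mutation frequencies: one G:C site and the adjacent A:T site of the insert
#' are each replaced by the three alternative base pairs.
#'
#' @slot reference single-contig [ReferenceGenome] of the control construct.
#' @slot insertStart,insertEnd 0-based half-open insert region.
#' @slot gcPos,atPos 0-based positions of the variant G:C and A:T sites.
#' @slot gcRef,atRef reference bases at those sites.
#' @slot variants named character vector of the six variant sequences.
#' @slot nGCInsert,nATInsert class site counts over the insert region, the
#'   denominators of the designed frequencies.
#' @exportClass SpikeInDesign
setClass("SpikeInDesign",
  representation(reference = "ANY", insertStart = "integer",
                 insertEnd = "integer", gcPos = "integer", atPos = "integer",
                 gcRef = "character", atRef = "character",
                 variants = "character", nGCInsert = "numeric",
                 nATInsert = "numeric"))

#' Weighted molecule pool
#'
#' A finite population of template molecules with sampling weights, e.g. a
#' spike-in mixture. All molecules must share coordinates with the reference
#' they derive from (single-substitution variants do).
#'
#' @slot sequences molecule sequences.
#' @slot weights sampling weights (need not sum to 1).
#' @slot reference the [ReferenceGenome] the molecules derive from.
#' @slot truth free-form list describing the designed mutation content.
#' @exportClass MoleculePool
setClass("MoleculePool",
  representation(sequences = "character", weights = "numeric",
                 reference = "ANY", truth = "list"))

setValidity("MoleculePool", function(object) {
  if (length(object@sequences) != length(object@weights))
    return("sequences and weights lengths differ")
  if (any(object@weights < 0) || sum(object@weights) <= 0)
    return("weights must be non-negative with positive sum")
  TRUE
})

#' Per-context exposure model
#'
#' Excess mutation rates per eligible site per molecule for each of the 96
#' trinucleotide classes. Used by the read simulator to plant substitutions
#' as independent per-site events; the simulated population is effectively
#' infinite (every fragment derives from an independent molecule), matching a
#' bulk DNA extract.
#'
#' @slot reference single-contig [ReferenceGenome].
#' @slot rate96 named per-site rates for the 96 classes (pyrimidine
#'   representation; a rate applies to both strands' sites of its class).
#' @slot rateNoContext per-type rates applied at class sites lacking
#'   trinucleotide context (contig ends, N neighbours).
#' @exportClass ExposureModel
setClass("ExposureModel",
  representation(reference = "ANY", rate96 = "numeric",
                 rateNoContext = "numeric"))

#' Sequencing error profile
#'
#' Per-base miscall rates for the read simulator, a flat base quality, an
#' optional fragment-level oxidative G>T artifact, and per-sample lognormal
#' rate jitter emulating library-to-library variability. Miscalls are
#' independent between mates, so after overlap consensus a miscall pair
#' survives at rate(b,a)^2; the oxidative artifact modifies the fragment
#' before sequencing and therefore survives consensus, on the read-1 strand
#' only.
#'
#' @slot misRates 4x4 matrix of per-base miscall rates, rows = true base,
#'   columns = called base (A,C,G,T order), diagonal ignored.
#' @slot oxoRate fragment-level G>T modification rate on the read-1 strand.
#' @slot qualPhred flat Phred quality assigned to simulated bases.
#' @slot jitterSdLog,oxoJitterSdLog sdlog of the per-sample lognormal
#'   multipliers applied to misRates / oxoRate.
#' @exportClass ErrorProfile
setClass("ErrorProfile",
  representation(misRates = "matrix", oxoRate = "numeric",
                 qualPhred = "numeric", jitterSdLog = "numeric",
                 oxoJitterSdLog = "numeric"))

setValidity("ErrorProfile", function(object) {
  m <- object@misRates
  if (!all(dim(m) == c(4, 4))) return("misRates must be 4x4")
  if (any(m < 0) || any(m[row(m) != col(m)] > 0.01))
    return("miscall rates must lie in [0, 0.01]")
  if (object@oxoRate < 0 || object@oxoRate > 0.01)
    return("oxoRate must lie in [0, 0.01]")
  TRUE
})
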