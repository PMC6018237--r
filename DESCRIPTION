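Package: popmutscan
Title: Population-Level Mutation Frequency Detection from Overlapping
    Paired-End Reads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects chemically induced increases in base-substitution
    frequencies in heterogeneous cell populations from paired-end
    overlapping sequencing reads, without single-cell cloning. Read pairs
    are merged over their overlap and only mate-consistent bases are
    retained, suppressing sequencing error quadratically. Per-type
    mutation frequencies per million G:C or A:T base calls are computed
    from pileup counts, control background is subtracted, and dose groups
    are compared against control with Dunnett's many-to-one test.
    Trinucleotide (96-class) mutation spectra are built from the excess
    frequencies and compared with signature catalogues by cosine
    similarity and hierarchical clustering. A seeded simulator generates
    spike-in plasmid validation samples and mutagen-exposed genome
    populations with calibrated per-type error models, so detection
    limits and parameter recovery are testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    mvtnorm,
    ape,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    jsonlite,
    optparse,
    Rsamtools
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
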