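Package: tefam
Title: Transposable-Element Family Enrichment from ChIP-Seq with an
    Input-Based Simulated Background
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates ChIP-seq enrichment at transposable-element (TE)
    families and subfamilies while retaining ambiguously mapping reads.
    Read mappings are counted fractionally, down-weighted by each read's
    number of genomic mappings and by the fraction of the read overlapping
    a TE copy. A background model is learned from the input-control
    library as a per-nucleotide, ambiguity-weighted coverage distribution;
    simulated input libraries of matched size are drawn from it and used
    to compute empirical P-values and fold-changes per family. Includes
    RepeatMasker annotation processing, coverage-percentile artifact
    masking, a uniform-shuffle baseline for bias comparison, and a
    synthetic fixture generator with known multimapping structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    GenomicAlignments,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Biostrings,
    Rsamtools,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
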