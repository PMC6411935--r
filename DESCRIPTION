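Package: locusTE
Title: Locus-Level Quantification of Transposable Element Expression from RNA-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies transposable element (TE) RNA expression at
    single-locus resolution from genome-wide RNA-seq alignments that retain
    multi-mapping reads. Multi-mapped fragments are fractionally assigned to
    candidate TE loci in proportion to unique-read evidence normalized by
    uniquely alignable length, then refined by an expectation-maximization
    loop that normalizes by transcribed effective length and zeroes
    unsupported loci. Includes RepeatMasker annotation parsing, SAM/BAM
    fragment classification with mate rescue and a 50%-flank rule, per-locus
    confidence scores and FPKM, subfamily aggregation, table/BED/bedGraph
    writers, and a synthetic genome/read/alignment generator with an
    exhaustive oracle aligner for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    optparse,
    yaml,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    GenomicAlignments
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
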