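Package: TIRpoly
Title: DNA Transposon Insertion and Excision Polymorphisms Between
    Closely Related Genome Assemblies
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects and classifies presence/absence polymorphisms caused by
    DNA (Class II, TIR-order) transposon insertions and excisions between two
    closely related genome assemblies. Implements whole-genome anchoring by
    5-kb fragments, windowed Smith-Waterman alignment with affine gap
    penalties, indel extraction with size, merge and N-content filters,
    target-site-duplication based classification of insertions versus
    excision footprints (perfect, flanking deletion, filler DNA), iterative
    de novo discovery of TIR element families, and the downstream activity
    statistics: insertion-to-excision ratio tests against the 2:1
    replication-fork expectation, relative activity and abundance groupings,
    fixation-rate arithmetic, attribution of assembly gaps to hidden
    transposons, and gene-context classification. A seeded simulator
    generates pairs of diverged genomes with planted elements and a ground
    truth log for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
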