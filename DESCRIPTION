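Package: srnapipe
Title: Small RNA Sequencing Analysis with Planted-Truth Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for small RNA sequencing libraries:
    adapter trimming and tag collapsing, exact all-hits genome mapping,
    priority-rule annotation against noncoding RNA references, gene models
    and known microRNAs, siRNA duplex detection with 2-nt 3' overhang
    geometry, hairpin precursor discovery with a dinucleotide-shuffle
    minimum-free-energy significance test and a 5'-end homogeneity decision
    rule, and rule-based microRNA target prediction. A synthetic-data
    generator plants truth-annotated hairpin loci, noncoding RNA fragments,
    siRNA duplexes and repeats in a toy genome so that every stage is
    testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
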