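Package: satscribe
Title: Satellite DNA Detection, Family Clustering and Tissue-Level
    Transcription Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects tandem-repeat satellites in a genome by clustering
    primitive decamer seeds, delimits repeat arrays and their unit lengths,
    groups satellites into families by cyclic-permutation- and
    strand-aware alignment of repeat consensuses, classifies each
    satellite's genomic context against gene models and transposon
    annotation, quantifies tissue-level satellite transcription from
    RNA-seq reads with an RPKM normalization, and renders per-nucleotide
    coverage profiles. Includes a synthetic-data generator that plants
    satellites, gene models, Helitron-style loci and tissue-stratified
    reads with full ground truth, so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    ggplot2,
    methods,
    rlang,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
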