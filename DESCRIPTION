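Package: atacqc
Title: Quality Metrics, Defined-FRiP Simulation and Functional-Bias
    Statistics for ATAC-seq Fragment Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the five library-quality metrics commonly used for
    ATAC-seq (fraction of reads in peaks, TSS enrichment, sub-nucleosomal
    score, percent mitochondrial reads, and Lander-Waterman library
    complexity) on aligned paired-end fragments; reconstitutes libraries at
    defined FRiP and read depth from a signal/background partition to study
    metric robustness; calls peaks with a desk-scale Poisson pileup caller;
    tracks peak reproducibility across experimental conditions; and tests
    condition-specific "missing" peaks for enrichment against ChIP-seq peak
    sets with hypergeometric statistics, FRiP-TF coverage matrices, and
    genome-segmentation read annotation. A seeded synthetic-data generator
    emulates genomes, peak landscapes and fragment libraries so that every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
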