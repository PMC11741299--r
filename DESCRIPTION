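Package: cutnet
Title: Bias-Factorized Base-Resolution Models of Chromatin Accessibility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Base-resolution modelling of ATAC-seq and DNase-seq cleavage
    profiles with explicit factorization of enzyme sequence bias (Tn5
    transposase or DNase-I) from regulatory sequence signal. A small frozen
    convolutional bias submodel trained on background chromatin is combined
    with a trainable residual submodel; disconnecting the bias submodel
    yields bias-corrected profile and count predictions. On top of the
    corrected model the package provides per-base contribution scores
    against dinucleotide-shuffled references, marginal footprinting with
    footprint height and width geometry, allele-substitution variant effect
    scores (logFC, signed JSD, AAQ, IES, IPS) with empirical p-values, and
    profile and count evaluation metrics. A seeded cleavage simulator
    generates synthetic genomes with planted enzyme bias, motif-driven
    accessibility and footprints so that every stage is testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    methods,
    S4Vectors,
    rtracklayer,
    jsonlite,
    pROC,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
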