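Package: introscan
Title: Detecting Adaptive Introgression with Simulation-Trained
    Convolutional Networks
Version: 0.1.0
Authors@R:
    person("introscan", "developers", email = "introscan@example.org",
           role = c("aut", "cre"))
Description: Simulation, encoding, training, calibration and genome-scanning
    machinery for detecting adaptive introgression from population genomic
    data. Includes a forward Wright-Fisher simulator with selection,
    admixture pulses and rejection sampling; conversion of haplotype data to
    population-blocked, similarity-sorted minor-allele-count matrices; a
    strided convolutional binary classifier trained on simulations; beta,
    isotonic and Platt probability calibration for imbalanced class ratios;
    archaic-admixture summary statistics (U, Q95, f_d) with empirical
    p-values; classifier evaluation (ROC, precision-recall, MCC-F1 curves);
    input-gradient saliency maps; and sliding-window genome scans of VCF
    data with gene annotation of top-ranked regions.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    VariantAnnotation,
    SummarizedExperiment,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
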