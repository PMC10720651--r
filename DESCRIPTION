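Package: dcmscan
Title: Selection-Signature Genome Scans with De-Correlated Composite Signals
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting signatures of recent
    positive selection from multi-sample SNP data: GATK-style hard
    filtering and PLINK-style quality control (call rate, minor allele
    frequency, Hardy-Weinberg exact test, windowed LD pruning,
    identity-by-state sample filtering), genetic-diversity summaries
    (observed homozygosity, inbreeding coefficients, nonparametric group
    tests, PCA), four per-locus selection statistics (sliding-window
    Tajima's D, per-site nucleotide diversity, iHS and nSL from phased
    haplotypes), and their combination into the de-correlated composite
    of multiple signals (DCMS) using a minimum covariance determinant
    robust correlation matrix, with candidate-region calling and gene
    overlap. Includes a seedable phased-haplotype simulator with planted
    selective sweeps so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    IRanges,
    GenomicRanges,
    S4Vectors,
    VariantAnnotation,
    SummarizedExperiment
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
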