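Package: starchgwas
Title: Single-Locus and Multi-Locus GWAS for Maize Starch Pasting Properties
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide association analysis of quantitative traits
    on inbred association panels, built around the starch pasting properties of
    maize. Provides a synthetic inbred-panel generator with population
    structure and linkage disequilibrium, genotype input/output and marker
    quality control, kinship, principal-component structure control and LD
    decay, REML variance components and heritability, one exact single-locus
    mixed-model scan and three multi-locus scans (two-stage EM empirical
    Bayes, iterative pseudo-QTN fixed/random modelling, and L1-penalised
    regression with a Wald test), a Monte-Carlo power and Type-I-error
    benchmark, and QTN reporting with candidate-gene window annotation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Rcpp,
    data.table,
    yaml,
    lme4,
    vcfR,
    GenomicRanges,
    IRanges,
    rtracklayer
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    jsonlite,
    knitr
Config/testthat/edition: 3
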