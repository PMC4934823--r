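Package: hybridgp
Title: Genomic Prediction of Hybrid Performance in Factorial Crossing Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for hybrid breeding programs based
    on factorial (female x male) crossing schemes evaluated in multi-environment,
    partially replicated field trials. Provides synthetic-data generation with
    known genetic architecture, SNP marker quality control and F-infinity
    additive/dominance coding, two-stage phenotypic analysis (per-environment
    adjusted entry means, across-environment BLUEs, mid-parent heterosis,
    combining-ability decomposition, one-step variance components and
    heritability), kinship-corrected genome-wide association scans with
    Bonferroni-Holm multiple-testing control, genomic prediction by RR-BLUP,
    weighted BLUP and Bayes-C-pi with additive and dominance marker effects, and
    relatedness-stratified (T2/T1/T0) cross-validation including estimation-set
    composition and marker-density resampling studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    lme4,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
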