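Package: amazonswitch
Title: Transcriptomic and Population-Genomic Analysis of Repeated
    Transitions to Asexuality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for characterising independent transitions
    from sexual reproduction to asexuality ("Amazon" populations) in
    haploid-dioicous organisms such as the brown alga Scytosiphon.
    Provides sex-biased expression calling from count matrices with a
    per-gene negative binomial GLM, detection of convergent expression
    shifts across species with a block-constrained permutation null,
    defeminization/masculinization indices, within-population piN/piS
    estimation from haploid variant tables (Nei-Gojobori site counting),
    an Amazon-associated variant filter cascade with cross-species
    intersection, pairwise dN/dS by the counting estimator, and a
    ground-truth-labelled synthetic data generator emulating the study
    design.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    lme4,
    vcfR,
    seqinr,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    Biostrings
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
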