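Package: omicblup
Title: Genomic and Transcriptomic BLUP Models for Phenotype Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mixed linear models for predicting phenotypes from SNP genotypes and
    transcript abundances in a single population: GBLUP, TBLUP, GTBLUP and the
    genotype-conditioned GTCBLUP/GTCBLUPi models in which transcript abundances are
    conditioned on genotypes through a ridge-regression smoother matrix so that the
    transcript random effect carries only non-heritable signal.  Provides
    average-information REML estimation of variance components with dense
    relationship matrices, profile-likelihood grid search for the heritability of
    transcript-level effects, random and family-blocked cross-validation with
    Fisher-z confidence intervals and paired model comparisons, back-solving and
    association testing of individual transcript effects, bivariate transcriptomic
    correlation models, Box-Cox preprocessing, and a gene-dropping simulator for
    F2-cross multi-omics data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
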