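Package: proteodiscover
Title: Discovery-Replication Workflow for Plasma Proteomic Biomarkers of
    Parkinson Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, testable implementation of a multicohort
    plasma-proteomics biomarker workflow for Parkinson disease (PD):
    quality control and normalization of aptamer-based (SOMAScan-style)
    relative-fluorescence measurements, covariate-adjusted per-protein
    linear models for PD versus control discovery with Benjamini-Hochberg
    false-discovery control, candidate ranking by Stability Selection
    (LASSO under double jackknife of samples and features), multisite
    replication with direction-concordance checks, robustness analyses
    (paired on/off-medication tests, sample-handling percent change,
    disease specificity against ALS), and prediction of cognitive decline
    through linear mixed-effects and tertile-stratified Cox proportional
    hazards models.  A synthetic-cohort generator reproduces the
    statistical structure of the study designs so every stage can be
    exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    nlme,
    survival,
    ape,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
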