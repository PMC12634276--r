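Package: rewardrsa
Title: Trial-Level Neural Consistency Analysis of Reward Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for trial-to-trial neural
    consistency of reward receipt in task fMRI. Generates synthetic cohorts
    (event designs, labelled reward-region phantoms, 4D BOLD runs with a
    controllable trial-pattern reliability), performs DVARS-based volume
    censoring and least-squares-sum (LSS) single-trial beta estimation,
    computes representational-similarity statistics within region masks and
    via a spherical searchlight, and applies group inference (ANCOVA with a
    pubertal-development covariate, leave-one-ROI-out MANOVA, permutation
    tests with threshold-free cluster enhancement and family-wise error
    correction) and clinical association models (linear mixed models,
    covariate-adjusted partial correlations, Benjamini-Hochberg FDR).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    Rcpp,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
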