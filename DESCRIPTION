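Package: stressnets
Title: Latent Stress-Network Analysis of Regional Brain Activity and
    Quality-of-Life Outcomes in Multiple Sclerosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting longitudinal change in health-related
    quality of life (HRQoL) in multiple sclerosis from latent neural
    networks extracted from regional cerebral blood flow (CBF) measured
    during an fMRI stress task. Implements per-participant gray-matter
    centering of regional CBF, principal-component extraction of
    stress-stage networks with winner-takes-all region assignment,
    differential network activity for stress exposure and stress
    cessation, robust (Huber M-estimation) regression with
    heteroskedasticity-consistent Wald statistics and permutation
    inference, Bonferroni family-wise error control across networks,
    random-intercept linear mixed models with within-participant
    sign-flip permutation tests for repeated measures, HAQUAMS
    questionnaire scoring, a lesion-aware gray-matter group mask
    builder, and a seeded synthetic-cohort generator that emulates the
    full study design for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    lme4,
    RNifti,
    withr
Config/testthat/edition: 3
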