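Package: nirscit
Title: Prefrontal fNIRS Analysis of Contour Identification Tasks with
    Exhaustive Channel-Subset SVM Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates and analyses block-design prefrontal functional
    near-infrared spectroscopy (fNIRS) recordings acquired during melodic
    contour identification tasks (CITs). Provides symbolic CIT stimulus and
    block construction with behavioural scoring and correlation reports;
    modified Beer-Lambert conversion of two-wavelength intensities to
    oxy-/deoxy-haemoglobin, zero-phase Butterworth band-pass filtering,
    pre-stimulus baseline standardisation and block-mean feature extraction;
    a linear soft-margin support vector machine (sequential minimal
    optimisation in C++) with repeated stratified k-fold cross-validation
    scored by the Matthews correlation coefficient and balanced accuracy;
    exhaustive channel-subset search over hemisphere groupings with ranked
    reports and weight-sign matrices; and a fully seeded synthetic-data
    generator producing two-group cohorts with planted channel effects,
    physiological noise, and behavioural tables with coupled neurocognitive
    scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite,
    optparse
Config/testthat/edition: 3
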