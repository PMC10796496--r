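Package: htematch
Title: Risk-Stratified Heterogeneous Treatment Effects by Propensity
    Kernel Matching and Smoothing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for post hoc heterogeneous-treatment-effect (HTE) analysis
    of two-arm stroke thrombolysis cohorts stratified by clinical
    hemorrhagic-transformation risk scores (DRAGON, SEDAN, HTI). Implements
    the full analysis chain: score calculators, binary logistic models with a
    postestimation battery (link test, Box-Tidwell, Hosmer-Lemeshow,
    collinearity, pseudo R-squared, information criteria, Romano-Wolf
    stepdown multiplicity adjustment, ROC/AUC comparison), conditional
    marginal effects with Sidak-corrected intervals, generalized ordered
    logistic regression under proportional and partial-proportional odds
    with the Brant test, propensity-score Epanechnikov kernel matching
    (ATE/ATT/ATC/NATE and potential-outcome averages), subgroup-as-study
    meta-analytic heterogeneity (Mantel-Haenszel and inverse-variance fixed
    effects, REML random effects, I-squared/H-squared, Egger test), and a
    matching-smoothing local-linear HTE estimator with per-score treatment
    effects. Includes a synthetic cohort generator and a deterministic
    grouped fixture reconstructed from published arm-by-score tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    metafor,
    pROC,
    jsonlite
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
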