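Package: rwenma
Title: Predicting Real-World Treatment Outcomes by Combining Randomized
    and Non-Randomized Individual Patient Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage individual-patient-data (IPD) network meta-analysis
    for building multivariable models that predict a continuous real-world
    outcome under each of several competing treatments.  Each study
    (randomized trial or registry) is analysed separately with a Bayesian
    linear regression, optionally shrinking treatment-covariate interactions
    with a Laplace (Bayesian LASSO) prior; study-level estimates are then
    pooled with multivariate meta-analysis models, including design-adjusted
    variance inflation that down-weights non-randomized evidence.  Includes
    chained-equations predictive-mean-matching imputation, a synthetic
    multi-study IPD generator with a tunable efficacy-effectiveness gap,
    calibration of predicted outcomes and predicted treatment benefit, and
    internal (bootstrap optimism-corrected) and internal-external
    cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
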