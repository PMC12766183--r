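Package: protscore
Title: Sex-Specific Proteomic Extension of Cox Survival Risk Scores
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for extending classical cardiovascular risk scores with
    sex-specific plasma-proteomic biomarkers. Provides a seeded generator of
    biobank-style synthetic cohorts with censored 10-year time-to-event
    outcomes, protein and participant quality filters, chained-equations
    imputation, bootstrap stability selection with LASSO-penalized Cox
    regression per sex stratum, sex-stratified Cox risk models with Breslow
    baseline hazards, and a validation battery covering Harrell's C-index,
    a correlated C-index difference test, categorical net reclassification
    improvement, the integrated discrimination improvement, decile
    calibration, horizon ROC curves, and per-protein incremental
    discrimination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    survival,
    truncnorm,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
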