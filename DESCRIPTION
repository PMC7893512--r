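Package: paitrial
Title: Personalized Advantage Index Analysis for Two-Arm Longitudinal Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates Personalized Advantage Index (PAI) treatment
    recommendations from two-arm randomized-trial data with longitudinal
    depression outcomes. Provides a synthetic-trial generator with known
    predictor/moderator structure, cubic-spline area-under-the-curve outcome
    aggregation with baseline residualization, attenuation-corrected
    collinearity screening and variable transformation, iterative
    random-forest imputation of missing covariates and outcomes, two-step
    variable selection (a forest of model-based recursive-partitioning trees
    with permutation importance, followed by bootstrap backward elimination),
    cross-validated factual/counterfactual outcome prediction with signed PAI
    scores, Johnson-Neyman moderator regions, evaluation contrasts of
    indicated versus non-indicated allocations, and a nested fivefold
    validation that repeats selection and fitting inside training folds.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ranger,
    e1071,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
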