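# Nested fivefold validation: leakage bookkeeping, oracle-forced agreement
# with the primary analysis, and null calibration of the pooled contrast.

test_that("fold bookkeeping keeps training and test ids disjoint", {
  g <- small_complete_trial(seed = 23, n = 60)
  nested <- nested_validate(g$trial,
                            config = pai_config(n_trees = 30, n_boot = 20,
                                                seed = 1),
                            k = 2, seed = 2,
                            forced_selection = list(
                              predictors = "parental_alcohol",
                              moderators = "life_events"))
  expect_true(nested$leakage_audit)
  expect_equal(sort(nested$pai$id), g$trial$id)
  f <- nested$fold_assignments
  expect_equal(sort(unique(f)), 1:2)
  for (ff in 1:2)
    expect_length(intersect(which(f == ff), which(f != ff)), 0)
})

test_that("oracle-forced nested PAIs track the primary PAIs", {
  g <- generate_trial(trial_config(
    n_participants = 1000, missing_rate_covariates = 0,
    missing_rate_outcomes = 0, seed = 33))
  out <- compute_outcomes(g$trial)
  arm01 <- as.integer(g$trial$arm == "IPT")
  kinds <- g$trial$covariate_meta$kind
  tfm <- fit_transforms(g$trial$covariates, kinds)
  Zt <- as.matrix(apply_transforms(g$trial$covariates, tfm))
  oracle <- list(predictors = g$truth$predictor_names,
                 moderators = g$truth$moderator_names)
  primary <- crossval_predict(out$auc_residual, arm01, Zt,
                              oracle$predictors, oracle$moderators,
                              id = g$trial$id, k = 5, seed = 34)
  nested <- nested_validate(g$trial, config = pai_config(seed = 35),
                            k = 5, seed = 36, primary = primary,
                            forced_selection = oracle)
  expect_gt(nested$comparison$correlation, 0.9)
  expect_gt(nested$comparison$agreement["overall"], 0.9)
})

test_that("the indicated/non-indicated contrast is calibrated when the\n          grouping comes from independent data, and its CV-coupled\n          inflation stays bounded", {
  # Control: recommendations from a model fitted on an independent
  # dataset; the participant outcomes never touch the grouping, so the
  # two-sample t test should reject at its nominal level.
  set.seed(40)
  p_ind <- vapply(1:300, function(r) {
    n <- 151
    m <- fit_final_model(rnorm(n), rep_len(0:1, n),
                         cbind(m1 = rnorm(n), m2 = rnorm(n)),
                         moderators = c("m1", "m2"))
    Z <- cbind(m1 = rnorm(n), m2 = rnorm(n))
    a <- rep_len(0:1, n)
    y <- rnorm(n, 16, 5)
    pai <- paitrial:::predict_final(m, Z, rep(0, n)) -
      paitrial:::predict_final(m, Z, rep(1, n))
    got <- ifelse(pai < 0, "CT", "IPT") == ifelse(a == 1, "IPT", "CT")
    contrast(y[got], y[!got])$p
  }, 0)
  expect_gt(mean(p_ind < 0.05), 0.02)
  expect_lt(mean(p_ind < 0.05), 0.09)

  # Cross-validated grouping on the same data couples every participant's
  # outcome to everyone else's label; the null rejection rate roughly
  # doubles (a property of the evaluation design, quantified here so a
  # regression would be caught) but stays well below the double-dipping
  # regime.
  set.seed(41)
  p_cv <- vapply(1:150, function(r) {
    n <- 100
    Z <- cbind(m1 = rnorm(n), m2 = rnorm(n))
    a <- rep_len(0:1, n)
    y <- rnorm(n, 16, 4)
    tab <- crossval_predict(y, a, Z, moderators = c("m1", "m2"),
                            k = 5, seed = 41 + r)
    ev <- evaluate_pai(tab, y)
    ev$contrasts$p[ev$contrasts$contrast == "indicated_vs_non"]
  }, 0)
  rate <- mean(p_cv < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.25)
})

test_that("empty fold selections fall back to an arm-only model", {
  g <- small_complete_trial(seed = 43, n = 64)
  nested <- nested_validate(g$trial,
                            config = pai_config(n_trees = 20, n_boot = 10,
                                                seed = 3),
                            k = 2, seed = 4,
                            forced_selection = list(
                              predictors = character(),
                              moderators = character()))
  # arm-only models give every participant the same signed PAI per fold
  expect_equal(length(unique(round(nested$pai$pai_signed, 10))), 2)
  expect_false(anyNA(nested$pai$pai_signed))
})

test_that("nested selection recovers direction on strongly moderated data", {
  hits <- vapply(1:5, function(r) {
    g <- generate_trial(trial_config(
      n_participants = 151, missing_rate_covariates = 0,
      missing_rate_outcomes = 0, seed = 50 + r))
    out <- compute_outcomes(g$trial)
    arm01 <- as.integer(g$trial$arm == "IPT")
    kinds <- g$trial$covariate_meta$kind
    tfm <- fit_transforms(g$trial$covariates, kinds)
    Zt <- as.matrix(apply_transforms(g$trial$covariates, tfm))
    primary <- crossval_predict(out$auc_residual, arm01, Zt,
                                g$truth$predictor_names,
                                g$truth$moderator_names,
                                id = g$trial$id, k = 5, seed = 60 + r)
    nested <- nested_validate(g$trial,
                              config = pai_config(n_trees = 200,
                                                  n_boot = 100,
                                                  seed = 70 + r),
                              k = 5, seed = 80 + r, primary = primary)
    d_nested <- nested$evaluation$contrasts$d[
      nested$evaluation$contrasts$contrast == "indicated_vs_non"]
    d_primary <- evaluate_pai(primary, out$avg_bdi)$contrasts$d[1]
    length(d_nested) == 1 && sign(d_nested) == sign(d_primary)
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})
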