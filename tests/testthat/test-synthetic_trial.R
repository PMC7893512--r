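# Synthetic trial generator: structure, determinism, missingness,
# correlation targets and generative-coefficient recovery.

test_that("default configuration reproduces the study dimensions", {
  g <- generate_trial(trial_config(seed = 7))
  expect_equal(length(g$trial$id), 151)
  expect_equal(as.vector(table(g$trial$arm)), c(76, 75))
  expect_equal(ncol(g$trial$covariates), 38)
  expect_equal(g$trial$schedule_months, c(7, 8, 9, 10, 11, 12, 24))
  expect_true(all(g$trial$outcomes >= 0 & g$trial$outcomes <= 63,
                  na.rm = TRUE))
  # missingness lands near the study rates
  expect_lt(abs(mean(is.na(g$trial$outcomes)) - 0.155), 0.02)
  expect_lt(mean(is.na(as.matrix(g$trial$covariates))), 0.02)
  # nobody loses every outcome
  expect_true(all(rowSums(!is.na(g$trial$outcomes)) >= 1))
})

test_that("generation is bit-reproducible and mask-free at rate zero", {
  cfg <- trial_config(seed = 21)
  g1 <- generate_trial(cfg)
  g2 <- generate_trial(cfg)
  expect_identical(g1$trial$outcomes, g2$trial$outcomes)
  expect_identical(g1$trial$covariates, g2$trial$covariates)
  expect_identical(g1$truth$avg_outcome_true, g2$truth$avg_outcome_true)
  g0 <- small_complete_trial()
  expect_false(anyNA(g0$trial$outcomes))
  expect_false(anyNA(g0$trial$covariates))
})

test_that("null moderation flags every optimal arm as undefined", {
  g <- generate_trial(trial_config(
    n_participants = 80, mod_effects = c(life_events = 0,
                                         childhood_trauma = 0),
    pred_effects = c(parental_alcohol = 0.5), arm_effect = 0,
    missing_rate_covariates = 0, missing_rate_outcomes = 0, seed = 5))
  expect_equal(g$truth$expected_ct, g$truth$expected_ipt)
  expect_true(all(g$truth$optimal_arm == "none"))
})

test_that("invalid configurations are rejected", {
  expect_error(trial_config(missing_rate_outcomes = 1), "rates")
  expect_error(trial_config(pred_effects = c(life_events = 1)),
               "both a true predictor and a true moderator")
  expect_error(trial_config(schedule_months = c(7, 7, 8)), "increasing")
  expect_error(trial_config(mod_effects = c(life_events = Inf,
                                            childhood_trauma = 0)),
               "finite")
  expect_error(trial_config(n_continuous = 2,
                            block_specs = list(list(size = 5, rho = 0.5))),
               "blocks exceed")
})

test_that("injected missingness hits its target rate", {
  g <- small_complete_trial(seed = 31, n = 151)
  tr <- inject_missingness(g$trial, rate_outcomes = 0.155, seed = 2)
  n_na <- sum(is.na(tr$outcomes))
  expect_lt(abs(n_na / length(tr$outcomes) - 0.155), 0.02)  # ~164 cells
  # rate zero is the identity
  tr0 <- inject_missingness(g$trial, rate_outcomes = 0, seed = 2)
  expect_identical(tr0$outcomes, g$trial$outcomes)
})

test_that("MAR missingness depends on the designated covariate", {
  g <- generate_trial(trial_config(
    n_participants = 5000, n_continuous = 3, n_count = 1, n_binary = 1,
    block_specs = list(), missing_rate_covariates = 0,
    missing_rate_outcomes = 0, seed = 41))
  tr <- inject_missingness(g$trial, rate_outcomes = 0.2,
                           mechanism = "MAR",
                           mar_covariate = "life_events", seed = 3)
  miss_frac <- rowMeans(is.na(tr$outcomes))
  fit <- glm(cbind(round(miss_frac * 7), 7 - round(miss_frac * 7)) ~
               tr$covariates$life_events, family = binomial)
  expect_gt(coef(fit)[2] / sqrt(diag(vcov(fit)))[2], 3)  # positive slope
  expect_lt(abs(mean(is.na(tr$outcomes)) - 0.2), 0.02)
})

test_that("correlated blocks converge to their target correlations", {
  g <- generate_trial(trial_config(
    n_participants = 5000, seed = 51,
    missing_rate_covariates = 0, missing_rate_outcomes = 0))
  X <- as.matrix(g$trial$covariates)
  b1 <- cor(X[, sprintf("cont_%02d", 1:5)])
  b2 <- cor(X[, sprintf("cont_%02d", 6:9)])
  expect_lt(max(abs(b1[upper.tri(b1)] - 0.5)), 0.03)
  expect_lt(max(abs(b2[upper.tri(b2)] - 0.35)), 0.03)
  # off-block stays near zero
  expect_lt(abs(cor(X[, "cont_01"], X[, "cont_06"])), 0.05)
})

test_that("generating coefficients are recovered by regression at n=5000", {
  g <- generate_trial(trial_config(
    n_participants = 5000, seed = 61,
    missing_rate_covariates = 0, missing_rate_outcomes = 0))
  fit <- lm(g$truth$avg_outcome_true ~ g$truth$design - 1)
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  names(est) <- names(se) <- colnames(g$truth$design)
  for (nm in names(g$truth$coefficients)) {
    truth <- g$truth$coefficients[[nm]]
    expect_lt(abs(est[[nm]] - truth), 3 * se[[nm]] + 1e-9)
  }
})

test_that("trial CSV round trip preserves the dataset", {
  g <- small_complete_trial(seed = 71)
  tr <- inject_missingness(g$trial, rate_covariates = 0.01,
                           rate_outcomes = 0.1, seed = 4)
  f <- tempfile(fileext = ".csv")
  write_trial_csv(tr, f, truth = g$truth)
  tr2 <- read_trial_csv(f)
  expect_equal(tr2$arm, tr$arm)
  expect_equal(as.matrix(tr2$covariates), as.matrix(tr$covariates),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(tr2$outcomes, tr$outcomes, tolerance = 1e-12)
  expect_true(file.exists(paste0(f, ".meta.json")))
  unlink(c(f, paste0(f, ".meta.json")))
})
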