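# Shared fixtures, all generated in code.

default_schedule <- c(7, 8, 9, 10, 11, 12, 24)

# a small complete trial without missingness, for deterministic module tests
small_complete_trial <- function(seed = 3, n = 60) {
  generate_trial(trial_config(
    n_participants = n, n_continuous = 4, n_count = 2, n_binary = 1,
    block_specs = list(),
    missing_rate_covariates = 0, missing_rate_outcomes = 0,
    seed = seed))
}

# simple regression fixture: y = b0 + b1*x1 + b2*x2*a + noise
sim_moderated <- function(n, b_arm = 0, b_pred = 0, b_mod = 0, sd = 1,
                          seed = 1) {
  set.seed(seed)
  a <- rep_len(0:1, n)
  Z <- cbind(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  y <- b_arm * a + b_pred * Z[, "x1"] + b_mod * Z[, "x2"] * (a - 0.5) +
    rnorm(n, 0, sd)
  list(y = y, a = a, Z = Z)
}
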