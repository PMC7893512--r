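# Synthetic two-arm randomized trial generator with known
# predictor/moderator structure, longitudinal BDI-II outcomes and injected
# missingness. The generator is the test bed for the whole pipeline: it
# returns both the observable dataset and the ground truth needed for
# recovery checks.

#' Configuration for the synthetic trial generator
#'
#' Defaults emulate the target study conditions: n = 151 participants
#' randomized 1:1 to cognitive therapy (CT) versus interpersonal
#' psychotherapy (IPT), 38 screened baseline covariates of mixed kind, one
#' true binary predictor ("parental_alcohol") and two true count moderators
#' ("life_events", "childhood_trauma") acting on an average-BDI-II outcome
#' followed up at months 7--24, with ~0.4% covariate and ~15.5% outcome
#' missingness.
#'
#' Effect sizes are standardized: outcome residual-SDs per covariate SD
#' (moderator effects per covariate SD per arm contrast). The arm contrast is
#' coded -1/2 (CT) vs +1/2 (IPT) in the generative model, so a positive
#' moderator effect means higher (worse) outcomes under IPT for high values
#' of the covariate.
#'
#' @param n_participants number of participants.
#' @param n_continuous,n_count,n_binary covariate counts by kind; the named
#'   true variables below are appended to these, giving the total covariate
#'   count (defaults total 38).
#' @param block_specs list of `list(size=, rho=)` giving groups of
#'   continuous noise covariates sharing an exchangeable correlation `rho`.
#' @param pred_effects named numeric: true predictor effects (names become
#'   covariate names; kind is binary with prevalence `binary_prev`).
#' @param mod_effects named numeric: true moderator interaction effects
#'   (kind is count with mean `count_lambda`).
#' @param mod_main_ratio moderator main effects as a fraction of their
#'   interaction effects (default 1: moderators are strongly prognostic as
#'   well as prescriptive, consistent with importance rankings in which
#'   moderators outrank pure predictors; 0.5 carries the moderated effect
#'   entirely on one arm as in a `y = x * treatment` node model).
#' @param arm_effect main effect of arm, residual-SD units (default 0: the
#'   two therapies are equally effective on average).
#' @param baseline_mean,baseline_sd baseline BDI-II distribution.
#' @param baseline_slope prognostic effect of baseline BDI-II on the
#'   average-outcome scale, BDI-II points per baseline SD.
#' @param outcome_mean mean of the average follow-up BDI-II.
#' @param residual_sd residual SD of the average follow-up BDI-II.
#' @param schedule_months follow-up measurement months (strictly increasing).
#' @param drift_sd SD of the participant-level linear drift (points/month).
#' @param visit_sd marginal SD of per-visit deviations (BDI-II points).
#' @param visit_rho month-lag autocorrelation of the visit deviations.
#'   Deviations are kept smooth (AR(1)-correlated, small SD) because the
#'   spline AUC over the sparse 12-to-24-month tail is highly sensitive to
#'   independent jitter at adjacent dense visits.
#' @param count_lambda Poisson mean for count covariates.
#' @param binary_prev prevalence for binary covariates.
#' @param missing_rate_covariates,missing_rate_outcomes cell-wise missingness
#'   rates in [0, 1).
#' @param mechanism "MCAR" or "MAR"; under MAR the outcome missingness
#'   probability increases with `mar_covariate`.
#' @param mar_covariate name of the (observed) covariate driving MAR
#'   missingness; defaults to the first moderator.
#' @param month3 include the auxiliary month-3 BDI-II score.
#' @param seed integer RNG seed; the full generation is reproducible.
#' @return object of class `pai_trial_config`.
#' @export
trial_config <- function(n_participants = 151,
                         n_continuous = 21, n_count = 10, n_binary = 4,
                         block_specs = list(list(size = 5, rho = 0.5),
                                            list(size = 4, rho = 0.35)),
                         pred_effects = c(parental_alcohol = 0.4),
                         mod_effects = c(life_events = 0.8,
                                         childhood_trauma = 0.5),
                         mod_main_ratio = 1,
                         arm_effect = 0,
                         baseline_mean = 26.5, baseline_sd = 8,
                         baseline_slope = 3,
                         outcome_mean = 16, residual_sd = 5,
                         schedule_months = c(7, 8, 9, 10, 11, 12, 24),
                         drift_sd = 0.15, visit_sd = 0.5, visit_rho = 0.9,
                         count_lambda = 1.5, binary_prev = 0.3,
                         missing_rate_covariates = 0.004,
                         missing_rate_outcomes = 0.155,
                         mechanism = c("MCAR", "MAR"),
                         mar_covariate = NULL,
                         month3 = TRUE,
                         seed = 1L) {
  mechanism <- match.arg(mechanism)
  stopifnot(n_participants > 0, n_continuous >= 0, n_count >= 0, n_binary >= 0)
  if (missing_rate_covariates < 0 || missing_rate_covariates >= 1 ||
      missing_rate_outcomes < 0 || missing_rate_outcomes >= 1)
    stop("missingness rates must lie in [0, 1)")
  if (any(!is.finite(c(pred_effects, mod_effects, arm_effect))))
    stop("effect sizes must be finite")
  if (is.null(names(pred_effects)) || is.null(names(mod_effects)))
    stop("pred_effects and mod_effects must be named")
  if (length(intersect(names(pred_effects), names(mod_effects))))
    stop("a covariate cannot be both a true predictor and a true moderator")
  if (any(diff(schedule_months) <= 0) || length(schedule_months) < 3)
    stop("schedule_months must be strictly increasing with >= 3 points")
  if (sum(vapply(block_specs, `[[`, 0, "size")) > n_continuous)
    stop("correlated blocks exceed the number of continuous covariates")
  for (b in block_specs)
    if (b$rho < 0 || b$rho >= 1) stop("block rho must lie in [0, 1)")
  if (is.null(mar_covariate) && length(mod_effects)) {
    mar_covariate <- names(mod_effects)[1]
  }
  structure(as.list(environment()), class = "pai_trial_config")
}

# Covariate metadata implied by a config: names and kinds, true variables
# appended after the noise covariates.
covariate_meta <- function(config) {
  nm_noise <- c(sprintf("cont_%02d", seq_len(config$n_continuous)),
                sprintf("count_%02d", seq_len(config$n_count)),
                sprintf("bin_%02d", seq_len(config$n_binary)))
  kind_noise <- rep(c("continuous", "count", "binary"),
                    c(config$n_continuous, config$n_count, config$n_binary))
  nm <- c(nm_noise, names(config$mod_effects), names(config$pred_effects))
  kind <- c(kind_noise,
            rep("count", length(config$mod_effects)),
            rep("binary", length(config$pred_effects)))
  data.frame(name = nm, kind = kind, stringsAsFactors = FALSE)
}

#' Generate a synthetic randomized trial
#'
#' Draws arms (1:1, CT receiving the extra participant for odd n), correlated
#' baseline covariates, baseline BDI-II, a linear generative model on the
#' average follow-up BDI-II scale, smooth within-person trajectories whose
#' noiseless spline AUC equals the model-implied outcome, and finally injects
#' missingness.
#'
#' @param config a [trial_config()].
#' @return list with elements `trial` (class `pai_trial`) and `truth`
#'   (class `pai_truth`).
#' @export
generate_trial <- function(config) {
  stopifnot(inherits(config, "pai_trial_config"))
  with_private_seed(config$seed, {
    n <- config$n_participants
    meta <- covariate_meta(config)
    p <- nrow(meta)

    # 1:1 randomization; CT gets the extra slot for odd n
    n_ct <- ceiling(n / 2)
    arm <- rep("IPT", n)
    arm[sample.int(n, n_ct)] <- "CT"
    arm <- factor(arm, levels = c("CT", "IPT"))
    a <- ifelse(arm == "IPT", 0.5, -0.5)           # centered arm contrast

    # latent Gaussians with exchangeable correlated blocks among the
    # continuous noise covariates
    Z <- matrix(stats::rnorm(n * p), n, p)
    offset <- 0
    for (b in config$block_specs) {
      cols <- offset + seq_len(b$size)
      common <- stats::rnorm(n)
      Z[, cols] <- sqrt(b$rho) * common + sqrt(1 - b$rho) * Z[, cols]
      offset <- offset + b$size
    }

    X <- matrix(NA_real_, n, p, dimnames = list(NULL, meta$name))
    for (j in seq_len(p)) {
      X[, j] <- switch(meta$kind[j],
        continuous = Z[, j],
        count = stats::qpois(stats::pnorm(Z[, j]), lambda = config$count_lambda),
        binary = as.numeric(Z[, j] > stats::qnorm(1 - config$binary_prev)))
    }

    # theoretical standardization so ground-truth coefficients do not depend
    # on the realized sample
    std_moments <- function(kind) switch(kind,
      continuous = c(0, 1),
      count = c(config$count_lambda, sqrt(config$count_lambda)),
      binary = c(config$binary_prev,
                 sqrt(config$binary_prev * (1 - config$binary_prev))))
    Xs <- X
    for (j in seq_len(p)) {
      m <- std_moments(meta$kind[j])
      Xs[, j] <- (X[, j] - m[1]) / m[2]
    }

    baseline <- clip(round(stats::rnorm(n, config$baseline_mean,
                                        config$baseline_sd)), 0, 63)
    base_std <- (baseline - config$baseline_mean) / config$baseline_sd

    sd_r <- config$residual_sd
    beta_pred <- config$pred_effects * sd_r
    beta_mod <- config$mod_effects * sd_r
    beta_arm <- config$arm_effect * sd_r

    beta_mod_main <- beta_mod * config$mod_main_ratio
    fixed <- config$outcome_mean + config$baseline_slope * base_std
    if (length(beta_pred))
      fixed <- fixed + Xs[, names(beta_pred), drop = FALSE] %*% beta_pred
    if (length(beta_mod))
      fixed <- fixed + Xs[, names(beta_mod), drop = FALSE] %*% beta_mod_main
    mod_part <- if (length(beta_mod))
      as.numeric(Xs[, names(beta_mod), drop = FALSE] %*% beta_mod) else 0
    expected_ct <- as.numeric(fixed) + (-0.5) * (beta_arm + mod_part)
    expected_ipt <- as.numeric(fixed) + 0.5 * (beta_arm + mod_part)
    eps <- stats::rnorm(n, 0, sd_r)
    avg_true <- ifelse(arm == "IPT", expected_ipt, expected_ct) + eps

    # trajectories: level + linear drift centered at the midpoint of the
    # follow-up window, so the noiseless spline AUC equals avg_true * span
    sched <- config$schedule_months
    span <- diff(range(sched))
    mid <- mean(range(sched))
    drift <- stats::rnorm(n, 0, config$drift_sd)
    # smooth AR(1)-correlated visit deviations (see visit_rho above)
    vis <- if (config$visit_sd > 0) {
      Svis <- config$visit_sd^2 *
        config$visit_rho^abs(outer(sched, sched, "-"))
      matrix(stats::rnorm(n * length(sched)), n) %*% chol(Svis)
    } else 0
    traj <- outer(avg_true, rep(1, length(sched))) +
      outer(drift, sched - mid) + vis
    n_clipped <- sum(traj < 0 | traj > 63)
    outcomes <- clip(traj, 0, 63)
    colnames(outcomes) <- paste0("bdi_m", sched)

    bdi_m3 <- if (config$month3)
      clip(round(0.5 * baseline + 0.5 * avg_true + stats::rnorm(n, 0, 3)),
           0, 63) else NULL

    trial <- structure(list(
      id = seq_len(n), arm = arm,
      covariates = as.data.frame(X),
      covariate_meta = meta,
      baseline_bdi = baseline,
      bdi_m3 = bdi_m3,
      outcomes = outcomes,
      schedule_months = sched,
      n_clipped = n_clipped), class = "pai_trial")

    diff_true <- expected_ct - expected_ipt
    truth <- structure(list(
      predictor_names = names(beta_pred),
      moderator_names = names(beta_mod),
      coefficients = c(intercept = config$outcome_mean,
                       baseline_slope = config$baseline_slope,
                       arm = beta_arm, beta_pred,
                       beta_mod_main,
                       stats::setNames(beta_mod,
                                       paste0(names(beta_mod), ":arm"))),
      expected_ct = expected_ct, expected_ipt = expected_ipt,
      avg_outcome_true = avg_true,
      true_pai = diff_true,                 # prediction(CT) - prediction(IPT)
      optimal_arm = ifelse(abs(diff_true) < 1e-12, "none",
                           ifelse(diff_true < 0, "CT", "IPT")),
      design = local({
        d <- cbind(intercept = 1, baseline_slope = base_std, arm = a)
        if (length(beta_pred))
          d <- cbind(d, Xs[, names(beta_pred), drop = FALSE])
        if (length(beta_mod))
          d <- cbind(d, Xs[, names(beta_mod), drop = FALSE])
        if (length(beta_mod)) {
          m <- Xs[, names(beta_mod), drop = FALSE] * a
          colnames(m) <- paste0(names(beta_mod), ":arm")
          d <- cbind(d, m)
        }
        d
      }),
      residual_sd = sd_r), class = "pai_truth")

    miss_seed <- config$seed + 1L
    trial <- inject_missingness(trial,
                                rate_covariates = config$missing_rate_covariates,
                                rate_outcomes = config$missing_rate_outcomes,
                                mechanism = config$mechanism,
                                mar_covariate = config$mar_covariate,
                                seed = miss_seed)
    list(trial = trial, truth = truth)
  })
}

#' Inject missingness into a trial dataset
#'
#' Masks covariate cells (MCAR) and outcome cells (MCAR, or MAR with the
#' missingness probability tied to an observed covariate) at the target
#' rates. Rows that would lose every follow-up outcome are re-drawn so each
#' participant keeps at least one observed outcome.
#'
#' @param trial a `pai_trial`.
#' @param rate_covariates,rate_outcomes target cell-wise rates in [0, 1).
#' @param mechanism "MCAR" or "MAR" (outcomes only).
#' @param mar_covariate covariate name driving MAR outcome missingness.
#' @param seed RNG seed.
#' @return the trial with NA cells inserted.
#' @export
inject_missingness <- function(trial, rate_covariates = 0, rate_outcomes = 0,
                               mechanism = c("MCAR", "MAR"),
                               mar_covariate = NULL, seed = 1L) {
  mechanism <- match.arg(mechanism)
  if (rate_covariates < 0 || rate_covariates >= 1 ||
      rate_outcomes < 0 || rate_outcomes >= 1)
    stop("rates must lie in [0, 1)")
  with_private_seed(seed, {
    n <- length(trial$id)
    if (rate_covariates > 0) {
      pcells <- n * ncol(trial$covariates)
      mask <- matrix(stats::runif(pcells) < rate_covariates, n,
                     ncol(trial$covariates))
      trial$covariates[mask] <- NA
    }
    if (rate_outcomes > 0) {
      m <- ncol(trial$outcomes)
      if (mechanism == "MCAR") {
        prob <- matrix(rate_outcomes, n, m)
      } else {
        if (is.null(mar_covariate) ||
            !mar_covariate %in% names(trial$covariates))
          stop("MAR mechanism needs an existing mar_covariate")
        x <- trial$covariates[[mar_covariate]]
        x[is.na(x)] <- mean(x, na.rm = TRUE)
        xs <- as.numeric(scale(x))
        # solve the intercept so the marginal rate hits the target
        alpha <- stats::uniroot(function(al)
          mean(stats::plogis(al + xs)) - rate_outcomes,
          interval = c(-20, 20))$root
        prob <- matrix(stats::plogis(alpha + xs), n, m)
      }
      mask <- matrix(stats::runif(n * m), n, m) < prob
      # keep >= 1 observed outcome per participant
      for (i in which(rowSums(!mask) == 0))
        mask[i, sample.int(m, 1)] <- FALSE
      trial$outcomes[mask] <- NA
    }
    trial
  })
}

#' @export
print.pai_trial <- function(x, ...) {
  cat(sprintf("<pai_trial> %d participants (CT %d / IPT %d), %d covariates\n",
              length(x$id), sum(x$arm == "CT"), sum(x$arm == "IPT"),
              ncol(x$covariates)))
  cat(sprintf("  follow-up months: %s\n",
              paste(x$schedule_months, collapse = ", ")))
  cat(sprintf("  missing: %d covariate cells (%.2f%%), %d outcome cells (%.1f%%)\n",
              sum(is.na(x$covariates)),
              100 * mean(is.na(as.matrix(x$covariates))),
              sum(is.na(x$outcomes)), 100 * mean(is.na(x$outcomes))))
  invisible(x)
}

#' Write a trial dataset to CSV with a JSON metadata sidecar
#'
#' One row per participant; empty cells are missing values. The sidecar
#' stores covariate kinds and the follow-up schedule (and ground truth, if
#' supplied).
#'
#' @param trial a `pai_trial`.
#' @param file CSV path; the sidecar is written next to it as
#'   `<file>.meta.json`.
#' @param truth optional `pai_truth` to embed in the sidecar.
#' @export
write_trial_csv <- function(trial, file, truth = NULL) {
  df <- data.frame(id = trial$id, arm = as.character(trial$arm),
                   baseline_bdi = trial$baseline_bdi)
  if (!is.null(trial$bdi_m3)) df$bdi_m3 <- trial$bdi_m3
  df <- cbind(df, trial$covariates, as.data.frame(trial$outcomes))
  utils::write.csv(df, file, row.names = FALSE, na = "")
  meta <- list(covariate_meta = trial$covariate_meta,
               schedule_months = trial$schedule_months,
               has_month3 = !is.null(trial$bdi_m3))
  if (!is.null(truth))
    meta$truth <- truth[c("predictor_names", "moderator_names",
                          "coefficients", "optimal_arm")]
  jsonlite::write_json(meta, paste0(file, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read a trial dataset written by [write_trial_csv()]
#' @param file CSV path (sidecar `<file>.meta.json` must exist).
#' @return a `pai_trial`.
#' @export
read_trial_csv <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(file, ".meta.json"),
                              simplifyVector = TRUE)
  sched <- meta$schedule_months
  ocols <- paste0("bdi_m", sched)
  structure(list(
    id = df$id, arm = factor(df$arm, levels = c("CT", "IPT")),
    covariates = df[, meta$covariate_meta$name, drop = FALSE],
    covariate_meta = as.data.frame(meta$covariate_meta),
    baseline_bdi = df$baseline_bdi,
    bdi_m3 = if (isTRUE(meta$has_month3)) df$bdi_m3 else NULL,
    outcomes = as.matrix(df[, ocols, drop = FALSE]),
    schedule_months = sched, n_clipped = NA), class = "pai_trial")
}
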