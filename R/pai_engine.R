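# Final moderated regression, cross-validated factual/counterfactual
# predictions, signed PAI scores, and Johnson-Neyman moderator regions.
#
# Sign convention (documented prominently because it is easy to get wrong):
# the arm is coded 0/1 with CT = 0 and IPT = 1, and the signed PAI is
# prediction(CT) - prediction(IPT). Lower outcomes are better, so a
# negative PAI indicates CT and a positive PAI indicates IPT.

final_design <- function(Z, arm01, predictors, moderators,
                         include_arm_main = TRUE) {
  X <- cbind(`(Intercept)` = rep(1, length(arm01)))
  if (include_arm_main) X <- cbind(X, arm = arm01)
  for (v in predictors) { X <- cbind(X, Z[, v]); colnames(X)[ncol(X)] <- v }
  for (v in moderators) { X <- cbind(X, Z[, v]); colnames(X)[ncol(X)] <- v }
  for (v in moderators) {
    X <- cbind(X, Z[, v] * arm01)
    colnames(X)[ncol(X)] <- paste0(v, ":arm")
  }
  X
}

#' Fit the final moderated outcome regression
#'
#' OLS of the outcome on the selected predictors (main effects only), the
#' moderators' main effects, and the moderator-by-arm interactions. The arm
#' main effect is included by default (marginality) even though a selected
#' model may not demand it; switching it off triggers a warning.
#'
#' @param y outcome (residualized AUC in the primary analysis).
#' @param arm01 0/1 arm indicator (CT = 0, IPT = 1).
#' @param Z covariate matrix on the modeling (transformed) scale.
#' @param predictors,moderators covariate names by role (either may be
#'   empty).
#' @param include_arm_main keep the arm main effect (default TRUE).
#' @return list of class `pai_final_model`: `coef`, `vcov`, `df_residual`,
#'   `predictors`, `moderators`, `moderator_means`, `moderator_range`,
#'   `arm_coding`.
#' @export
fit_final_model <- function(y, arm01, Z, predictors = character(),
                            moderators = character(),
                            include_arm_main = TRUE) {
  if (!include_arm_main)
    warning("arm main effect excluded; interaction terms are no longer ",
            "interpretable as treatment-effect modification")
  Z <- as.matrix(Z)
  if (length(unique(arm01)) < 2) stop("both arms must be present")
  X <- final_design(Z, arm01, predictors, moderators, include_arm_main)
  if (nrow(X) <= ncol(X)) stop("more parameters than observations")
  fit <- fast_ols(X, y)
  if (any(fit$aliased)) stop("design matrix is rank deficient")
  mods <- moderators
  structure(list(coef = fit$coef, vcov = fit$vcov,
                 df_residual = fit$df_residual, sigma2 = fit$sigma2,
                 predictors = predictors, moderators = mods,
                 include_arm_main = include_arm_main,
                 moderator_means = if (length(mods))
                   colMeans(Z[, mods, drop = FALSE]) else numeric(),
                 moderator_range = if (length(mods))
                   apply(Z[, mods, drop = FALSE], 2, range) else NULL,
                 arm_coding = c(CT = 0, IPT = 1)),
            class = "pai_final_model")
}

predict_final <- function(model, Z, arm01) {
  X <- final_design(as.matrix(Z), arm01, model$predictors,
                    model$moderators, model$include_arm_main)
  drop(X %*% model$coef)
}

#' Cross-validated factual/counterfactual predictions and PAI scores
#'
#' Splits participants into `k` near-equal folds (random, stratified by arm
#' so every training set keeps both arms), fits the final model on the
#' other k-1 folds, and predicts each held-out participant twice: once with
#' the arm set to CT and once to IPT. The signed PAI is
#' prediction(CT) - prediction(IPT); its sign gives the indicated arm
#' (negative = CT, positive = IPT, exact zero = "none") and its magnitude
#' the predicted advantage.
#'
#' @inheritParams fit_final_model
#' @param id participant identifiers.
#' @param k number of folds (default 5).
#' @param seed RNG seed for the fold assignment.
#' @param folds optional precomputed fold assignment (overrides `k`/`seed`);
#'   every training split must retain both arms.
#' @return data.frame of class `pai_table`: `id`, `arm`, `fold`,
#'   `pred_ct`, `pred_ipt`, `factual`, `counterfactual`, `pai_signed`,
#'   `pai_abs`, `pai_percentile`, `indicated`.
#' @export
crossval_predict <- function(y, arm01, Z, predictors = character(),
                             moderators = character(), id = seq_along(y),
                             k = 5, seed = 1L, include_arm_main = TRUE,
                             folds = NULL) {
  stopifnot(k >= 2)
  Z <- as.matrix(Z)
  n <- length(y)
  fold <- folds %||% with_private_seed(seed, make_folds(arm01, k))
  k <- max(fold)
  pred_ct <- pred_ipt <- numeric(n)
  for (f in seq_len(k)) {
    test <- fold == f
    train <- !test
    if (length(unique(arm01[train])) < 2)
      stop("training split lost an arm; lower k")
    m <- fit_final_model(y[train], arm01[train], Z[train, , drop = FALSE],
                         predictors, moderators, include_arm_main)
    pred_ct[test] <- predict_final(m, Z[test, , drop = FALSE],
                                   rep(0, sum(test)))
    pred_ipt[test] <- predict_final(m, Z[test, , drop = FALSE],
                                    rep(1, sum(test)))
  }
  pai <- pred_ct - pred_ipt
  tab <- data.frame(
    id = id, arm = factor(ifelse(arm01 == 1, "IPT", "CT"),
                          levels = c("CT", "IPT")),
    fold = fold, pred_ct = pred_ct, pred_ipt = pred_ipt,
    factual = ifelse(arm01 == 1, pred_ipt, pred_ct),
    counterfactual = ifelse(arm01 == 1, pred_ct, pred_ipt),
    pai_signed = pai, pai_abs = abs(pai),
    pai_percentile = rank(abs(pai)) / n,
    indicated = ifelse(pai == 0, "none", ifelse(pai < 0, "CT", "IPT")))
  class(tab) <- c("pai_table", "data.frame")
  tab
}

#' Johnson-Neyman region for a moderator
#'
#' Finds the moderator values at which the between-arm difference
#' delta(m) = beta_arm* + beta_int * m is significant at level `alpha`,
#' where beta_arm* folds the other moderators' interactions in at their
#' sample means. Boundaries are the real roots of
#' delta(m)^2 = t^2 * SE(m)^2 (a quadratic in m); the returned regions are
#' clipped to the observed moderator range and annotated with the favored
#' arm (delta > 0 means higher outcomes under IPT, so CT is favored).
#'
#' @param model a [fit_final_model()] containing the moderator.
#' @param moderator moderator name.
#' @param alpha two-sided significance level (default 0.05).
#' @return list of class `pai_jn`: `regions` (data.frame lower/upper/
#'   favored), `boundaries` (real roots inside the range), `range`.
#' @export
johnson_neyman <- function(model, moderator, alpha = 0.05) {
  stopifnot(inherits(model, "pai_final_model"),
            moderator %in% model$moderators)
  if (!model$include_arm_main)
    stop("Johnson-Neyman probing needs the arm main effect in the model")
  cn <- names(model$coef)
  u <- stats::setNames(numeric(length(cn)), cn)   # combo for delta intercept
  u["arm"] <- 1
  for (v in setdiff(model$moderators, moderator))
    u[paste0(v, ":arm")] <- model$moderator_means[v]
  v_ <- stats::setNames(numeric(length(cn)), cn)  # combo for delta slope
  v_[paste0(moderator, ":arm")] <- 1
  A <- sum(u * model$coef)
  B <- sum(v_ * model$coef)
  Vaa <- drop(t(u) %*% model$vcov %*% u)
  Vai <- drop(t(u) %*% model$vcov %*% v_)
  Vii <- drop(t(v_) %*% model$vcov %*% v_)
  tc2 <- stats::qt(1 - alpha / 2, df = model$df_residual)^2
  # delta(m)^2 - t^2 SE(m)^2 = a m^2 + b m + c
  a <- B^2 - tc2 * Vii
  b <- 2 * (A * B - tc2 * Vai)
  cc <- A^2 - tc2 * Vaa
  rng <- model$moderator_range[, moderator]
  roots <- if (abs(a) < 1e-300) {
    if (abs(b) > 0) -cc / b else numeric()
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) numeric() else sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a))
  }
  sig_at <- function(m) (A + B * m)^2 - tc2 * (Vaa + 2 * m * Vai + m^2 * Vii) > 0
  pts <- sort(unique(c(rng[1], roots[roots > rng[1] & roots < rng[2]],
                       rng[2])))
  regions <- NULL
  for (i in seq_len(length(pts) - 1)) {
    mid <- (pts[i] + pts[i + 1]) / 2
    if (sig_at(mid)) {
      fav <- if (A + B * mid > 0) "CT" else "IPT"
      regions <- rbind(regions, data.frame(lower = pts[i], upper = pts[i + 1],
                                           favored = fav))
    }
  }
  structure(list(regions = regions %||%
                   data.frame(lower = numeric(), upper = numeric(),
                              favored = character()),
                 boundaries = roots[roots > rng[1] & roots < rng[2]],
                 range = rng, moderator = moderator, alpha = alpha,
                 delta = c(intercept = A, slope = B)),
            class = "pai_jn")
}

#' @export
print.pai_jn <- function(x, ...) {
  cat(sprintf("<pai_jn> moderator '%s', alpha = %.3g\n", x$moderator,
              x$alpha))
  if (nrow(x$regions) == 0) cat("no significant region in observed range\n")
  else print(x$regions, row.names = FALSE, digits = 4)
  invisible(x)
}
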