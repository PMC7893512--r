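# End-to-end orchestration of the primary analysis: imputation, outcome
# construction, screening/transforms, two-step variable selection, final
# model, cross-validated PAI scores and evaluation.

#' Pipeline configuration
#'
#' Defaults follow the primary analysis settings: a 10000-tree MOB forest
#' with splitting alpha 0.10 and minimum subgroup size 15, 1000 bootstrap
#' resamples with elimination alpha 0.05 and a 60% robustness threshold,
#' fivefold cross-validation. Scale `n_trees`/`n_boot` down for simulation
#' studies.
#'
#' @param n_trees MOB forest size.
#' @param alpha_split,min_node,mtry,bonferroni see [mob_config()].
#' @param n_boot,alpha,freq_threshold see [bootstrap_selection()].
#' @param k_folds folds for the PAI cross-validation.
#' @param impute_trees trees per imputation forest.
#' @param prune_threshold collinearity pruning threshold (|r| > 0.70).
#' @param skew_threshold see [fit_transforms()].
#' @param seed master seed; stage seeds are derived from it.
#' @return list of class `pai_config`.
#' @export
pai_config <- function(n_trees = 10000, alpha_split = 0.10, min_node = 15,
                       mtry = NULL, bonferroni = TRUE, n_boot = 1000,
                       alpha = 0.05, freq_threshold = 0.60, k_folds = 5,
                       impute_trees = 100, prune_threshold = 0.70,
                       skew_threshold = 1, seed = 1L) {
  structure(as.list(environment()), class = "pai_config")
}

# selection stages shared by the primary pipeline and nested validation:
# returns predictors/moderators plus the stage reports
select_variables <- function(y, arm01, Z, kinds, config, seed) {
  mobc <- mob_config(n_trees = config$n_trees,
                     alpha_split = config$alpha_split,
                     min_node = config$min_node, mtry = config$mtry,
                     bonferroni = config$bonferroni, seed = seed)
  forest <- mob_forest(y, arm01, Z, kinds = kinds, config = mobc)
  imp <- importance(forest, seed = seed + 1L)
  if (!length(imp$selected))
    return(list(importance = imp, bootstrap = NULL,
                predictors = character(), moderators = character()))
  boot <- bootstrap_selection(y, arm01, Z, imp$selected,
                              n_boot = config$n_boot, alpha = config$alpha,
                              freq_threshold = config$freq_threshold,
                              seed = seed + 2L)
  list(importance = imp, bootstrap = boot,
       predictors = boot$predictors, moderators = boot$moderators)
}

#' Run the full PAI analysis on a trial dataset
#'
#' Steps: (1) random-forest imputation of missing covariates and outcomes;
#' (2) spline-AUC outcome with baseline residualization; (3) collinearity
#' pruning and variable transformation; (4) stage-1 MOB-forest importance
#' screening; (5) stage-2 bootstrap backward elimination; (6) final
#' moderated regression with Johnson-Neyman probing of each moderator;
#' (7) fivefold cross-validated PAI scores; (8) evaluation contrasts on the
#' average-BDI scale.
#'
#' @param trial a `pai_trial`.
#' @param config a [pai_config()].
#' @return list of class `pai_analysis` with elements `trial` (completed),
#'   `imputation`, `outcomes`, `screening`, `transforms`, `selection`,
#'   `model`, `johnson_neyman`, `pai`, `evaluation`, `config`.
#' @export
run_pai_pipeline <- function(trial, config = pai_config()) {
  seed <- config$seed
  imputation <- NULL
  if (anyNA(trial$outcomes) || anyNA(as.matrix(trial$covariates))) {
    imp <- impute_trial(trial, n_trees = config$impute_trees, seed = seed)
    trial <- imp$trial
    imputation <- imp$imputation
  }
  outcomes <- compute_outcomes(trial)
  y <- outcomes$auc_residual
  arm01 <- as.integer(trial$arm == "IPT")

  kinds <- trial$covariate_meta$kind
  transforms <- fit_transforms(trial$covariates, kinds,
                               skew_threshold = config$skew_threshold)
  Zt <- as.matrix(apply_transforms(trial$covariates, transforms))
  corr <- attenuation_corrected_corr(Zt)
  screening <- prune_collinear(corr, threshold = config$prune_threshold,
                               outcome_corr = drop(stats::cor(Zt, y)[, 1]))
  Zt <- Zt[, screening$retained, drop = FALSE]
  kinds <- kinds[match(screening$retained, trial$covariate_meta$name)]

  selection <- select_variables(y, arm01, Zt, kinds, config, seed + 10L)

  model <- fit_final_model(y, arm01, Zt, selection$predictors,
                           selection$moderators)
  jn <- lapply(selection$moderators, function(v) {
    r <- johnson_neyman(model, v)
    # report boundaries on the raw covariate scale as well
    r$boundaries_raw <- vapply(r$boundaries, untransform_value, 0,
                               r = transforms[[v]])
    r
  })
  names(jn) <- selection$moderators

  pai <- crossval_predict(y, arm01, Zt, selection$predictors,
                          selection$moderators, id = trial$id,
                          k = config$k_folds, seed = seed + 20L)
  evaluation <- evaluate_pai(pai, outcomes$avg_bdi)

  structure(list(trial = trial, imputation = imputation,
                 outcomes = outcomes, screening = screening,
                 transforms = transforms, selection = selection,
                 model = model, johnson_neyman = jn, pai = pai,
                 evaluation = evaluation, config = config),
            class = "pai_analysis")
}

#' @export
print.pai_analysis <- function(x, ...) {
  cat("<pai_analysis>\n")
  cat("  predictors:", paste(x$selection$predictors, collapse = ", "), "\n")
  cat("  moderators:", paste(x$selection$moderators, collapse = ", "), "\n")
  cat(sprintf("  indicated CT: %d, IPT: %d, none: %d\n",
              sum(x$pai$indicated == "CT"), sum(x$pai$indicated == "IPT"),
              sum(x$pai$indicated == "none")))
  print(x$evaluation)
  invisible(x)
}

#' Write the PAI table to CSV
#' @param pai a `pai_table`.
#' @param file path.
#' @export
write_pai_csv <- function(pai, file) {
  utils::write.csv(as.data.frame(pai), file, row.names = FALSE)
  invisible(file)
}
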