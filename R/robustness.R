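# Nested fivefold validation: the whole screening-to-model chain is
# repeated inside training folds, so held-out PAI predictions are never
# touched by the variable selection that produced their model ("no
# double-dipping").

#' Nested k-fold validation of the PAI pipeline
#'
#' Partitions participants into `k` folds (stratified by arm, on a seed
#' stream separate from the primary cross-validation). For each fold, the
#' baseline residualization, variable transformations, stage-1 forest,
#' stage-2 bootstrap elimination and final model are all fitted on the
#' training folds only; the held-out participants are then predicted under
#' both arms. The pooled held-out table is evaluated like the primary one
#' and compared against a primary-mode PAI table when supplied.
#'
#' @param trial a completed (fully observed) `pai_trial`; imputation is a
#'   data-preparation step that precedes nesting by default.
#' @param config a [pai_config()]; inside folds `n_trees` is typically
#'   scaled down (default here 2000).
#' @param k number of outer folds (default 5).
#' @param seed fold-assignment seed.
#' @param primary optional primary-mode `pai_table` for the comparison.
#' @param forced_selection optional list(predictors=, moderators=) to skip
#'   the selection stages in every fold (oracle mode for calibration
#'   checks).
#' @return list of class `pai_nested`: `pai` (pooled held-out table),
#'   `evaluation`, `fold_selections`, `fold_assignments`, `comparison`
#'   (vs `primary`), `leakage_audit`.
#' @export
nested_validate <- function(trial, config = pai_config(n_trees = 2000),
                            k = 5, seed = 1L, primary = NULL,
                            forced_selection = NULL) {
  if (anyNA(trial$outcomes) || anyNA(as.matrix(trial$covariates)))
    stop("nested validation expects a completed dataset; impute first")
  n <- length(trial$id)
  arm01 <- as.integer(trial$arm == "IPT")
  sched <- trial$schedule_months
  span <- diff(range(sched))
  auc_raw <- apply(trial$outcomes, 1,
                   function(v) spline_auc(sched, v, method = "natural"))
  fold <- with_private_seed(seed, make_folds(arm01, k))

  rows <- vector("list", k)
  fold_selections <- vector("list", k)
  audit <- logical(k)
  for (f in seq_len(k)) {
    test <- which(fold == f)
    train <- which(fold != f)
    audit[f] <- length(intersect(train, test)) == 0
    res_fit <- fit_residualizer(auc_raw[train], trial$baseline_bdi[train])
    y_train <- apply_residualizer(res_fit, auc_raw[train],
                                  trial$baseline_bdi[train])
    kinds <- trial$covariate_meta$kind
    tr <- fit_transforms(trial$covariates[train, , drop = FALSE], kinds,
                         skew_threshold = config$skew_threshold)
    Zt <- as.matrix(apply_transforms(trial$covariates, tr))
    sel <- if (!is.null(forced_selection)) forced_selection
    else select_variables(y_train, arm01[train],
                          Zt[train, , drop = FALSE], kinds, config,
                          seed = config$seed + 100L * f)
    fold_selections[[f]] <- list(predictors = sel$predictors,
                                 moderators = sel$moderators)
    model <- fit_final_model(y_train, arm01[train],
                             Zt[train, , drop = FALSE],
                             sel$predictors, sel$moderators)
    pc <- predict_final(model, Zt[test, , drop = FALSE],
                        rep(0, length(test)))
    pi_ <- predict_final(model, Zt[test, , drop = FALSE],
                         rep(1, length(test)))
    rows[[f]] <- data.frame(id = trial$id[test],
                            arm = as.character(trial$arm[test]),
                            fold = f, pred_ct = pc, pred_ipt = pi_)
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$id), ]
  arm01_tab <- as.integer(tab$arm == "IPT")
  pai <- tab$pred_ct - tab$pred_ipt
  out <- data.frame(id = tab$id,
                    arm = factor(tab$arm, levels = c("CT", "IPT")),
                    fold = tab$fold, pred_ct = tab$pred_ct,
                    pred_ipt = tab$pred_ipt,
                    factual = ifelse(arm01_tab == 1, tab$pred_ipt,
                                     tab$pred_ct),
                    counterfactual = ifelse(arm01_tab == 1, tab$pred_ct,
                                            tab$pred_ipt),
                    pai_signed = pai, pai_abs = abs(pai),
                    pai_percentile = rank(abs(pai)) / length(pai),
                    indicated = ifelse(pai == 0, "none",
                                       ifelse(pai < 0, "CT", "IPT")))
  class(out) <- c("pai_table", "data.frame")
  avg_bdi <- to_average_bdi(auc_raw, span)[match(out$id, trial$id)]
  evaluation <- evaluate_pai(out, avg_bdi)
  comparison <- if (!is.null(primary) &&
                    stats::sd(out$pai_signed) > 0 &&
                    stats::sd(primary$pai_signed) > 0)
    compare_pai_sets(out, primary) else NULL
  structure(list(pai = out, evaluation = evaluation,
                 fold_selections = fold_selections,
                 fold_assignments = fold,
                 comparison = comparison,
                 leakage_audit = all(audit)),
            class = "pai_nested")
}
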