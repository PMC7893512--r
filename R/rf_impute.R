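# Iterative random-forest imputation (missForest scheme) for missing
# covariates and outcomes, with masking-based accuracy validation. The
# iteration loop is implemented here; the per-column forests are fitted with
# ranger.

#' Assemble the imputation feature matrix for a trial
#'
#' Columns are: change-from-baseline scores of every follow-up BDI-II
#' measurement (month 3 and the scheduled months), all baseline covariates,
#' and the received treatment arm. A `manifest` attribute records each
#' column's provenance so imputed change scores can be mapped back to BDI-II
#' values.
#'
#' @param trial a `pai_trial`; baseline BDI-II must be complete.
#' @return data.frame (binary/categorical covariates as factors) with
#'   attribute `manifest`.
#' @export
assemble_imputation_features <- function(trial) {
  if (anyNA(trial$baseline_bdi))
    stop("baseline BDI-II must be observed for every participant")
  chg <- trial$outcomes - trial$baseline_bdi
  colnames(chg) <- paste0("chg_m", trial$schedule_months)
  feats <- as.data.frame(chg)
  manifest <- data.frame(column = colnames(chg), source = "outcome_change",
                         stringsAsFactors = FALSE)
  if (!is.null(trial$bdi_m3)) {
    feats <- cbind(chg_m3 = trial$bdi_m3 - trial$baseline_bdi, feats)
    manifest <- rbind(data.frame(column = "chg_m3", source = "outcome_change"),
                      manifest)
  }
  for (j in seq_len(nrow(trial$covariate_meta))) {
    nm <- trial$covariate_meta$name[j]
    v <- trial$covariates[[nm]]
    if (trial$covariate_meta$kind[j] %in% c("binary", "categorical"))
      v <- factor(v)
    feats[[nm]] <- v
    manifest <- rbind(manifest, data.frame(column = nm, source = "covariate"))
  }
  feats$arm <- trial$arm
  manifest <- rbind(manifest, data.frame(column = "arm", source = "treatment"))
  attr(feats, "manifest") <- manifest
  feats
}

#' Iterative random-forest imputation
#'
#' missForest algorithm: initialize missing cells with the column
#' mean/mode, then sweep the columns in order of increasing missingness,
#' fitting a random forest of each column on all others (observed rows
#' only) and predicting its missing rows. Sweeps repeat until the
#' normalized change in the imputed values first increases (continuous:
#' normalized squared change; categorical: fraction changed), at which point
#' the previous sweep's matrix is returned, or until `max_iter`.
#'
#' @param x data.frame with NA cells; factors are imputed by classification
#'   forests, numeric columns by regression forests.
#' @param n_trees trees per forest (default 100).
#' @param max_iter maximum sweeps (default 10).
#' @param mtry variables tried per split; default floor(sqrt(p)).
#' @param seed RNG seed (forests are seeded deterministically from it).
#' @return list of class `pai_imputation`: `completed`, `n_iter`,
#'   `diffs` (per-sweep difference statistics), `converged`.
#' @export
missforest_impute <- function(x, n_trees = 100, max_iter = 10,
                              mtry = NULL, seed = 1L) {
  x <- as.data.frame(x)
  p <- ncol(x)
  miss <- is.na(x)
  if (any(colSums(!miss) == 0)) stop("column with no observed values")
  if (any(rowSums(!miss) == 0)) stop("row with no observed values")
  num <- vapply(x, is.numeric, TRUE)
  if (any(vapply(x[num], function(v) any(!is.finite(v[!is.na(v)])), TRUE)))
    stop("non-finite observed values")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))

  ximp <- x
  for (j in seq_len(p)) {
    mj <- miss[, j]
    if (!any(mj)) next
    ximp[[j]][mj] <- if (num[j]) mean(x[[j]], na.rm = TRUE) else {
      tab <- table(x[[j]])
      factor(names(tab)[which.max(tab)], levels = levels(x[[j]]))
    }
  }
  cols <- order(colSums(miss))
  cols <- cols[colSums(miss)[cols] > 0]
  if (!length(cols))
    return(structure(list(completed = ximp, n_iter = 1L,
                          diffs = data.frame(continuous = NA, categorical = NA),
                          converged = TRUE), class = "pai_imputation"))

  num_miss <- intersect(which(num), cols)
  cat_miss <- setdiff(cols, num_miss)
  diff_cont_prev <- diff_cat_prev <- Inf
  diffs <- NULL
  converged <- FALSE
  iter <- 0L
  # classification forests may break prediction-vote ties through the R
  # RNG; pin the whole sweep loop to a private seeded stream so the cycle
  # is reproducible
  with_private_seed(seed, while (iter < max_iter) {
    iter <- iter + 1L
    old <- ximp
    for (j in cols) {
      mj <- miss[, j]
      fit <- ranger::ranger(
        x = ximp[!mj, -j, drop = FALSE], y = ximp[[j]][!mj],
        num.trees = n_trees, mtry = min(mtry, p - 1L),
        seed = seed + iter * 1000L + j,
        num.threads = 1L, verbose = FALSE)
      pred <- stats::predict(fit, data = ximp[mj, -j, drop = FALSE],
                             num.threads = 1L)$predictions
      ximp[[j]][mj] <- pred
    }
    diff_cont <- if (length(num_miss)) {
      newv <- unlist(ximp[num_miss]); oldv <- unlist(old[num_miss])
      sum((newv - oldv)^2) / max(sum(newv^2), .Machine$double.eps)
    } else NA_real_
    diff_cat <- if (length(cat_miss)) {
      ch <- 0; tot <- 0
      for (j in cat_miss) {
        mj <- miss[, j]
        ch <- ch + sum(ximp[[j]][mj] != old[[j]][mj]); tot <- tot + sum(mj)
      }
      ch / tot
    } else NA_real_
    diffs <- rbind(diffs, data.frame(continuous = diff_cont,
                                     categorical = diff_cat))
    worse_cont <- is.na(diff_cont) || diff_cont > diff_cont_prev
    worse_cat <- is.na(diff_cat) || diff_cat > diff_cat_prev
    if (worse_cont && worse_cat) {
      ximp <- old                       # standard missForest stopping:
      converged <- TRUE                 # return the previous sweep
      break
    }
    still_cont <- is.na(diff_cont) || diff_cont <= 1e-12
    still_cat <- is.na(diff_cat) || diff_cat == 0
    if (still_cont && still_cat) {      # imputations stopped changing
      converged <- TRUE
      break
    }
    diff_cont_prev <- diff_cont
    diff_cat_prev <- diff_cat
  })
  structure(list(completed = ximp, n_iter = iter, diffs = diffs,
                 converged = converged), class = "pai_imputation")
}

#' Impute a trial dataset
#'
#' Runs [assemble_imputation_features()] + [missforest_impute()] and maps
#' the completed feature matrix back onto the trial: imputed change scores
#' become BDI-II values (baseline + change, clipped to [0, 63]), count
#' covariates are rounded to the nearest admissible value, and binary
#' covariates come back from the classification forests.
#'
#' @param trial a `pai_trial`.
#' @inheritParams missforest_impute
#' @return list: `trial` (completed), `imputation` (the `pai_imputation`).
#' @export
impute_trial <- function(trial, n_trees = 100, max_iter = 10, seed = 1L) {
  feats <- assemble_imputation_features(trial)
  res <- missforest_impute(feats, n_trees = n_trees, max_iter = max_iter,
                           seed = seed)
  comp <- res$completed
  out <- trial
  for (m in trial$schedule_months) {
    col <- paste0("chg_m", m)
    filled <- clip(round(comp[[col]] + trial$baseline_bdi), 0, 63)
    obs <- !is.na(trial$outcomes[, paste0("bdi_m", m)])
    out$outcomes[!obs, paste0("bdi_m", m)] <- filled[!obs]
  }
  for (j in seq_len(nrow(trial$covariate_meta))) {
    nm <- trial$covariate_meta$name[j]
    kind <- trial$covariate_meta$kind[j]
    v <- comp[[nm]]
    if (is.factor(v)) v <- as.numeric(as.character(v))
    if (kind == "count") v <- pmax(round(v), 0)
    obs <- !is.na(trial$covariates[[nm]])
    out$covariates[[nm]][!obs] <- v[!obs]
  }
  list(trial = out, imputation = res)
}

#' Validate imputation accuracy by masking observed data
#'
#' Masks cells of a fully observed matrix at the given rate, imputes, and
#' scores the imputations against the held-back truth: NRMSE =
#' sqrt(mean((true - imputed)^2) / var(true)) over masked continuous cells,
#' PFC = misclassified fraction over masked categorical cells.
#'
#' @param x fully observed data.frame (factors = categorical).
#' @param rate masking rate in (0, 1).
#' @param seed RNG seed for the mask and the forests.
#' @param imputer function(data.frame with NAs) -> completed data.frame;
#'   defaults to [missforest_impute()]. Swap in alternatives (column-mean,
#'   truth oracle) for baseline comparisons.
#' @param ... passed on to the default imputer.
#' @return list of class `pai_imputation_accuracy`: `nrmse`, `pfc`,
#'   `n_masked_continuous`, `n_masked_categorical`, `rate`, `seed`.
#' @export
validate_imputation <- function(x, rate, seed = 1L, imputer = NULL, ...) {
  x <- as.data.frame(x)
  if (anyNA(x)) stop("validation input must be fully observed")
  if (rate <= 0 || rate >= 1) stop("rate must lie in (0, 1)")
  n <- nrow(x); p <- ncol(x)
  masked <- with_private_seed(seed, {
    m <- matrix(stats::runif(n * p) < rate, n, p)
    # keep every row and column identifiable
    for (i in which(rowSums(!m) == 0)) m[i, sample.int(p, 1)] <- FALSE
    for (j in which(colSums(!m) == 0)) m[sample.int(n, 1), j] <- FALSE
    m
  })
  xm <- x
  for (j in seq_len(p)) xm[[j]][masked[, j]] <- NA
  completed <- if (is.null(imputer))
    missforest_impute(xm, seed = seed, ...)$completed else imputer(xm)
  num <- vapply(x, is.numeric, TRUE)
  err2 <- truth2 <- c()
  mis <- tot <- 0L
  for (j in seq_len(p)) {
    mj <- masked[, j]
    if (!any(mj)) next
    if (num[j]) {
      err2 <- c(err2, (x[[j]][mj] - completed[[j]][mj])^2)
      truth2 <- c(truth2, x[[j]][mj])
    } else {
      mis <- mis + sum(as.character(x[[j]][mj]) !=
                         as.character(completed[[j]][mj]))
      tot <- tot + sum(mj)
    }
  }
  nrmse <- if (length(err2) > 1 && stats::var(truth2) > 0)
    sqrt(mean(err2) / stats::var(truth2)) else NA_real_
  pfc <- if (tot > 0) mis / tot else NA_real_
  structure(list(nrmse = nrmse, pfc = pfc,
                 n_masked_continuous = length(err2),
                 n_masked_categorical = tot, rate = rate, seed = seed),
            class = "pai_imputation_accuracy")
}

#' Column-mean/mode imputer (baseline for accuracy comparisons)
#' @param x data.frame with NA cells.
#' @return completed data.frame.
#' @export
mean_impute <- function(x) {
  for (j in seq_len(ncol(x))) {
    mj <- is.na(x[[j]])
    if (!any(mj)) next
    x[[j]][mj] <- if (is.numeric(x[[j]])) mean(x[[j]], na.rm = TRUE) else {
      tab <- table(x[[j]])
      factor(names(tab)[which.max(tab)], levels = levels(x[[j]]))
    }
  }
  x
}
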