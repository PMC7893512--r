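# Stage-2 variable selection: bootstrap backward elimination with
# selection-frequency and coefficient-sign accounting, and classification of
# survivors as predictors versus moderators.

# build the stage-2 design matrix: intercept, arm, main effects of the
# stage-1 variables, and their arm interactions
stage2_design <- function(Z, arm01, vars) {
  X <- cbind(`(Intercept)` = rep(1, length(arm01)), arm = arm01)
  for (v in vars) {
    X <- cbind(X, Z[, v])
    colnames(X)[ncol(X)] <- v
  }
  for (v in vars) {
    X <- cbind(X, Z[, v] * arm01)
    colnames(X)[ncol(X)] <- paste0(v, ":arm")
  }
  X
}

#' Backward elimination honoring marginality
#'
#' Starting from `outcome ~ arm + main effects + arm interactions`,
#' iteratively refits and drops the eliminable term with the largest
#' p-value above `alpha`, until every eliminable term is significant. A main
#' effect is not eliminable while its interaction remains, and the arm main
#' effect is never dropped while any interaction remains. Aliased (rank
#' deficient) terms are dropped first.
#'
#' @param y outcome.
#' @param arm01 0/1 arm indicator.
#' @param Z covariate matrix (transformed scale).
#' @param vars stage-1 variable names.
#' @param alpha elimination level (default 0.05).
#' @return list: `terms` (surviving term labels, excluding the intercept),
#'   `coef` (their coefficients), `dropped` (in elimination order).
#' @export
backward_eliminate <- function(y, arm01, Z, vars, alpha = 0.05) {
  X <- stage2_design(as.matrix(Z), arm01, vars)
  terms <- setdiff(colnames(X), "(Intercept)")
  dropped <- character()
  repeat {
    fit <- fast_ols(X[, c("(Intercept)", terms), drop = FALSE], y)
    if (any(fit$aliased)) {
      al <- setdiff(names(fit$coef)[fit$aliased], "(Intercept)")
      dropped <- c(dropped, al)
      terms <- setdiff(terms, al)
      next
    }
    ints <- grep(":arm$", terms, value = TRUE)
    prot <- c(sub(":arm$", "", ints), if (length(ints)) "arm")
    elig <- setdiff(terms, prot)
    if (!length(elig)) break
    pv <- fit$pval[elig]
    worst <- elig[which.max(pv)]
    if (pv[worst] <= alpha) break
    dropped <- c(dropped, worst)
    terms <- setdiff(terms, worst)
  }
  fit <- fast_ols(X[, c("(Intercept)", terms), drop = FALSE], y)
  list(terms = terms, coef = fit$coef[terms], dropped = dropped)
}

#' Bootstrap stability selection by backward elimination
#'
#' Draws `n_boot` bootstrap resamples (with replacement, original size),
#' runs [backward_eliminate()] on each, and tallies, per term, the selection
#' frequency and the sign split of its coefficient among selections. Terms
#' selected in at least `freq_threshold` of the resamples form the robust
#' set; a variable whose arm interaction is robust is classified as a
#' moderator, one whose main effect alone is robust as a predictor.
#'
#' @inheritParams backward_eliminate
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param freq_threshold robustness threshold on the selection frequency
#'   (default 0.60).
#' @param seed RNG seed.
#' @return list of class `pai_boot_selection`: `table` (term, frequency,
#'   positive/negative sign fractions, robust flag, role), `predictors`,
#'   `moderators`, `n_boot`, `n_redrawn`.
#' @export
bootstrap_selection <- function(y, arm01, Z, vars, n_boot = 1000,
                                alpha = 0.05, freq_threshold = 0.60,
                                seed = 1L) {
  if (!length(vars)) stop("stage-1 variable set is empty")
  Z <- as.matrix(Z)
  n <- length(y)
  all_terms <- c("arm", vars, paste0(vars, ":arm"))
  sel <- pos <- stats::setNames(numeric(length(all_terms)), all_terms)
  n_redrawn <- 0L
  with_private_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        rows <- sample.int(n, n, replace = TRUE)
        if (length(unique(arm01[rows])) == 2) break
        n_redrawn <- n_redrawn + 1L
      }
      res <- backward_eliminate(y[rows], arm01[rows],
                                Z[rows, , drop = FALSE], vars, alpha = alpha)
      sel[res$terms] <- sel[res$terms] + 1
      up <- res$terms[res$coef > 0]
      pos[up] <- pos[up] + 1
    }
  })
  freq <- sel / n_boot
  tab <- data.frame(term = all_terms, frequency = freq,
                    positive_fraction = ifelse(sel > 0, pos / sel, NA),
                    negative_fraction = ifelse(sel > 0, 1 - pos / sel, NA),
                    robust = freq >= freq_threshold,
                    stringsAsFactors = FALSE, row.names = NULL)
  robust_terms <- tab$term[tab$robust]
  moderators <- sub(":arm$", "",
                    grep(":arm$", robust_terms, value = TRUE))
  predictors <- setdiff(intersect(robust_terms, vars), moderators)
  tab$role <- ifelse(tab$term %in% paste0(moderators, ":arm"), "moderator",
                     ifelse(tab$term %in% predictors, "predictor", ""))
  structure(list(table = tab, predictors = predictors,
                 moderators = moderators, n_boot = n_boot,
                 freq_threshold = freq_threshold, n_redrawn = n_redrawn),
            class = "pai_boot_selection")
}

#' @export
print.pai_boot_selection <- function(x, ...) {
  cat(sprintf("<pai_boot_selection> %d resamples, threshold %.0f%%\n",
              x$n_boot, 100 * x$freq_threshold))
  cat("predictors:", paste(x$predictors, collapse = ", ") %||% "", "\n")
  cat("moderators:", paste(x$moderators, collapse = ", ") %||% "", "\n")
  print(x$table[order(-x$table$frequency), ], row.names = FALSE, digits = 3)
  invisible(x)
}
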