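# Stage-1 variable selection: a forest of MOB trees over bootstrap samples,
# out-of-bag permutation importance, and the lowest-rank threshold rule.

#' Fit a forest of model-based recursive-partitioning trees
#'
#' Each tree is grown on a bootstrap sample with a random subset of `mtry`
#' candidate covariates (drawn per tree), so weaker moderators are not
#' always dominated by stronger ones.
#'
#' @param y outcomes (the residualized AUC in the primary analysis).
#' @param arm01 0/1 arm indicator (CT = 0, IPT = 1).
#' @param Z numeric covariate matrix with column names.
#' @param kinds per-column kinds ("continuous", "count", "binary", ...).
#' @param config a [mob_config()].
#' @return list of class `pai_mob_forest` holding the trees, their
#'   candidate sets and out-of-bag row indices.
#' @export
mob_forest <- function(y, arm01, Z, kinds = NULL, config = mob_config()) {
  Z <- as.matrix(Z)
  n <- length(y)
  p <- ncol(Z)
  if (is.null(kinds)) kinds <- rep("continuous", p)
  mtry <- config$mtry %||% max(1L, floor(sqrt(p)))
  stopifnot(mtry >= 1, mtry <= p)
  trees <- vector("list", config$n_trees)
  oob <- vector("list", config$n_trees)
  with_private_seed(config$seed, {
    for (t in seq_len(config$n_trees)) {
      rows <- if (config$bootstrap) sample.int(n, n, replace = TRUE)
      else seq_len(n)
      cands <- sort(sample.int(p, mtry))
      trees[[t]] <- grow_tree(y[rows], arm01[rows], Z[rows, , drop = FALSE],
                              candidates = cands, kinds = kinds,
                              config = config)
      oob[[t]] <- setdiff(seq_len(n), unique(rows))
    }
  })
  structure(list(trees = trees, oob = oob, y = y, arm01 = arm01, Z = Z,
                 kinds = kinds, config = config,
                 var_names = colnames(Z) %||% paste0("V", seq_len(p))),
            class = "pai_mob_forest")
}

#' Out-of-bag permutation importance and the threshold selection rule
#'
#' For each covariate, importance is the mean (over trees in which the
#' covariate was a candidate) of the out-of-bag mean squared prediction
#' error with that covariate's values randomly permuted minus the error
#' with the real values; larger values indicate covariates whose
#' information the trees actually used. The selection threshold is the
#' absolute value of the importance score of the lowest-ranking covariate,
#' and covariates strictly above it are selected for stage 2.
#'
#' @param forest a [mob_forest()] fit with `bootstrap = TRUE`.
#' @param seed RNG seed for the permutations.
#' @return list of class `pai_importance`: `table` (variable, importance,
#'   n_trees, rank), `threshold`, `selected`.
#' @export
importance <- function(forest, seed = 1L) {
  stopifnot(inherits(forest, "pai_mob_forest"))
  if (!forest$config$bootstrap)
    stop("importance needs out-of-bag sets; refit with bootstrap = TRUE")
  p <- ncol(forest$Z)
  sums <- numeric(p)
  counts <- integer(p)
  with_private_seed(seed, {
    for (t in seq_along(forest$trees)) {
      o <- forest$oob[[t]]
      if (length(o) < 2) next
      tree <- forest$trees[[t]]
      Zo <- forest$Z[o, , drop = FALSE]
      ao <- forest$arm01[o]
      yo <- forest$y[o]
      err0 <- mean((yo - predict(tree, Zo, ao))^2)
      for (v in tree$candidates) {
        Zp <- Zo
        Zp[, v] <- Zp[sample.int(length(o)), v]
        errp <- mean((yo - predict(tree, Zp, ao))^2)
        sums[v] <- sums[v] + (errp - err0)
        counts[v] <- counts[v] + 1L
      }
    }
  })
  imp <- ifelse(counts > 0, sums / pmax(counts, 1), NA_real_)
  tab <- data.frame(variable = forest$var_names, importance = imp,
                    n_trees = counts, stringsAsFactors = FALSE)
  tab <- tab[order(-tab$importance, tab$variable), ]
  tab$rank <- seq_len(nrow(tab))
  defined <- tab$importance[!is.na(tab$importance)]
  threshold <- abs(defined[length(defined)])
  structure(list(table = tab, threshold = threshold,
                 selected = tab$variable[!is.na(tab$importance) &
                                           tab$importance > threshold]),
            class = "pai_importance")
}

#' @export
print.pai_importance <- function(x, ...) {
  cat("<pai_importance> threshold =", signif(x$threshold, 4), "\n")
  cat("selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n")
  print(utils::head(x$table, 10), row.names = FALSE)
  invisible(x)
}
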