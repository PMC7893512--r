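# Model-based recursive partitioning: node treatment-outcome regression,
# score-based parameter-instability tests, and single-tree growth. The node
# model is outcome ~ intercept + arm; a split is made where the fitted
# coefficients are most unstable along a candidate covariate.

#' Configuration for the MOB forest
#'
#' @param n_trees number of trees (default 10000).
#' @param alpha_split significance level for splitting (default 0.10),
#'   applied to the Bonferroni-adjusted minimum instability p-value.
#' @param min_node minimum subgroup (child) size for a split (default 15).
#' @param mtry candidate variables available per tree; default
#'   floor(sqrt(p)).
#' @param bootstrap draw a bootstrap sample per tree (default TRUE; needed
#'   for out-of-bag importance).
#' @param bonferroni adjust instability p-values across the candidates
#'   tested in a node (default TRUE).
#' @param seed RNG seed for the whole forest.
#' @return list of class `pai_mob_config`.
#' @export
mob_config <- function(n_trees = 10000, alpha_split = 0.10, min_node = 15,
                       mtry = NULL, bootstrap = TRUE, bonferroni = TRUE,
                       seed = 1L) {
  stopifnot(alpha_split > 0, alpha_split < 1, min_node >= 2, n_trees >= 1)
  structure(list(n_trees = as.integer(n_trees), alpha_split = alpha_split,
                 min_node = as.integer(min_node), mtry = mtry,
                 bootstrap = bootstrap, bonferroni = bonferroni,
                 seed = as.integer(seed)), class = "pai_mob_config")
}

#' Fit the node treatment-outcome model
#'
#' Least-squares fit of `outcome ~ intercept + arm` in a node, returning the
#' per-observation estimating-function contributions (scores) used by the
#' instability tests. With a 0/1 arm the coefficients are the CT mean and
#' the IPT-minus-CT difference.
#'
#' @param y node outcomes.
#' @param arm01 0/1 arm indicator (CT = 0, IPT = 1).
#' @return list: `coef` (intercept, arm), `scores` (n x 2 matrix of
#'   residual x regressor contributions), `rss`, `ok` (FALSE when the node
#'   holds fewer than 2 observations of either arm, in which case the node
#'   model is the plain mean).
#' @export
fit_node_model <- function(y, arm01) {
  n0 <- sum(arm01 == 0); n1 <- sum(arm01 == 1)
  if (n0 < 2 || n1 < 2) {
    mu <- mean(y)
    r <- y - mu
    return(list(coef = c(intercept = mu, arm = NA_real_),
                scores = cbind(r, r * arm01), rss = sum(r^2), ok = FALSE))
  }
  m0 <- mean(y[arm01 == 0]); m1 <- mean(y[arm01 == 1])
  fitted <- ifelse(arm01 == 1, m1, m0)
  r <- y - fitted
  list(coef = c(intercept = m0, arm = m1 - m0),
       scores = cbind(r, r * arm01), rss = sum(r^2), ok = TRUE)
}

# ---- sup-LM asymptotic null distribution (Monte-Carlo, cached) -----------
#
# The limiting null of the sup-LM statistic over split fractions
# t in [trim, 1 - trim] is sup ||B(t)||^2 / (t (1 - t)) for a k-dimensional
# Brownian bridge B. We simulate the bridge process once on a fixed grid
# under a private seed and cache per (k, trim-range) sorted suprema; a
# p-value is then an empirical tail lookup. The 150-point t-grid matches
# the discreteness of the cut-point sets at the node sizes this pipeline
# targets (n ~ 100-150); 20000 paths give p-resolution 5e-5.
.suplm_cache <- new.env(parent = emptyenv())

suplm_process <- function(k, n_paths = 10000L, n_grid = 150L) {
  key <- sprintf("proc_k%d", k)
  if (!is.null(.suplm_cache[[key]])) return(.suplm_cache[[key]])
  tt <- seq_len(n_grid - 1L) / n_grid
  proc <- with_private_seed(20240901L + k, {
    acc <- matrix(0, n_paths, n_grid - 1L)
    for (d in seq_len(k)) {
      inc <- matrix(stats::rnorm(n_paths * n_grid, sd = sqrt(1 / n_grid)),
                    n_paths, n_grid)
      w <- t(apply(inc, 1, cumsum))
      b <- w[, seq_len(n_grid - 1L), drop = FALSE] -
        outer(w[, n_grid], tt)
      acc <- acc + b^2
    }
    sweep(acc, 2, tt * (1 - tt), "/")
  })
  .suplm_cache[[key]] <- list(proc = proc, tt = tt)
  .suplm_cache[[key]]
}

# p-value of the realized supremum: the reference is the simulated bridge
# process maximized over the grid columns nearest the realized admissible
# cut fractions. Dense cut sets (near-continuous covariates) collapse to
# the full trim range; sparse sets (ties, ordinal covariates) keep their
# exact positions, which keeps the test calibrated under heavy ties.
# Null suprema are summarized by 4096 quantiles and cached under a size
# cap so forests over discrete covariates stay within memory.
suplm_pvalue <- function(stat, k, cut_fractions) {
  n_grid <- 150L
  cols <- unique(sort(clip(round(cut_fractions * n_grid), 1L, n_grid - 1L)))
  ref <- suplm_process(k)
  if (length(cols) > 25) {
    # dense set: collapse to the full range; bounded key space, cached as
    # quantile summaries
    cols <- seq.int(min(cols), max(cols))
    key <- sprintf("q_k%d_%d_%d", k, cols[1], cols[length(cols)])
    qs <- .suplm_cache[[key]]
    if (is.null(qs)) {
      sups <- ref$proc[, cols[1]]
      for (j in cols[-1]) sups <- pmax(sups, ref$proc[, j])
      qs <- stats::quantile(sups, probs = seq(0, 1, length.out = 4097),
                            names = FALSE)
      if (length(ls(.suplm_cache)) < 2000) .suplm_cache[[key]] <- qs
    }
    pos <- findInterval(stat, qs)
    return(max(1 - pos / 4097, 1 / 4098))
  }
  # sparse set (heavy ties): unbounded key space, so evaluate directly on a
  # fixed subsample of paths instead of caching
  m <- min(5000L, nrow(ref$proc))
  sups <- ref$proc[seq_len(m), cols[1]]
  for (j in cols[-1]) sups <- pmax(sups, ref$proc[seq_len(m), j])
  (1 + sum(sups >= stat)) / (m + 1)
}

#' Parameter-instability test of the node model along one covariate
#'
#' Ordered (continuous/count) covariates: sup-LM statistic of the cumulative
#' score process on the covariate's sort order, with the supremum restricted
#' to admissible split fractions (both sides >= `min_node`); the p-value
#' comes from the simulated asymptotic Brownian-bridge reference.
#' Categorical/binary covariates: chi-square test on per-category score
#' sums with k(C-1) degrees of freedom.
#'
#' @param scores n x k matrix of per-observation estimating functions.
#' @param z the candidate partitioning covariate.
#' @param min_node minimum admissible child size.
#' @param categorical treat `z` as unordered categories.
#' @return p-value (1 for constant `z` or degenerate scores).
#' @export
instability_test <- function(scores, z, min_node = 15, categorical = FALSE) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  k <- ncol(scores)
  if (length(unique(z)) < 2) return(1)
  J <- crossprod(scores) / n
  Jinv <- tryCatch(solve(J), error = function(e) NULL)
  if (is.null(Jinv)) return(1)
  if (categorical) {
    lev <- unique(z)
    stat <- 0
    for (l in lev) {
      sel <- z == l
      s <- colSums(scores[sel, , drop = FALSE])
      stat <- stat + drop(t(s) %*% Jinv %*% s) / sum(sel)
    }
    return(stats::pchisq(stat, df = k * (length(lev) - 1),
                         lower.tail = FALSE))
  }
  ord <- order(z)
  zs <- z[ord]
  S <- apply(scores[ord, , drop = FALSE], 2, cumsum)
  cut <- seq_len(n - 1L)
  ok <- cut >= min_node & cut <= n - min_node & zs[cut] < zs[cut + 1L]
  if (!any(ok)) return(1)
  tt <- cut[ok] / n
  Sk <- S[cut[ok], , drop = FALSE]
  lm_stat <- rowSums((Sk %*% Jinv) * Sk) / n / (tt * (1 - tt))
  suplm_pvalue(max(lm_stat), k = k, cut_fractions = tt)
}

# best split point of y ~ arm on covariate z: minimizes the sum of the two
# children's node-model RSS (within-arm sums of squares), both children
# >= min_node; ties broken by the smaller split value
best_split <- function(y, arm01, z, min_node) {
  n <- length(y)
  ord <- order(z)
  zs <- z[ord]; ys <- y[ord]; as <- arm01[ord]
  cut <- seq_len(n - 1L)
  ok <- cut >= min_node & cut <= n - min_node & zs[cut] < zs[cut + 1L]
  if (!any(ok)) return(NULL)
  rss_sides <- function(ind) {           # ind: 1 for this arm
    s <- cumsum(ys * ind); s2 <- cumsum(ys^2 * ind); m <- cumsum(ind)
    tot_s <- s[n]; tot_s2 <- s2[n]; tot_m <- m[n]
    left <- s2 - ifelse(m > 0, s^2 / pmax(m, 1), 0)
    rs <- tot_s - s; rm <- tot_m - m
    right <- (tot_s2 - s2) - ifelse(rm > 0, rs^2 / pmax(rm, 1), 0)
    left + right
  }
  rss <- rss_sides(as == 0) + rss_sides(as == 1)
  cand <- cut[ok]
  best <- cand[which.min(rss[cand])]
  list(split = (zs[best] + zs[best + 1L]) / 2, rss = rss[best])
}

#' Grow a single model-based recursive-partitioning tree
#'
#' Recursively fits the node model, tests each candidate covariate for
#' parameter instability, and (if the Bonferroni-adjusted minimum p-value is
#' below `alpha_split`) splits on the winning covariate at the point
#' minimizing the children's residual sums of squares, subject to child
#' sizes >= `min_node`. Degenerates gracefully to a root-only tree.
#'
#' @param y outcomes.
#' @param arm01 0/1 arm indicator.
#' @param Z numeric covariate matrix (columns = candidate variables).
#' @param candidates column indices available to this tree.
#' @param kinds per-column kinds; "binary"/"categorical" entries use the
#'   chi-square instability test, others the sup-LM test.
#' @param config a [mob_config()].
#' @return nested node list of class `pai_mob_tree`.
#' @export
grow_tree <- function(y, arm01, Z, candidates = seq_len(ncol(Z)),
                      kinds = NULL, config = mob_config()) {
  if (is.null(kinds)) kinds <- rep("continuous", ncol(Z))
  node <- grow_node(y, arm01, Z, candidates, kinds, config,
                    idx = seq_along(y))
  structure(list(root = node, candidates = candidates),
            class = "pai_mob_tree")
}

grow_node <- function(y, arm01, Z, candidates, kinds, config, idx) {
  ys <- y[idx]; as <- arm01[idx]
  nm <- fit_node_model(ys, as)
  leaf <- list(leaf = TRUE, n = length(idx), coef = nm$coef, idx = idx)
  if (length(idx) < 2 * config$min_node || !nm$ok) return(leaf)
  cat_kind <- kinds[candidates] %in% c("binary", "categorical")
  pvals <- rep(NA_real_, length(candidates))
  for (j in seq_along(candidates)) {
    z <- Z[idx, candidates[j]]
    if (length(unique(z)) < 2) { pvals[j] <- 1; next }
    pvals[j] <- instability_test(nm$scores, z, min_node = config$min_node,
                                 categorical = cat_kind[j])
  }
  adj <- if (config$bonferroni) pmin(pvals * length(candidates), 1) else pvals
  ord <- order(adj, pvals)
  for (j in ord) {
    if (adj[j] >= config$alpha_split) break
    v <- candidates[j]
    sp <- best_split(ys, as, Z[idx, v], config$min_node)
    if (is.null(sp)) next                 # no admissible cut; try runner-up
    left <- idx[Z[idx, v] <= sp$split]
    right <- idx[Z[idx, v] > sp$split]
    return(list(leaf = FALSE, n = length(idx), coef = nm$coef,
                var = v, split = sp$split, p_adj = adj[j],
                left = grow_node(y, arm01, Z, candidates, kinds, config, left),
                right = grow_node(y, arm01, Z, candidates, kinds, config,
                                  right)))
  }
  leaf
}

# vectorized tree prediction from the treatment-conditional leaf models
predict_mob_node <- function(node, Z, arm01, rows, out) {
  if (node$leaf || length(rows) == 0) {
    b <- node$coef
    pred <- if (is.na(b["arm"])) rep(b["intercept"], length(rows))
    else b["intercept"] + b["arm"] * arm01[rows]
    out[rows] <- pred
    return(out)
  }
  go_left <- Z[rows, node$var] <= node$split
  out <- predict_mob_node(node$left, Z, arm01, rows[go_left], out)
  predict_mob_node(node$right, Z, arm01, rows[!go_left], out)
}

#' Predict from a MOB tree
#' @param object a `pai_mob_tree`.
#' @param Z covariate matrix (same columns as at fit time).
#' @param arm01 0/1 arm indicator.
#' @param ... unused.
#' @return predicted outcomes.
#' @export
predict.pai_mob_tree <- function(object, Z, arm01, ...) {
  predict_mob_node(object$root, Z, arm01, seq_len(nrow(Z)),
                   numeric(nrow(Z)))
}

# number of terminal nodes (used by tests)
n_leaves <- function(node) {
  if (inherits(node, "pai_mob_tree")) node <- node$root
  if (node$leaf) return(1L)
  n_leaves(node$left) + n_leaves(node$right)
}
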