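# Internal helpers shared across modules.

#' Run code under a private RNG seed, restoring the caller's RNG state
#'
#' Used for internal reference simulations (e.g. the sup-LM null cache) so
#' package internals never disturb a user's seeded analysis stream.
#' @noRd
with_private_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Ordinary least squares via QR with coefficient covariance
#'
#' Thin wrapper around the QR normal equations used by the node models,
#' backward elimination and the final moderated regression. Aliased columns
#' (rank deficiency) get NA coefficients, mirroring [stats::lm()].
#'
#' @param X design matrix (with intercept column if wanted).
#' @param y numeric response.
#' @return list with `coef`, `vcov`, `se`, `tval`, `pval`, `residuals`,
#'   `fitted`, `sigma2`, `df_residual`, `rank`, `aliased`.
#' @keywords internal
fast_ols <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  qx <- qr(X)
  r <- qx$rank
  coef <- qr.coef(qx, y)
  fitted <- qr.fitted(qx, y)
  res <- as.numeric(y - fitted)
  df <- n - r
  sigma2 <- if (df > 0) sum(res^2) / df else NA_real_
  vc <- matrix(NA_real_, p, p, dimnames = list(colnames(X), colnames(X)))
  if (r > 0 && is.finite(sigma2)) {
    R <- qr.R(qx)[seq_len(r), seq_len(r), drop = FALSE]
    piv <- qx$pivot[seq_len(r)]
    vc[piv, piv] <- chol2inv(R) * sigma2
  }
  se <- sqrt(diag(vc))
  tval <- coef / se
  pval <- 2 * stats::pt(abs(tval), df = max(df, 1), lower.tail = FALSE)
  list(coef = coef, vcov = vc, se = se, tval = tval, pval = pval,
       residuals = res, fitted = as.numeric(fitted), sigma2 = sigma2,
       df_residual = df, rank = r, aliased = is.na(coef))
}

# Stratified fold assignment: within each stratum, ids are shuffled and dealt
# to folds round-robin, so fold sizes are near-equal and every training split
# keeps both strata (provided k <= smallest stratum size).
make_folds <- function(strata, k) {
  n <- length(strata)
  fold <- integer(n)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

`%||%` <- function(a, b) if (is.null(a)) b else a
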