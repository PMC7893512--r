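# Covariate pre-selection (attenuation-corrected correlation pruning) and
# variable transformation.

#' Correlation matrix corrected for attenuation
#'
#' Pearson correlations (pairwise-complete) divided by the square root of
#' the product of the two variables' reliabilities:
#' r*_ij = r_ij / sqrt(rel_i * rel_j). Corrected values can exceed 1 in
#' magnitude; these are capped at +/-1 and recorded in the `capped`
#' attribute rather than silently clipped.
#'
#' @param x numeric matrix or data.frame of covariates.
#' @param reliabilities per-variable reliabilities in (0, 1]; default 1
#'   (no correction).
#' @return correlation matrix with unit diagonal; attributes `capped`
#'   (logical matrix) and `undefined` (zero-variance flags).
#' @export
attenuation_corrected_corr <- function(x, reliabilities = NULL) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (is.null(reliabilities)) reliabilities <- rep(1, p)
  if (length(reliabilities) != p || any(reliabilities <= 0) ||
      any(reliabilities > 1))
    stop("reliabilities must be per-variable values in (0, 1]")
  sds <- apply(x, 2, stats::sd, na.rm = TRUE)
  r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  denom <- sqrt(outer(reliabilities, reliabilities))
  rc <- r / denom
  diag(rc) <- 1
  capped <- !is.na(rc) & abs(rc) > 1
  if (any(capped)) {
    warning(sum(capped[upper.tri(capped)]),
            " corrected correlation(s) exceeded 1 in magnitude; capped")
    rc[capped] <- sign(rc[capped])
  }
  structure(rc, capped = capped, undefined = sds == 0 | is.na(sds))
}

#' Greedy collinearity pruning
#'
#' Repeatedly finds the pair with the largest |corrected correlation| above
#' the threshold and removes the lower-priority member, until no violating
#' pair remains. Priority: a variable with larger mean |correlation| with
#' the outcome is kept when `outcome_corr` is given; otherwise the
#' earlier-listed variable is kept (the "total scale before subscales"
#' convention).
#'
#' @param corr square (corrected) correlation matrix with dimnames.
#' @param threshold removal threshold on |r| (default 0.70).
#' @param outcome_corr optional named vector of correlations with the
#'   outcome, used to break ties in favor of the more outcome-relevant
#'   variable.
#' @return list of class `pai_screening` with `retained`, `removed`
#'   (data.frame: variable, partner, correlation), and the pruned matrix.
#' @export
prune_collinear <- function(corr, threshold = 0.70, outcome_corr = NULL) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  vars <- colnames(corr)
  if (is.null(vars)) vars <- colnames(corr) <- rownames(corr) <-
      paste0("V", seq_len(ncol(corr)))
  removed <- data.frame(variable = character(), partner = character(),
                        correlation = numeric(), stringsAsFactors = FALSE)
  keep <- vars
  repeat {
    sub <- abs(corr[keep, keep, drop = FALSE])
    diag(sub) <- 0
    sub[is.na(sub)] <- 0
    if (max(sub) <= threshold) break
    ij <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    v1 <- keep[ij[1]]; v2 <- keep[ij[2]]
    drop_var <- if (!is.null(outcome_corr) &&
                    all(c(v1, v2) %in% names(outcome_corr))) {
      if (abs(outcome_corr[v1]) >= abs(outcome_corr[v2])) v2 else v1
    } else {
      # keep the earlier-listed variable
      if (match(v1, vars) <= match(v2, vars)) v2 else v1
    }
    kept_var <- setdiff(c(v1, v2), drop_var)
    removed <- rbind(removed, data.frame(
      variable = drop_var, partner = kept_var,
      correlation = corr[v1, v2], stringsAsFactors = FALSE))
    keep <- setdiff(keep, drop_var)
  }
  structure(list(retained = keep, removed = removed,
                 corr = corr[keep, keep, drop = FALSE],
                 threshold = threshold), class = "pai_screening")
}

#' Fit variable transformations
#'
#' Continuous variables are standardized; discrete (count) and
#' binary/categorical variables are centered. A variable whose |skewness|
#' exceeds `skew_threshold` is first symmetrized: log1p when its minimum is
#' >= 0, otherwise square root after shifting to the origin. The threshold
#' rule replaces case-by-case visual inspection so the pipeline is
#' reproducible.
#'
#' @param x data.frame of covariates (training data).
#' @param kinds character vector per column: "continuous", "count",
#'   "discrete", "binary" or "categorical".
#' @param skew_threshold absolute sample skewness above which a
#'   symmetrizing transform is applied (default 1).
#' @return list of class `pai_transforms`: per-variable records with
#'   `skew_fix` ("none"/"log1p"/"sqrt_shift"), `shift`, `location`, `scale`.
#' @export
fit_transforms <- function(x, kinds, skew_threshold = 1) {
  stopifnot(ncol(x) == length(kinds))
  rec <- lapply(seq_along(kinds), function(j) {
    v <- x[[j]]
    kind <- kinds[j]
    skew <- if (stats::sd(v, na.rm = TRUE) > 0)
      e1071::skewness(v[!is.na(v)], type = 2) else 0
    fix <- "none"; shift <- 0
    if (kind %in% c("count", "discrete", "continuous") &&
        is.finite(skew) && abs(skew) > skew_threshold) {
      if (min(v, na.rm = TRUE) >= 0) {
        fix <- "log1p"; v <- log1p(v)
      } else {
        fix <- "sqrt_shift"; shift <- min(v, na.rm = TRUE)
        v <- sqrt(v - shift)
      }
    }
    loc <- mean(v, na.rm = TRUE)
    scl <- if (kind == "continuous") stats::sd(v, na.rm = TRUE) else 1
    if (kind == "continuous" && (is.na(scl) || scl == 0))
      stop("cannot standardize zero-variance variable: ", names(x)[j])
    list(name = names(x)[j], kind = kind, skew_fix = fix, shift = shift,
         location = loc, scale = scl)
  })
  names(rec) <- names(x)
  structure(rec, class = "pai_transforms")
}

#' Apply fitted transformations
#'
#' Replays the fitted transform parameters (no refitting), so applying a
#' training-fitted record to the training data reproduces the fit-time
#' output exactly, and new data are mapped onto the training scale.
#'
#' @param x data.frame with the recorded columns.
#' @param record a `pai_transforms` from [fit_transforms()].
#' @return transformed data.frame.
#' @export
apply_transforms <- function(x, record) {
  stopifnot(inherits(record, "pai_transforms"))
  out <- x
  for (r in record) {
    v <- x[[r$name]]
    if (r$skew_fix == "log1p") v <- log1p(v)
    if (r$skew_fix == "sqrt_shift") v <- sqrt(v - r$shift)
    out[[r$name]] <- (v - r$location) / r$scale
  }
  out
}

# invert a transformed value back to the raw covariate scale (used to report
# Johnson-Neyman boundaries in natural units)
untransform_value <- function(value, r) {
  v <- value * r$scale + r$location
  if (r$skew_fix == "log1p") v <- expm1(v)
  if (r$skew_fix == "sqrt_shift") v <- v^2 + r$shift
  v
}

#' Serialize / restore a transform record as JSON
#' @param record a `pai_transforms`.
#' @param file path.
#' @export
write_transforms_json <- function(record, file) {
  jsonlite::write_json(unclass(record), file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_transforms_json
#' @export
read_transforms_json <- function(file) {
  rec <- jsonlite::read_json(file, simplifyVector = TRUE)
  structure(lapply(rec, as.list), class = "pai_transforms")
}
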