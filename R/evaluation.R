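# Evaluation of PAI recommendations: observed outcomes of indicated versus
# non-indicated allocations (full sample, top-60% |PAI| subset,
# per-indicated-arm subsets) and agreement between two PAI score sets.

#' Pooled-variance two-sample contrast
#'
#' Student's t test with the pooled variance (df = n1 + n2 - 2, matching
#' the conventional reporting for randomized allocations) plus Cohen's d
#' from the pooled SD. d and t are linked by d = t * sqrt(1/n1 + 1/n2).
#'
#' @param x1,x2 outcome vectors for the two groups (each of size >= 2).
#' @return list: `n1`, `n2`, `mean1`, `mean2`, `t`, `df`, `p`, `d`.
#' @export
contrast <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  if (n1 < 2 || n2 < 2) stop("both groups need >= 2 observations")
  tt <- stats::t.test(x1, x2, var.equal = TRUE)
  sp <- sqrt(((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) /
               (n1 + n2 - 2))
  list(n1 = n1, n2 = n2, mean1 = mean(x1), mean2 = mean(x2),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, d = (mean(x1) - mean(x2)) / sp)
}

#' Participants with the largest |PAI| scores
#'
#' Ranks by |PAI| descending and keeps the `ceiling(fraction * n)` highest;
#' ties at the boundary are broken by participant id (ascending), so the
#' subset is deterministic.
#'
#' @param pai_table a [crossval_predict()] table.
#' @param fraction fraction to keep, in (0, 1] (default 0.60).
#' @return vector of participant ids.
#' @export
top_magnitude_subset <- function(pai_table, fraction = 0.60) {
  stopifnot(fraction > 0, fraction <= 1)
  n_keep <- ceiling(fraction * nrow(pai_table))
  ord <- order(-pai_table$pai_abs, pai_table$id)
  pai_table$id[ord[seq_len(n_keep)]]
}

eval_one <- function(avg, got_indicated, label, skip_log) {
  g1 <- avg[got_indicated]; g0 <- avg[!got_indicated]
  if (length(g1) < 2 || length(g0) < 2)
    return(list(rec = NULL,
                skip = data.frame(contrast = label,
                                  reason = "a group has fewer than 2 members")))
  cr <- contrast(g1, g0)
  list(rec = cbind(data.frame(contrast = label), as.data.frame(cr)),
       skip = NULL)
}

#' Evaluate PAI recommendations against observed outcomes
#'
#' Compares the observed average follow-up BDI-II of participants who,
#' by randomization, received their PAI-indicated treatment against those
#' who received the non-indicated treatment: (a) in the full sample, (b) in
#' the top-60% |PAI| subset, (c)/(d) among CT-indicated and IPT-indicated
#' participants separately, and (e) the per-arm contrasts repeated in the
#' top-60% subset. Participants with a signed PAI of exactly zero carry no
#' recommendation and are excluded. Degenerate contrasts are skipped with a
#' reason.
#'
#' @param pai_table a [crossval_predict()] table.
#' @param avg_bdi observed average follow-up BDI-II, aligned with
#'   `pai_table$id`.
#' @param top_fraction |PAI| fraction for the enrichment subset
#'   (default 0.60).
#' @return list of class `pai_evaluation`: `contrasts` (one row per
#'   computed contrast), `skipped`, `top_ids`.
#' @export
evaluate_pai <- function(pai_table, avg_bdi, top_fraction = 0.60) {
  stopifnot(nrow(pai_table) == length(avg_bdi))
  keep <- pai_table$indicated != "none"
  tab <- pai_table[keep, ]
  avg <- avg_bdi[keep]
  got <- as.character(tab$arm) == tab$indicated
  top_ids <- top_magnitude_subset(pai_table, top_fraction)
  in_top <- tab$id %in% top_ids

  specs <- list(
    list(sel = rep(TRUE, nrow(tab)), label = "indicated_vs_non"),
    list(sel = in_top, label = "indicated_vs_non_top"),
    list(sel = tab$indicated == "CT", label = "ct_indicated"),
    list(sel = tab$indicated == "IPT", label = "ipt_indicated"),
    list(sel = in_top & tab$indicated == "CT", label = "ct_indicated_top"),
    list(sel = in_top & tab$indicated == "IPT", label = "ipt_indicated_top"))
  contrasts <- NULL; skipped <- NULL
  for (s in specs) {
    r <- eval_one(avg[s$sel], got[s$sel], s$label, skipped)
    contrasts <- rbind(contrasts, r$rec)
    skipped <- rbind(skipped, r$skip)
  }
  structure(list(contrasts = contrasts,
                 skipped = skipped %||%
                   data.frame(contrast = character(), reason = character()),
                 top_ids = top_ids, top_fraction = top_fraction,
                 n_zero_pai = sum(!keep)),
            class = "pai_evaluation")
}

#' @export
print.pai_evaluation <- function(x, ...) {
  cat("<pai_evaluation> group means on the average follow-up BDI-II scale\n")
  print(x$contrasts, row.names = FALSE, digits = 3)
  if (nrow(x$skipped)) {
    cat("skipped:\n"); print(x$skipped, row.names = FALSE)
  }
  invisible(x)
}

#' Agreement between two sets of PAI scores
#'
#' Pearson correlation of the signed PAIs, the 2x2 cross-tabulation of the
#' recommended arms with a Pearson chi-square test (no continuity
#' correction), and per-arm agreement fractions. Participants are matched
#' on id; at least 3 must overlap.
#'
#' @param pai_a,pai_b two `pai_table`s (e.g. a long-term and a
#'   post-treatment PAI, or primary and nested-validation runs).
#' @return list of class `pai_agreement`: `correlation`, `table`,
#'   `chisq`, `chisq_p`, `agreement` (overall and per recommended arm of
#'   set A), `n`.
#' @export
compare_pai_sets <- function(pai_a, pai_b) {
  ids <- intersect(pai_a$id, pai_b$id)
  if (length(ids) < 3) stop("need at least 3 overlapping participants")
  a <- pai_a[match(ids, pai_a$id), ]
  b <- pai_b[match(ids, pai_b$id), ]
  if (stats::sd(a$pai_signed) == 0 || stats::sd(b$pai_signed) == 0)
    stop("zero variance in a PAI score set")
  rho <- stats::cor(a$pai_signed, b$pai_signed)
  tab <- table(A = factor(a$indicated, levels = c("CT", "IPT")),
               B = factor(b$indicated, levels = c("CT", "IPT")))
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  agree <- as.character(a$indicated) == as.character(b$indicated)
  structure(list(correlation = rho, table = tab,
                 chisq = unname(chi$statistic), chisq_p = chi$p.value,
                 agreement = c(
                   overall = mean(agree),
                   CT = mean(agree[a$indicated == "CT"]),
                   IPT = mean(agree[a$indicated == "IPT"])),
                 n = length(ids)), class = "pai_agreement")
}
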