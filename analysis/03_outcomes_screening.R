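#!/usr/bin/env Rscript
# Build the analysis outcome (natural-cubic-spline AUC of BDI-II over
# months 7-24, residualized on baseline) and screen/transform the
# covariates (attenuation-corrected correlation pruning at |r| > 0.70;
# skewed counts log-transformed, discrete centered, continuous
# standardized).

suppressMessages(library(paitrial))

trial <- read_trial_csv("results/trial_completed.csv")
outc <- compute_outcomes(trial)
cat(sprintf("average follow-up BDI-II: mean %.1f, sd %.1f\n",
            mean(outc$avg_bdi), sd(outc$avg_bdi)))

kinds <- trial$covariate_meta$kind
tfm <- fit_transforms(trial$covariates, kinds)
n_skew <- sum(vapply(tfm, function(r) r$skew_fix != "none", TRUE))
cat(n_skew, "covariates received a symmetrizing transform\n")
Zt <- as.matrix(apply_transforms(trial$covariates, tfm))

corr <- attenuation_corrected_corr(Zt)
scr <- prune_collinear(corr, threshold = 0.70,
                       outcome_corr = drop(cor(Zt, outc$auc_residual)[, 1]))
cat(length(scr$retained), "covariates retained after pruning (",
    nrow(scr$removed), "removed )\n")

write.csv(outc, "results/outcomes.csv", row.names = FALSE)
write.csv(cbind(id = trial$id, as.data.frame(Zt[, scr$retained])),
          "results/covariates_transformed.csv", row.names = FALSE)
write_transforms_json(tfm, "results/transforms.json")
cat("wrote results/outcomes.csv, results/covariates_transformed.csv,",
    "results/transforms.json\n")
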