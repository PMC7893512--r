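# paitrial

Treatment selection for depression from randomized-trial data: a complete,
tested implementation of the **Personalized Advantage Index (PAI)**
workflow for two-arm trials with longitudinal outcomes, together with a
synthetic-trial generator with known predictor/moderator structure for
validating every stage.

## The problem

Cognitive therapy (CT) and interpersonal psychotherapy (IPT) help
depressed patients about equally *on average*, but individuals differ in
which treatment serves them better over the long run. Given baseline
covariates `x` and follow-up depression severity `y` (BDI-II aggregated
over months 7–24 into a cubic-spline AUC, residualized on baseline), the
pipeline:

1. **imputes** missing covariates and outcomes (iterative random-forest
   imputation, validated by NRMSE/PFC on re-masked cells);
2. **screens** covariates (attenuation-corrected correlations, greedy
   pruning at |r| > 0.70; skew-fixing and centering/standardizing
   transforms);
3. **selects variables in two steps** — a forest of model-based
   recursive-partitioning trees (node model `y ~ arm`, score-based
   sup-LM/chi-square instability tests, out-of-bag permutation importance
   with the lowest-rank threshold rule), then backward elimination
   (α = 0.05) on 1000 bootstrap resamples with a 60% robustness
   threshold, classifying survivors as predictors or moderators;
4. **fits the final moderated regression**

   `y = β0 + β_arm·arm + Σ β_p·pred + Σ β_m·mod + Σ β_int·mod·arm`

   and computes fivefold cross-validated predictions of each participant's
   outcome under both arms. The signed PAI is
   `prediction(CT) − prediction(IPT)`: negative indicates CT, positive
   IPT, the magnitude is the predicted advantage. Johnson–Neyman regions
   report where along each moderator the between-arm difference is
   significant;
5. **evaluates** the recommendations by comparing observed average
   follow-up BDI-II of participants randomized to their indicated vs
   non-indicated treatment (pooled-variance t, Cohen's d), overall, in the
   top-60 % |PAI| subset and per indicated arm; and
6. **stress-tests** the whole chain with a nested fivefold validation in
   which selection and fitting are repeated inside training folds only.

The intended users are biostatisticians and methods-minded clinical
researchers studying heterogeneous treatment effects in psychotherapy
trials. No clinical data ship with the package: `trial_config()` /
`generate_trial()` produce trials with the study's dimensions (n = 151,
38 mixed-kind covariates, 15.5 % outcome missingness, one planted binary
predictor and two planted count moderators) plus the ground truth needed
for recovery testing.

## Worked example

```r
library(paitrial)

g   <- generate_trial(trial_config(seed = 1))
res <- run_pai_pipeline(g$trial, pai_config(n_trees = 2000, n_boot = 500,
                                            seed = 2))
print(res)
```

```
<pai_analysis>
  predictors: parental_alcohol 
  moderators: life_events, childhood_trauma 
  indicated CT: 68, IPT: 83, none: 0
<pai_evaluation> group means on the average follow-up BDI-II scale
             contrast n1 n2 mean1 mean2      t  df      p      d
     indicated_vs_non 61 90  14.9  17.9 -2.415 149 0.0170 -0.400
 indicated_vs_non_top 33 58  16.6  18.2 -0.901  89 0.3701 -0.196
         ct_indicated 27 41  18.5  21.4 -1.566  66 0.1222 -0.388
        ipt_indicated 34 49  12.0  15.0 -2.092  81 0.0395 -0.467
     ct_indicated_top 13 23  22.9  25.3 -0.999  34 0.3251 -0.346
    ipt_indicated_top 20 35  12.5  13.5 -0.668  53 0.5073 -0.187
```

Reading this: the two-step selection recovered exactly the three planted
variables (one predictor, two moderators). Of 151 participants, 61
happened to be randomized to the arm their PAI indicates; their observed
average follow-up BDI-II is 14.9 vs 17.9 for the non-indicated group
(d = 0.40 in favor of the indicated allocation). Top-60% enrichment is
replicate-dependent at this sample size — absent in this draw, present
on average (the acceptance script reports the rates over replicate
pipelines). `res$johnson_neyman` locates the moderator values beyond
which the CT-vs-IPT difference is significant, on both the modeling and
the raw count scale.

The numbered scripts under `analysis/` run the same workflow stage by
stage (simulate → impute → outcomes/screening → selection → PAI →
evaluation → nested validation), printing what each stage found and
writing tables under `results/`.

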