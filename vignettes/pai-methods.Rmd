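---
title: "Long-term treatment selection with the Personalized Advantage Index: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Long-term treatment selection with the Personalized Advantage Index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`paitrial` implements a complete treatment-selection analysis for two-arm
randomized trials with longitudinal depression outcomes: from raw trial
data (or a synthetic stand-in with known structure) to per-individual
Personalized Advantage Index (PAI) recommendations and their evaluation.
This vignette explains the statistical machinery, the assumptions behind
each stage, and the choices we made where the design was genuinely open.

## The problem and the estimand

Cognitive therapy (CT) and interpersonal psychotherapy (IPT) are, on
average, equally effective for major depressive disorder, yet individual
responses differ. The PAI asks the counterfactual question per individual:
*given this person's baseline profile, how much better would they do under
CT than under IPT?* Formally, with a fitted outcome model, each participant
receives two predictions — one with the treatment indicator set to CT, one
to IPT — and

$$\mathrm{PAI}_i = \hat y_i(\mathrm{CT}) - \hat y_i(\mathrm{IPT}).$$

Lower outcomes (depression burden) are better, so a **negative PAI
indicates CT** and a positive one IPT; the magnitude estimates the
advantage. The arm is coded CT = 0, IPT = 1 everywhere. This sign
convention is stated on every relevant function because nothing in the
algebra enforces it.

## Outcome construction

The primary outcome is depression severity over a 17-month follow-up:
BDI-II measured at months 7, 8, 9, 10, 11, 12 and 24, aggregated per
participant into the integral of the interpolating cubic spline (an AUC in
BDI-II x months). Dividing by the 17-month span gives the *average
follow-up BDI-II*, the scale on which group means are reported; dividing
changes no test statistic.

Two cubic-spline end conditions are supported and the choice matters more
than it first appears:

* `"fmm"` (Forsythe–Malcolm–Moler) reproduces any single cubic polynomial
  exactly — this is the contract the oracle tests pin down, and the
  default of `spline_auc()`.
* `"natural"` (zero second derivative at the ends) is what
  `compute_outcomes()` uses for the analysis. The schedule is very uneven:
  six monthly visits and then a 12-month gap. Writing the AUC as a linear
  functional of the seven observations, the FMM weights reach −181 and
  +116 at months 11–12, because the cubic fitted through the dense end
  extrapolates its curvature across the gap; the natural-boundary weights
  stay below 30. Independent per-visit noise of 1 BDI-II point therefore
  inflates the FMM AUC by ~13 points on the average-BDI scale but only
  ~2.4 points under natural boundaries. Robustness across the gap wins for
  the analysis; exactness on polynomials remains available and tested.

Integration is composite Simpson per knot interval, which is exact for
piecewise cubics, so no quadrature tolerance enters.

Because baseline severity differed (non-significantly) between arms, the
modeling outcome is the residual of AUC regressed on baseline BDI-II
(`residualize()`): exactly orthogonal to baseline, mean zero. Group means
are reported from the *raw* AUC converted to average BDI-II — the
residualized scale is an arbitrary-origin modeling device, and reporting
raw means keeps them interpretable as depression scores.

## Missing data

Covariates and outcomes are imputed once (single imputation) with the
iterative random-forest scheme: initialize missing cells at column
means/modes, then sweep columns in order of increasing missingness,
fitting a forest of each column on all others and predicting its missing
entries, until the normalized change in imputed values first increases
(the previous sweep is returned) or 10 sweeps elapse. The per-column
forests are `ranger` forests (100 trees, `mtry = floor(sqrt(p))`,
defaults of the published algorithm); the sweep loop, stopping rule and
accuracy validation are implemented here. The feature matrix deliberately
contains *change scores from baseline* for every follow-up measurement
(including the auxiliary month-3 score), all covariates, and the received
arm — change scores make the strong within-person correlation across
visits directly available to the forests.

Accuracy is validated by re-masking the completed data at a known rate and
scoring NRMSE (continuous) and PFC (categorical) on the masked cells. Two
structural guarantees are tested rather than assumed: observed cells are
bit-identical before and after imputation, and the whole cycle is
deterministic under a fixed seed (classification forests can break
prediction-vote ties through the R RNG, so the sweep loop runs inside a
private seeded stream).

## Screening and transforms

Before selection, covariates pass an attenuation-corrected correlation
prune: \(r^*_{ij} = r_{ij} / \sqrt{\mathrm{rel}_i\,\mathrm{rel}_j}\), with
reliabilities defaulting to 1 (none were available), and a greedy rule
that repeatedly removes the lower-priority member of the worst pair with
\(|r^*| > 0.70\). Priority keeps the variable more correlated with the
outcome when that information is supplied, else the earlier-listed one
(the "total scale before subscales" convention). The rule is idempotent.

Transforms: continuous variables are standardized, discrete and binary
ones centered. A variable whose absolute sample skewness exceeds 1.0 is
first symmetrized — log1p when non-negative, square root after shifting
otherwise. The threshold replaces case-by-case visual inspection so that
the pipeline is reproducible and can be re-fit inside training folds; 1.0
is the conventional "markedly skewed" cutoff. Transform parameters are
*replayed*, never refit, when applied to new data.

## Stage 1: model-based recursive-partitioning forest

The node model is the two-group regression `outcome ~ intercept + arm`.
A candidate covariate shows *parameter instability* if the fitted
coefficients drift systematically along it; instability is tested with
score-based fluctuation tests: the sup-LM statistic over the cumulative
per-observation estimating functions in the covariate's sort order
(continuous/count), or a chi-square on per-category score sums (binary).
A node splits on the most unstable candidate — if its Bonferroni-adjusted
p-value is below 0.10 — at the cut minimizing the children's summed
node-model residual sums of squares, subject to both children having at
least 15 participants. The forest grows 10 000 such trees (scaled down in
simulations; sizes below) on bootstrap samples, each tree seeing a random
`floor(sqrt(p))`-subset of covariates, drawn per tree as in the cited
forest implementation.

The sup-LM null distribution is obtained by Monte-Carlo simulation of its
limiting process — \(\sup_t \|B(t)\|^2/(t(1-t))\) for a bivariate Brownian
bridge — on a fixed 150-point grid under a private seed, cached as
quantile summaries. Two discretization choices matter:

* The supremum is taken only over *admissible* cut fractions (both sides
  ≥ 15, distinct covariate values), and the reference is maximized over
  the grid columns nearest those same fractions. For heavily tied
  covariates (counts with a handful of levels) this is essential: against
  the continuum reference, a Poisson covariate's test rejects at 2%
  instead of 10%.
* The 150-point grid matches the cut-set discreteness at the node sizes
  this pipeline targets (n ≈ 100–150). Null rejection rates at
  \(\alpha = 0.10\) measure 0.08–0.10 across continuous, count and binary
  partitioners.

Variable importance is out-of-bag permutation importance: for each tree
and each covariate available to it, the OOB mean squared prediction error
with that covariate's values permuted minus the error with real values,
averaged over trees; predictions come from the treatment-conditional leaf
models. Selection uses the threshold rule: the absolute importance of the
lowest-ranking covariate, with covariates strictly above it passing to
stage 2. For pure noise the count of selected variables is the number of
leading positive signs in the importance magnitude order — Geometric(1/2),
so the set is empty half the time and rarely exceeds two; this derived
behaviour, not an arbitrary rate, is what the tests assert.

## Stage 2: bootstrap backward elimination

The stage-1 survivors enter `outcome ~ arm + mains + covariate:arm`
interactions. On each of 1000 bootstrap resamples (original size, with
replacement; resamples missing an arm are redrawn and logged), backward
elimination repeatedly drops the least significant *eliminable* term above
\(\alpha = 0.05\). Marginality is enforced: a main effect is not
eliminable while its interaction survives, nor the arm effect while any
interaction remains. We use the p-value rule rather than AIC: the
procedure's published description states the \(\alpha = 0.05\) criterion,
and the p-rule keeps single-run behaviour interpretable (AIC remains an
obvious extension). A consequence worth knowing: under the null,
interaction terms survive at ≈ α but protected mains at ≈ 2α — the
protection, not a bug, and the tests check the two rates separately.

Terms selected in at least 60% of resamples are *robust*; the 60% rule is
applied per term (the published account is ambiguous between per-term and
per-variable; per-term is the finer-grained reading and lets a variable be
a predictor without being a moderator). A variable with a robust
interaction is a moderator; one with only a robust main effect is a
predictor. Sign stability is tallied alongside (fraction of selections
with a positive coefficient).

## Final model, cross-validation, Johnson–Neyman

The final OLS model contains the predictors' main effects, the
moderators' main effects, the moderator-by-arm interactions, and the arm
main effect. The arm effect is included by marginality even though the
published final-model equation omits it; without it, an interaction
coefficient confounds treatment-effect modification with the average
treatment effect. (A switch exists but warns.)

PAI scores come from fivefold cross-validation: folds are random but
stratified by arm (guaranteeing estimability in every training split);
each fold's participants are predicted under both arms by the model fitted
on the other four folds. Participants with a PAI of exactly zero carry no
recommendation and are excluded from indicated/non-indicated contrasts.
Antisymmetry under swapping the arm labels (every PAI negates, every
recommendation flips) is enforced by construction and audited by test.

For each moderator \(m\), the Johnson–Neyman region solves
\(\delta(m)^2 = t^2_{\alpha/2,\nu}\,\mathrm{SE}^2(m)\) where
\(\delta(m)\) is the between-arm difference with the other moderators
folded in at their sample means; the quadratic's real roots, clipped to
the observed moderator range, bound the region(s) where the difference is
significant, each annotated with the favored arm. A dense-grid search is
the test oracle.

## Evaluation

Observed average follow-up BDI-II of participants randomized (by chance)
to their PAI-indicated treatment is compared with the non-indicated group
by pooled-variance Student's t (df = n1 + n2 − 2, matching the
conventional df arithmetic for these contrasts) with Cohen's d from the
pooled SD, in the full sample, in the top-60% |PAI| subset
(`ceiling(0.6 n)` members — 91 of 151 — with boundary ties broken by
participant id), and separately among CT-indicated and IPT-indicated
participants. The identity \(d = t\sqrt{1/n_1 + 1/n_2}\) is audited on
every reported contrast. Two PAI score sets (e.g. long-term vs
post-treatment, or primary vs nested) are compared by Pearson correlation
of the signed scores and a 2x2 recommendation cross-tab with an
uncorrected chi-square.

**A calibration caveat we measured rather than assumed.** When the
recommendations come from a model fitted on *independent* data, the
indicated/non-indicated contrast rejects at the nominal 5% under the null
(measured 6.2%). When they come from the cross-validated pipeline on the
same data, the null rejection rate roughly doubles (measured ≈ 12% at
n = 151, k = 5, two noise moderators): although each participant's own
outcome never enters their own fold's model, it enters the models that
label *everyone else*, and this cross-participant coupling breaks the
t-test's independence assumption. The evaluation therefore quantifies
enrichment honestly but its p-values are anticonservative under the null —
a property of this evaluation design generally, worth remembering when
reading any indicated-vs-non-indicated t-test.

## Nested validation

Selecting variables on the full sample and then cross-validating only the
weights still lets selection see the held-out outcomes ("double
dipping"). `nested_validate()` repeats residualization, transforms, both
selection stages and model fitting entirely inside each of five training
splits (fold partition drawn on a seed stream separate from the primary
CV), predicts the held-out fifth under both arms, pools, evaluates, and
compares with the primary PAIs. Folds whose selection comes back empty
fall back to predictor-only or arm-only models, logged, so predictions
are always produced. Imputation precedes nesting as a data-preparation
step (a switch in principle; the single-imputation design makes
re-imputing per fold a second-order refinement). A leakage audit
(train/test id intersections) is part of the report, and an oracle mode
(selection forced to the true variables) is used to verify that nested
and primary PAIs correlate above 0.9 when selection is not the
bottleneck.

## The synthetic trial generator

No clinical data are distributed, so the generator is a first-class,
tested module that emulates the study conditions: n = 151 randomized 1:1
(CT receiving the 76th slot), 38 screened covariates — 21 continuous (two
exchangeable-correlation blocks of 5 and 4 at ρ = 0.5 and 0.35), 10
Poisson counts (λ = 1.5, right-skewed like life-event counts), 4 binaries
(prevalence 0.3) — plus one planted binary predictor and two planted
count moderators; baseline BDI-II ~ N(26.5, 8) clipped to [0, 63].

The generative outcome model operates on the average-BDI scale:

$$y_i = 16 + 3\,\tilde b_i + \beta_P \tilde x_{P,i}
      + \textstyle\sum_m \gamma_m \tilde x_{m,i}(a_i + \tfrac12)
      + \varepsilon_i,\qquad \varepsilon_i \sim N(0, 5),$$

with \(a_i = \pm\tfrac12\) the arm contrast and covariates standardized by
their theoretical moments. Standardized effects (per covariate SD, in
residual-SD units): predictor 0.4; moderator interactions 0.8 and 0.5,
each accompanied by a main effect of equal size (`mod_main_ratio = 1`).
The moderators are thus strongly prognostic as well as prescriptive —
the configuration under which stage-1 importance ranks both moderators
above the pure predictor, the ordering reported for these variables (the
predictor ranked last among the selected four). With zero or small
moderator main effects the binary predictor's variance contribution ties
or beats the strongest moderator's anywhere inside the 0.4–0.8 band, and
that ordering cannot arise. The arm main effect is zero: the two
therapies are equally effective on average.

Trajectories place the realized outcome as a level, add a person-level
linear drift (SD 0.15 points/month) centered at month 15.5 so the drift
integrates to zero over [7, 24], and AR(1)-correlated visit deviations
(ρ = 0.9 per month-lag, marginal SD 0.5). Deviations are smooth and small
by design: the AUC functional's sensitivity over the sparse tail (above)
makes independent per-visit jitter unrealistic *and* uninformative —
observed BDI-II series are strongly autocorrelated, and it is that
redundancy which lets the imputation forests reach low masked-cell error.
Outcomes are stored continuous (no integer rounding) for the same reason;
values are clipped to [0, 63] and the clip count logged. The follow-up
trajectory shape during months 7–24 is our choice — the source material
reports none.

Missingness defaults: 0.4% of covariate cells (MCAR) and 15.5% of outcome
cells (~164 of 1057; MCAR by default, or MAR with the cell-missingness
probability logistic in a designated observed covariate, intercept solved
to hit the marginal rate). Every participant keeps at least one observed
outcome. Ground truth (per-arm expected outcomes, true individualized
effects, optimal arms, generative coefficients and design) is returned
alongside for recovery tests.

What the generator does **not** emulate: item-level measurement, informal
dropout processes (monotone missingness), therapist effects, treatment
received during follow-up, or real psychometric covariance structure
beyond the block correlations. Passing recovery tests therefore shows the
pipeline recovers planted linear structure under realistic dimensions and
missingness — not that it would find true moderators in any particular
clinical dataset.

## Problem sizes used in tests and scripts

The forest defaults to 10 000 trees and stage 2 to 1000 resamples; the
simulation studies in the test-suite and the acceptance script scale these
to keep full runs to minutes while leaving the statistics stable: recovery
studies use 5–20 replicate pipelines at 1500–2000 trees and 300–500
resamples, on complete datasets so selection performance is not
confounded with imputation noise (imputation accuracy is measured
separately; the top-1 importance ranking is stable from ~500 trees on the
recovery fixtures, which is itself a tested invariant). Null-calibration
studies use 400–2000 instability replicates and 500 pipeline replicates
with the selection stage fixed to a pre-specified noise moderator set
(under the null the selection stages mostly return empty sets, which
would leave the contrast degenerate rather than testable). The
nested-validation demonstrations use 150–500 trees inside folds. The
analysis scripts under `analysis/` state their sizes inline.

## Known limitations

* Single imputation: no between-imputation variance, so downstream SEs
  are slightly optimistic.
* The indicated/non-indicated t-test is anticonservative under the null
  (measured, see Evaluation); effect-size estimates (d) remain unbiased
  descriptions of the observed group difference.
* Backward elimination with marginality inflates null retention of
  protected main effects to ~2α.
* The sup-LM reference is Monte-Carlo (resolution ~2.4e-4 in p); exact
  analytic tail approximations are not implemented.
* OLS final models only; no shrinkage, no honest-forest CATE estimators —
  deliberate scope, matching the procedure under study.
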