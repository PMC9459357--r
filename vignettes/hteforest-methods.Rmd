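---
title: "Estimating subgroup and individual treatment effects with honest causal forests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating subgroup and individual treatment effects with honest causal forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hteforest)
```

## The problem

A two-arm randomized trial reports one overall treatment effect, but the
effect of an intervention rarely is one number: some patients benefit more
than others, and some may be harmed. `hteforest` estimates the conditional
average treatment effect (CATE)

$$\tau(x) = E[Y(1) - Y(0) \mid X = x]$$

for a binary outcome (here a 90-day mortality analogue, so negative
$\tau$ means the treatment saves lives), aggregates it into subgroup average
treatment effects on the risk-difference scale, tests globally for
heterogeneity, and summarizes the fitted effect surface with interpretable
trees. A fixed-parametric comparator (subgroup logistic models with recycled
predictions) is included because that is what trial reports conventionally
use, and the contrast between the two is itself informative.

The intended setting is a pragmatic critical-care trial in patients aged 65
and over: ~2500 patients, 1:1 randomization, binary 90-day mortality around
35%, and a mix of binary comorbidities, categorical admission
characteristics, and continuous severity scores. The synthetic generator
(`simulation_config()`, `generate_trial()`) emulates that covariate
structure with known potential outcomes so that every estimator in the
package can be validated against ground truth.

## The causal forest

### Honest causal trees

Each tree is grown on a subsample split into two disjoint halves. The
*split half* chooses splits; the *estimate half* supplies the leaf effects

$$\hat\tau_L = \bar Y_{\text{treated} \in L} - \bar Y_{\text{control} \in L}.$$

No observation influences both the shape of the tree and the effect
estimated in its leaf (honesty), which is what makes the ensemble's
confidence intervals meaningful.

Splits maximize the between-child heterogeneity of the split-half effect,
$\sum_{c} n_c \hat\tau_c^2$ for fixed parent, over all candidate variables
and thresholds (midpoints between consecutive distinct observed values on
the split half; one-hot indicators for categorical covariates). Both
children must keep at least `min_leaf_per_arm` treated and control
observations on *both* halves. We chose this direct difference-in-means
criterion rather than a gradient/pseudo-outcome approximation because it is
the plain reading of "maximize the variance of the estimated treatment
effect" and because it admits an exact exhaustive-search oracle: the test
suite recomputes every candidate split in R and requires the C++ tree to
agree exactly. Ties are broken toward the lowest covariate index, then the
smallest threshold, so fits are bit-reproducible given the seed.

### Ensemble, out-of-bag prediction, and variance

The forest averages leaf effects across `num_trees` trees (default 5000).
For training rows, predictions are out-of-bag: only trees whose subsample
excluded the row contribute, which is what the downstream calibration test
requires.

Trees are grown in *pairs sharing a half-sample* of the data (each pair
draws half the rows; both trees subsample within it). The variance of
$\hat\tau(x)$ is estimated as the between-pair variance of pair means minus
half the within-pair variance — the bootstrap-of-little-bags idea with
group size 2. The within-pair term debiases the Monte-Carlo noise of having
finitely many trees; the floor at zero is documented behaviour, and in
low-signal regions the standard error can be small. In a coverage study
under a smooth age-driven effect (n = 4000, 1000 trees) the 95% intervals
covered the true $\tau(x_i)$ for well over 85% of patients; that study is
run as part of the test suite, not quoted from anywhere.

### Variable importance and the two-pass refit

Importance is a depth-weighted split frequency: for depths 1–4, the share
of depth-$d$ splits made on a variable is weighted by $d^{-\text{decay}}$
(default decay 2) and the scores are normalized to sum to one. The forest
is fit twice: the first pass on all covariates, then a refit on covariates
whose importance is at or above `importance_multiplier` (default 1) times
the mean importance. This lets the second forest spend its splits on the
variables that matter in low-signal data. Multiplier 0 disables filtering
(single pass, recorded in the model and the run log); if the filter would
discard everything, the single most important covariate is kept with a
warning. Note the filter operates on the one-hot columns, so an individual
level of a categorical covariate can be retained or dropped.

A caveat worth stating plainly: with a weak effect step (a few percentage
points) competing against many continuous covariates, the split criterion's
maximum over hundreds of candidate thresholds is usually noise, a binary
modifier offers only one threshold, and the filter can drop the true
modifier. This is a property of threshold-exhaustive splitting in any
implementation, not a defect of the filter, but it means a non-significant
heterogeneity result on ~2500 patients is the expected outcome unless the
effect modification is strong.

## Aggregation: AIPW scores

Per-patient doubly robust scores

$$\Gamma_i = \hat\tau_i^{\text{oob}}
  + \frac{D_i\,(Y_i - \hat m(x_i, 1))}{e}
  - \frac{(1-D_i)\,(Y_i - \hat m(x_i, 0))}{1 - e}$$

use the design propensity $e$ (0.5 under 1:1 randomization; an option
estimates it for observational use) and arm-specific outcome predictions
$\hat m(x, d)$. We take $\hat m$ from the forest's own honest per-leaf arm
means, aggregated out-of-bag — the outcome model is thereby fit honestly on
the same subsamples as the effects, with no auxiliary fits. Group ATEs are
means of $\Gamma_i$ over a subgroup with $SE = SD(\Gamma)/\sqrt{n_g}$; these
ignore estimation error in $\hat m$ and $\hat\tau$ beyond the score
variance, which is standard AIPW practice and a documented limitation.
Group estimates decompose exactly: over any partition the size-weighted
mean equals the overall estimate.

## The omnibus calibration/heterogeneity test

The scores are regressed, without intercept, on the mean out-of-bag
prediction $\bar\tau$ (a constant) and the demeaned prediction
$\hat\tau_i - \bar\tau$, with HC3 heteroskedasticity-robust standard
errors. Coefficients of 1 mean, respectively, that the mean forest
prediction is correct and that the heterogeneity estimates are well
calibrated; a positive second coefficient is evidence of real
heterogeneity, so its one-sided p-value doubles as a heterogeneity test.
This best-linear-predictor construction is the one consistent with both
parameters targeting 1. Degenerate cases are handled explicitly: constant
predictions make the heterogeneity coefficient non-estimable (returned as
`NA` with p = 1), and a zero mean prediction drops the mean regressor.
Under a homogeneous-effect design (n = 1000, 200 trees, 200 replicates) the
one-sided rejection rate at the 5% level sits near nominal; the type-I
study runs in the test suite.

## The parametric comparator

For each subgroup indicator $G$ the baseline fits
$\text{logit}\,P(Y{=}1) = \beta_0 + \beta_G G + \alpha_1 D + \alpha_2 DG$
by maximum likelihood. An intercept is included — without it this is not
the standard subgroup logistic model. Effects are obtained by recycled
predictions (G-computation): predict every patient under each $(d, g)$,
then contrast; on this saturated model the subgroup total effect equals the
raw contingency-table risk difference, which the tests exploit as an exact
oracle. Uncertainty comes from a seeded case-resampling bootstrap of the
whole fit-and-contrast procedure with percentile intervals (percentile
rather than BCa: simpler, and adequate here). Complete separation (a
$(G,D)$ cell with all or no events) is a hard error naming the cell.
Multi-level subgroups (quintiles, vasopressor type) are handled one level
at a time as one-vs-rest fits, mirroring per-level forest-plot rows.

## Describing the CATEs

Three complementary summaries of the fitted individual effects:

* **Second-stage OLS** of $\hat\tau_i$ on the covariates — the linear,
  no-interaction view; its $R^2$ says how much of the fitted heterogeneity
  is linearly explainable.
* **Pruned CART** (`rpart`) on $\hat\tau_i$ with complexity parameter
  `cp = 0.2` by default: a split is kept only if it improves the
  root-relative error by at least `cp` (this is `rpart`'s convention, which
  we adopt since the convention is otherwise ambiguous); an optional cap
  re-prunes along the fitted complexity sequence to at most `max_leaves`
  subgroups. The fit is unweighted by default with an optional
  inverse-variance weighting argument. On low-heterogeneity data cp = 0.2
  legitimately prunes to the root — a root-only tree is a finding, not a
  failure.
* **Best tree from a regression forest** (`ranger`): fit `num_trees`
  regression trees on $\hat\tau_i$ with minimum leaf size `minN`, then keep
  the member tree whose predictions best correlate ($R^2$) with the
  ensemble's — the single tree most representative of the forest. The
  `minN` ladder 1/50/100/200 spans deep-to-coarse summaries.

For honest subgroup reporting the sample is split 50/50 (seeded; the split
fraction is our choice, stated here): trees are discovered on one half and
leaf effects re-estimated on the other as AIPW group ATEs with standard
errors. Leaves with fewer than two held-out patients per arm are flagged
not estimable rather than erroring. Both the training-sample leaf means and
the honest re-estimates are emitted, labelled, since reports sometimes show
either.

## Missing covariates

Baseline covariates with missing cells (the outcome and arm are never
missing by construction) are completed by chained equations: initialize
from observed-value draws, then cycle regressions — linear with predictive
mean matching (5 donors) for continuous variables, logistic draws for
binary, multinomial draws for categorical — for 5 sweeps (m = 5 completed
datasets by default; neither value is prescribed by the source setting, so
both are documented knobs). PMM guarantees imputed values are observed
values. Estimates are pooled across imputations by Rubin's rules
($\bar Q$, $W$, $B$, $T = W + (1+1/m)B$, the standard df formula);
individual CATEs are pooled per patient id. We impute once and then
analyze, rather than re-imputing inside each bootstrap replicate — a
stated simplification.

## The synthetic generator and the validation designs

`default_covariate_spec()` reproduces the *marginals* of the emulated
trial's baseline table (age truncated at 65; chronic hypertension 45.8%;
septic shock 48.3%; categorical admission source, vasopressor type,
ethnicity, CPR; continuous severity scores). Marginals are independent by
default because only marginals are published; a Gaussian-copula
`score_correlation` knob correlates the severity scores when realism
matters. The predicted risk of death is *not* the proprietary prognostic
model — it is a logistic function of the scores plus noise calibrated to a
median near 0.33 and IQR near (0.15, 0.60), and is labelled synthetic. The
default treatment-effect function is a step in chronic hypertension
(−0.06 vs −0.02 on the risk scale); potential-outcome risks are clipped to
[0.001, 0.999] with clip counts reported. Quintile subgroups assign
boundary ties to the lower quintile (a tie rule we fixed, since none is
prescribed). What passing tests on these data do *not* show: performance
under correlated covariates, non-logistic risk surfaces, informative
missingness, or any joint-distribution feature of the real trial.

The named validation designs are deliberately small and transparent:

* `design_step_cate()` — the two-level effect above with a *constant*
  control-arm risk of 0.15. The risk was fixed by a power argument before
  any estimator ran: parameter recovery is only a meaningful test when the
  truth is identifiable, and at n = 4000 the oracle difference-in-means
  between the two groups has SE ≈ 0.021, so the 0.04 step is resolvable
  (z ≈ 1.9); at a 35% control risk even the oracle misorders the groups
  roughly one run in ten and a recovery criterion would be testing the
  weather, not the estimator.
* `design_modifier_retention()` — one strong modifier (−0.25 vs 0) among
  8 pure-noise covariates, to verify the importance filter keeps a genuine
  modifier; the effect is strong because this design tests the filter
  mechanism, not low-signal behaviour.
* `design_homogeneous()` — constant effect over a varying risk surface,
  for type-I error of the heterogeneity test.
* `design_smooth_cate()` — effect decreasing smoothly in age, for CI
  coverage.

Problem sizes used by the test suite (n up to 4000, 200–1000 trees, 200
replicates for the type-I study, 500 for the bootstrap-coverage study) are
the package's validation scale: large enough for the asymptotics the
estimators rely on to be visible, small enough to run routinely.

## Numerical choices and degenerate inputs

* Candidate thresholds are midpoints of consecutive distinct values; a
  midpoint that fails `lo < t <= hi` in floating point is skipped.
* Split ties: lowest covariate index, then smallest threshold.
* No valid split at the root yields a single-leaf tree (not an error);
  an arm absent from a subsample is an error.
* Unseen categorical levels at prediction time encode as all-zero
  indicators and follow the corresponding branch, with a warning.
* The variance estimate is floored at zero; `ci_group_size = 1` disables
  interval estimation rather than fabricating one.
* Forests, imputations, bootstraps and the pipeline derive per-stage seeds
  from one global seed by hashing stage labels, so no two stages share a
  stream and byte-identical reruns are a tested invariant.

## Known limitations

Group standard errors ignore first-stage estimation error; the forest's
variance floor can produce degenerate intervals in very low signal; the
importance filter can discard weak true modifiers (see above); tuning is
fixed defaults plus an optional user grid, not an automated tuner; no
survival outcomes, clustering, overlap weighting, or rank-weighted
heterogeneity metrics. The parametric baseline deliberately adjusts for
nothing beyond $(G, D, DG)$.
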