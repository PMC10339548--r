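---
title: "Stacked ordinal nomograms: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked ordinal nomograms: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nomostack)
```

This vignette is the package's account of the science it implements: the
ordinal model, the stacking and feature-mapping construction, the
synthetic-cohort generator, and the numerical and design decisions that
were genuinely open.

## The ordinal outcome and the proportional-odds model

The outcome is a three-level ordered risk class (1 = low, 2 =
intermediate, 3 = high). The package's regression workhorse is the
cumulative-logit (proportional-odds) model

$$P(Y \le k \mid x) = \sigma(\theta_k - x^\top \beta), \qquad k = 1, 2,$$

with strictly ordered thresholds $\theta_1 < \theta_2$ and slopes $\beta$
shared across levels, so a positive coefficient means higher risk and
$e^{\beta_j}$ is the common cumulative odds ratio per unit of covariate
$j$. "Ordinal logistic regression" admits several variants
(adjacent-category, continuation-ratio); the cumulative-logit form is the
one nomogram practice is built on, and is what `fit_olr()` implements.

**Fitting.** The log-likelihood
$\sum_i \log\{\sigma(\theta_{y_i} - \eta_i) - \sigma(\theta_{y_i-1} -
\eta_i)\}$ (with $\theta_0 = -\infty$, $\theta_K = +\infty$,
$\eta_i = x_i^\top\beta$) is maximized by BFGS from a zero start with the
analytic gradient, keeping thresholds ordered through the
reparameterization $\theta_2 = \theta_1 + e^\delta$. The BFGS solution is
then Newton-polished in the natural $(\beta, \theta)$ parameterization,
using the observed information obtained by central finite differences of
the analytic gradient, until the gradient infinity norm is below $10^{-6}$
(usually it ends far below; 25 Newton iterations are allowed). The
covariance is the inverse observed information; tests cross-check
coefficients, thresholds and standard errors against `glm(family =
binomial)` in the two-level reduction and against `MASS::polr` at three
levels.

**Separation.** A monotone likelihood (quasi-separation) makes
coefficients drift to infinity. Because covariates here are min–max
normalized, a *large* coefficient alone is not evidence of separation: a
biomarker whose clinically relevant variation occupies a sliver of its
recorded range (PSA, recorded up to 1000 ng/mL but discriminative below
~50) legitimately earns $|\beta| \approx 100$ per unit of its normalized
scale. `fit_olr()` therefore flags separation only when a coefficient is
both large on the standardized scale ($|\beta_j|\,\mathrm{sd}(x_j) > 10$)
and carries no Wald information (its standard error is of the same order
or larger), which is the actual signature of a flat likelihood direction.

## Preprocessing

* **Truncation** mirrors how laboratories record out-of-range values:
  assay ceilings as upper caps (PSA at 1000 ng/mL) and detection limits as
  lower floors (ALT at 5 U/L, interleukin-6 at 1.5 pg/mL, interleukin-1β
  at 5 pg/mL). The operation is idempotent and configured by data
  (`cap_rule`), not code.
* **Min–max normalization** maps each feature to $[0,1]$. Constant
  features map to 0 with a warning instead of being dropped, so the
  selection stage can discard them on its own evidence. By default the
  scaler is fitted on the full cohort before splitting — replicating the
  common single-pass preprocessing of retrospective studies, which leaks
  test-set ranges into training; `pipeline_config(fit_scaler_on_train =
  TRUE)` gives the leak-free variant (scaler and lasso fitted on the
  training portion only, held-out values clipped to $[0,1]$).
* **Splitting** is stratified by risk group by default, each group
  contributing `round(n_g * fraction)` (half-up) test patients: a
  197-patient cohort with groups 59/48/90 at fraction 0.2 yields exactly
  12/10/18 test patients and a 157/40 split. Plain random splitting is a
  flag away.

## Feature selection

The ordinal outcome is coded 1/2/3 and a squared-error lasso path is
fitted (via coordinate descent in glmnet, convergence threshold
$10^{-12}$) over a log-spaced grid spanning four decades below the
smallest all-zero penalty. Treating the ordinal code as Gaussian is a
deliberate simplification: it makes the cross-validated objective the MSE
curve practitioners select on, and a KKT diagnostic
(`lasso_kkt_violation`) verifies path optimality to $10^{-6}$ at every
grid point. The default selection rule is the one-standard-error rule
(parsimony); `rule = "min"` is available, and the choice is recorded in
every run manifest. Ties at exactly zero are broken at magnitude
$10^{-10}$.

## Base learners and stacking

Five tabular classifiers — radial-kernel SVM (e1071), CART (rpart),
random forest (randomForest), gradient-boosted trees (xgboost), and a
SAMME AdaBoost implemented in the package over depth-3 rpart trees — are
trained under stratified 10-fold cross-validation. Each training patient
receives exactly one *out-of-fold* probability vector per model, from a
fold model that never saw that patient; the refit-on-everything model is
kept for test-time prediction. Library defaults are used for
hyperparameters throughout; no tuning is performed.

Two decisions here were genuinely open:

* **Scalarization.** A 3-class probability vector must become one
  nomogram-axis value per model. The default is the expected ordinal
  level $MV = 1p_1 + 2p_2 + 3p_3 \in [1, 3]$, which preserves ordering
  information and gives each model a single monotone axis;
  `scalarization = "prob_high"` uses $p_3$ instead.
* **Out-of-fold vs in-sample meta-features.** Stacking on out-of-fold
  predictions limits the optimism that in-sample stacking incurs
  (in-sample stacked training AUCs approach 1 because flexible base
  learners memorize their training labels). Out-of-fold is the default;
  `in_sample = TRUE` reproduces the optimistic variant.

**Feature importances.** Each model contributes a nonnegative importance
vector over the clinical features normalized to sum 1 — a simplex vector,
which the feature-mapping identity below requires. Tree models use their
native impurity/gain attributions; the SVM, which has none, falls back to
permutation importance (10 repeats, increase in out-of-fold log-loss,
negative raw values floored at zero before normalizing; if no permutation
changes the loss the vector is uniform).

## The feature-mapping algorithm and the stacked nomogram

The ordinal regression on the retained meta-features defines a model-axis
nomogram. To express it in clinical features, each patient's axis values
are redistributed along the importance weights:

$$CF_i = \sum_{j} FI_{i,j}\, MV_j,$$

over the retained models $j$. Since each importance column sums to one,
$\sum_i CF_i = \sum_j MV_j$ exactly (exchange the sums) — a conservation
identity tested to $10^{-12}$ on random instances: the mapping relabels
axis mass, it neither creates nor destroys it.

The mapping defines *values*, not coefficients, so the clinical-feature
nomogram requires a fit on the $CF$ matrix. With $M$ features and $N < M$
retained models, $CF = MV\,FI^\top$ has rank at most $N$: the likelihood
is flat along the null space and individual coefficients are not
identified, although every patient's linear predictor is. The default
refit therefore adds a small ridge penalty ($10^{-4}$ on $\|\beta\|^2$)
to pin a representative solution; predictive scores are insensitive to
this choice, and an analytic alternative
($\beta_{\text{clinic}} = FI\,\beta_{\text{ML}}$, thresholds recalibrated
by a one-covariate fit on the induced score) is available via
`method = "analytic"`. On synthetic data the clinical-feature scores track
the model-axis scores with Spearman correlation above 0.95.

## Nomogram geometry, scores and cutoffs

Axis $i$ maps its value affinely to points
$100\,\beta_i (x - r_i)/\Delta$, where $r_i$ is the protective end of the
axis range (low end for $\beta_i > 0$, high end otherwise) and
$\Delta = \max_i |\beta_i| (hi_i - lo_i)$, so points are nonnegative and
exactly one axis spans 100. Total points and the linear predictor are
affine images of one another; the round trip is exact to $10^{-9}$ by
construction and tested as such. The "predictive score" reported by
`score()` is the linear predictor $\eta$ (total points are co-reported):
published tripartite cutoffs of a few units (e.g. 2.24 and 6.00) are
plausible on the $\eta$ scale, not on a 0–100+ points scale.

`derive_cutoffs()` grid-searches cutoff pairs (candidate values are
midpoints between consecutive distinct scores, thinned to at most 200)
maximizing macro-averaged per-class recall; ties resolve to the smaller
lower cutoff, then the smaller upper cutoff. The boundary convention is
closed on the lower class (`score <= c1` is low). Axis ranges default to
observed training min/max; out-of-range values are clipped with a warning.

## Evaluation panel

* **Confusion metrics** are one-vs-rest per class, macro-averaged;
  classes absent from the truth are skipped and the average renormalized.
* **AUC** is the Mann–Whitney statistic with midrank tie handling,
  verified against exhaustive pair counting; the multiclass summary is
  macro one-vs-rest, with the ordinal low-vs-rest dichotomization
  available to match the decision-curve analysis.
* **DeLong's test** for two correlated AUCs is implemented from the
  structural components (placement values), exposing the variance of the
  AUC difference directly; it is cross-checked against pROC and against a
  bootstrap of the AUC difference. Identical score vectors short-circuit
  to $z = 0, p = 1$; tied degenerate scores are an error.
* **Calibration** uses equal-count bins and the standard bootstrap
  optimism recipe (refit on resample, evaluate on resample and original,
  subtract the mean difference). With flexible learners that memorize
  training rows (random forests), bootstrap optimism is known to be
  underestimated because resampled rows reappear in the original data;
  the tests therefore demonstrate the optimism direction with an overfit
  logistic model.
* **Decision curves** use
  $NB(t) = TP/n - FP/n \cdot t/(1-t)$ against treat-all and treat-none
  for the low vs {intermediate, high} dichotomization.
* **Bootstrap CIs** are percentile intervals from class-stratified
  resampling, $B = 1000$ by default.

## The synthetic-cohort generator

No patient-level data of this kind is publicly deposited, so
`builtin_profile()` encodes per-risk-group marginal means and SDs for the
full 41-feature panel (group weights 47/38/72), and `generate_cohort()`
draws patients group-first, then features. Design choices:

* **Families.** Skewed serum biomarkers (PSA, alkaline phosphatase,
  lactate dehydrogenase, creatinine, ALT, the interleukins, TNF-α) use
  moment-matched lognormals — a plain normal with SD 312.9 around mean
  199.6 (high-risk PSA) would produce many negative concentrations.
  Cellular percentages and counts use normals clamped at physiological
  floors (0) and caps (100 for percentages).
* **Measurement truncation** (PSA ceiling, detection floors) is applied
  during generation, mirroring how the recorded data would look. Where a
  floor carries real mass (interleukin-1β at 5 pg/mL), the printed
  moments being emulated are themselves post-truncation, so the
  generator's marginals match them only approximately; moment-recovery
  tests are run on features whose floors carry negligible mass.
* **Joint structure.** The profile provides marginal moments only. A
  Gaussian copula accepts an optional feature-correlation matrix, but none
  is invented silently: the default draws features independently within
  group. Group separation — the signal every downstream test relies on —
  is inherited from the printed group means, not invented.

Consequently, passing end-to-end tests show that the pipeline recovers
structure *of this synthetic form* (independent, mostly unimodal
marginals with group shifts); they do not certify performance on real
cohorts with correlated immune phenotypes, batch effects or label noise.

## Problem sizes and numerical choices

The test suite runs the full pipeline at $n = 1000$ (and smaller smoke
sizes), ordinal-regression recovery at $n = 5000 \times 100$ replicates,
and null-calibration checks at 200–500 replicates; the acceptance script
uses $n = 1000$ for the end-to-end run and $50 \times 2000$ for recovery.
These sizes were chosen to make Monte-Carlo noise small relative to the
asserted margins. Other numerical constants: optimizer gradient tolerance
$10^{-6}$ (Newton polish targets $10^{-7}$); lasso convergence
$10^{-12}$ and zero-coefficient threshold $10^{-10}$; probability rows
from learner back ends renormalized to sum exactly 1 (library outputs are
accurate only to ~$10^{-7}$); nomogram serialization at 17 significant
digits for bit-exact round trips.

## Known limitations

* The proportional-odds assumption is imposed, not tested; no
  partial-proportional-odds fallback is provided.
* Base-learner hyperparameters are library defaults; no tuning, no
  probability calibration of base models.
* The ridge-identified clinical-feature refit makes individual axis
  attributions depend (weakly) on the penalty; scores do not.
* Odds ratios are reported per unit of the model's input scale (min–max
  normalized features, or expected-rank meta-features); comparing them
  across differently scaled analyses requires rescaling.
* The synthetic generator emulates marginal structure only (see above).
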