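---
title: "Estimating individualized treatment rules by Outcome Weighted Learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating individualized treatment rules by Outcome Weighted Learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

owlitr estimates an optimal individualized treatment rule (ITR) for a
two-arm randomized trial — here framed as allocating patients between
telehealth and in-person delivery of a trauma-focused psychotherapy,
with the 6-month PCL-5 symptom score (0–80, lower is better) as the
outcome — and quantifies how much the rule improves on one-size-fits-all
policies.  This vignette explains the model, the estimation choices, the
synthetic validation design, and the numerical decisions, in that order.

## The estimand and the estimator

A linear decision rule over six standardized prescriptive factors
$z = (\text{age}, \text{white}, \text{disability}, \text{rural},
\text{low income}, \text{baseline symptoms})$ is

$$d(z) = I(\beta_0 + \beta^\top z \ge 0),$$

with $d = 1$ read as telehealth and $d = 0$ as in-person; the tie at a
score of exactly zero goes to telehealth, matching the indicator
convention in which the rule is reported.  The value of a rule,
$V(d) = E[Y \mid \text{everyone treated per } d]$, is what we want to
minimize (lower symptom scores are better).

Outcome Weighted Learning (OWL) turns value optimization into weighted
classification: under randomization, maximizing value is equivalent to
weighted 0–1 classification of the *received* arm with subject weights
proportional to the (transformed) outcome over the propensity of the
received arm.  With missing outcomes handled by inverse probability
weighting, the subject weight is

$$w_i = \frac{B_i \, r_i}{\pi_i}, \qquad
  B_i = 80 - Y_i,\quad r_i = \frac{R_i}{\hat p_i},\quad
  \pi_i = \widehat P(A = A_i),$$

where $R_i$ indicates an observed outcome, $\hat p_i$ is the fitted
observation probability, and $\pi_i$ the empirical frequency of the arm
actually received.  The hinge surrogate of the weighted 0–1 objective
with a ridge penalty gives the convex program solved by `fit_owl()`:

$$\min_{\beta_0, \beta}\;
  \frac1n \sum_i w_i \max\{0, 1 - a_i(\beta_0 + \beta^\top z_i)\}
  + \lambda \lVert \beta \rVert^2,
  \qquad a_i = 2A_i - 1,$$

with the intercept unpenalized (penalizing it would bias the rule toward
an arm-ratio artifact).

Choices worth making explicit:

* **Reward transform.** $B = 80 - Y$ anchors at the instrument's printed
  maximum so rewards are nonnegative and larger-is-better.  Vanilla OWL
  is known to be sensitive to the location of the reward: the common
  offset $E[B]$ enters every subject's weight, and when it dominates the
  between-arm differences the linear hinge minimizer can be pulled away
  from the best linear rule (see *Known limitations*).  Residualized or
  augmented OWL variants that remove this sensitivity are deliberately
  out of scope.
* **Propensities.** Empirical arm frequencies rather than the nominal
  0.5 — matching the realized randomization (e.g. a 62/60 split gives
  0.5082) — and configurable.
* **Tie convention.** Score 0 assigns telehealth, exactly the reported
  indicator $I(\text{score} \ge 0)$.

## Missing outcomes

About a third of 6-month outcomes are missing in the emulated study.
The analysis is intention-to-treat: every randomized participant stays
in the sample, and subjects with missing outcomes get weight zero in
both the OWL fit and the value estimator, with the selection corrected
by inverse-probability-of-observation weights.  The observation model is
a main-effects logistic regression of the observed-indicator on the six
standardized factors plus the arm — main effects because that is the
minimal faithful form when only the covariate set is known — fitted by
maximum likelihood (`stats::glm`, deviance tolerance $10^{-10}$, at most
100 iterations).  Quasi-separation falls back to a ridge-regularized fit
(`glmnet`, $\alpha = 0$) with a warning.  Fitted probabilities are
floored at 0.05 — a standard positivity safeguard bounding the weight
variance — and every floor event is reported.  Weights are unstabilized
$1/\hat p$; the Hájek normalization below absorbs the difference a
stabilizing numerator would make.

## Value estimation and inference

The value of any rule is estimated by the Hájek (normalized) inverse
probability estimator

$$\hat V(d) = \frac{\sum_i r_i\, Y_i\, I\{A_i = d(z_i)\} / \pi_i}
                   {\sum_i r_i\, I\{A_i = d(z_i)\} / \pi_i},$$

chosen over the unnormalized Horvitz–Thompson form for its invariance to
outcome location shifts and lower variance.  With complete outcomes and
a fixed-arm rule it reduces *exactly* to that arm's sample mean.

The headline report contrasts $\hat V(d_{\text{opt}})$ against the two
fixed policies.  Because a rule estimated and evaluated on the same
subjects is optimistically biased, the rule's own value is taken from
*held-out* assignments: the same leave-one-out (or k-fold) loop that
tunes the penalty also produces, for each subject, an assignment from a
fit that excluded them, and $\hat V(d_{\text{opt}})$ aggregates those.
This matches the role of the jackknife as an out-of-sample performance
estimate, and under a null (no-interaction) generator it removes the
systematic favorable bias an in-sample value would show.  The fixed-arm
comparators carry no overfitting and are estimated in-sample.

Standard errors come from the bootstrap (default $B = 1000$), resampling
subjects with replacement *stratified by arm* to condition on the
realized randomization ratio.  Within each replicate the observation
model, the weights and the values are re-estimated while the rule — its
held-out assignment vector — is held fixed; re-running the tuned OWL fit
inside every replicate would be computationally disproportionate, and
the interval is understood as inference on the value parameters given
the rule.  Intervals are Wald, $\pm 1.96 \cdot \text{SE}$: bootstrap
percentile intervals are a reasonable alternative, but the symmetric
form is what the reported intervals identify.

## Penalty selection

The ridge penalty is tuned by minimizing the cross-validated Hájek value
(on the outcome scale, so smaller is better) over a grid, with ties
broken toward the heavier penalty.  The default is the jackknife —
leave-one-out — which suits small trials; `method = "kfold"` (optionally
with `repeats` averaged splits, which damps split-randomness in the
selection) is provided for the simulation studies at $n$ in the
thousands, where $n$ refits per candidate are disproportionate.

The grid is 13 log-spaced candidates $2^{-8} \dots 2^{4}$ *in units of
the mean positive OWL weight*.  The hinge term scales with the weights —
order of the outcome range — so a grid fixed in absolute units would
span different shrinkage regimes on different outcome scales; after
scaling, the smallest candidate is effectively unregularized and the
largest collapses the rule to the weighted-majority arm on any dataset.

## The synthetic validation design

No individual-level data accompany the emulated study, so validation
rests on a seeded generator (`synthetic_config()`) with known ground
truth.  Defaults reproduce the study's reported marginal structure:

* age $\sim N(42.80, 11.61^2)$ truncated to $[18, 90]$ — with the
  truncated distribution's location and scale solved numerically so the
  *post-truncation* mean and SD hit the targets (naive truncation at 18
  would shift the mean by about +0.5 years);
* indicator prevalences 0.279 (white), 0.639 (disability), 0.344
  (rural), 0.492 (low income — the five income brackets below
  USD 35,000 out of 120 reporting participants);
* baseline score $\sim N(52.74, 12.81^2)$ clipped to $[0, 80]$ (the
  clip shifts the mean by only $-0.08$, left unadjusted);
* covariates independent: only marginals are reported for the real
  data, and a dependence structure would be invented detail (a
  correlation hook is the natural config extension);
* outcomes $Y = m(z) + A\,\tau(z) + \varepsilon$ clipped to $[0, 80]$,
  with linear surfaces on the population-standardized scale so the true
  optimal rule is itself linear — the estimator's hypothesis class,
  which makes regret recovery a fair test;
* residual SD 21 — calibrated once by Monte Carlo so the marginal
  6-month SD lands near the reported 21.84 after clipping;
* missingness MAR through a logistic model on covariates and arm (not
  MCAR — the IPW step is only meaningful when missingness is
  covariate-driven), with slopes loading on baseline severity and age
  (completers are healthier at baseline, a plausible follow-up
  mechanism, inducing a downward complete-case bias of a couple of
  points) and the intercept calibrated so about 35.25% of outcomes are
  missing;
* the default interaction surface mirrors the access-to-care reasoning
  behind the prescriptive factors — telehealth relatively better for
  rural, disabled and low-income subjects, relatively worse for older
  and white subjects — with a mean effect of ~3 points, consistent with
  a trial whose average arm difference is not significant.

Ground truth (`ground_truth()`, `true_policy_value()`,
`true_outcome_mean()`) integrates noise and clipping in closed form
(censored-normal mean) and covariates by Monte Carlo.  `regret()` uses
the *noise-free* clipped surfaces: the regret of the true rule is then
exactly zero, and in the single-covariate scenario the anti-optimal rule
has closed-form regret $c\sqrt{2/\pi}$ (that scenario sets the age
marginal to mean 50, SD 8, so its standardized value is an effectively
untruncated standard normal).

What passing on this generator does *not* show: behavior under
covariate dependence, non-linear effect surfaces, outcome distributions
other than clipped Gaussian, or missingness not at random.  The
generator validates the machinery under the assumptions the analysis
itself makes, no more.

### Named scenarios

`scenario_strong_interaction()` is the rule-recovery stress test: a
sign-varying interaction with SD about 12 points and zero mean.  Its
control surface keeps 6-month symptom levels high (intercept 55), which
makes the reward $B = 80 - Y$ small on average (~25) relative to the
effect — the regime where the prescriptive signal dominates the weights.
This is a deliberate scenario-design choice: with the default symptom
level (mean ~31, so $E[B] \approx 48$), the reward offset dominates the
weights and the linear hinge fit carries an appreciable regret floor
that does not shrink with sample size (see *Known limitations*) — a
property of the estimator's surrogate loss, not of the machinery the
scenario is meant to exercise.  `scenario_null()` and `scenario_single_covariate()` cover
the no-interaction and closed-form-regret cases described above.

## Numerical choices

* **Solver.** The weighted SVM dual is solved by a compiled SMO
  algorithm with maximal-violating-pair selection and a second-order
  gain criterion, a precomputed Gram matrix, and incremental $O(n)$
  gradient updates (periodically refreshed exactly).  Stopping is
  two-fold: pair violation below $10^{-7}$, or certified relative
  duality gap — primal objective at the current representer, intercept
  profiled out exactly, minus the dual objective — below $10^{-6}$.
  The second test governs on ill-conditioned instances (small penalty,
  large boxes, rank-6 Hessian) where the absolute pair violation stalls
  far above tolerance at an iterate that is already optimal to working
  precision.  The fit is deterministic.
* **Intercept.** Unpenalized, so it is absent from the dual kernel;
  given $\beta$ it is recovered by exact minimization of the convex
  piecewise-linear profile over its breakpoints, with a flat optimal
  segment resolved to the midpoint of its extreme breakpoints for
  determinism.
* **Degenerate inputs.** All-zero weights return the zero rule (all
  telehealth by the tie convention) with a warning; a training fold
  with no usable weights does the same inside cross-validation;
  all-observed samples give the constant observation model with all
  weights 1; zero-variance covariate columns are an error (the rule
  would be unidentifiable in that coordinate).
* **Imputation.** The small amount of covariate missingness (about
  2.5% in the emulated study) is single-imputed — mode for binary,
  mean for continuous, ties to 1 — because multiple imputation would be
  immaterial at that rate and determinism simplifies testing.
* **Seeds.** All randomness flows through explicit seeds; one run seed
  fans out to per-stage child seeds through a fixed affine map
  (`derive_seed()`), so stages are individually reproducible and no
  global RNG state leaks (the caller's RNG stream is saved and
  restored).

## Interpreting a saved rule

Two ambiguities in how such rules are reported are resolved explicitly:

* The printed coefficients act on *standardized* covariates.  A future
  individual's raw values must be standardized by the training means
  and SDs before the rule is applied; serialized rules therefore embed
  their standardization parameters, and `predict`-style scoring applies
  them.  Applying the coefficients to raw values is a different rule.
* "SES" in the rule is the low-income indicator (1 = annual household
  income below USD 35,000) as defined in the preprocessing step, not an
  income scale in the opposite direction.

## Problem sizes used in the validation suite

The shipped tests run the studies at sizes chosen to keep the full
suite in the minutes range while leaving the Monte-Carlo error bands
meaningful: marginal checks at $n = 10{,}000$; estimator unbiasedness
with 1000 replicates at $n = 200$; the IPW-correction study with 500
replicates at $n = 1000$; rule recovery at $n = 2000$ with 3×10-fold
tuning; null-scenario contrasts with 200 replicates at $n = 1000$;
bootstrap coverage with 200 replicates of $B = 200$ at $n = 300$; and
the jackknife-selection study at $n = 150$.

## Known limitations

* **Reward-anchor sensitivity.**  Vanilla OWL's weights shift with any
  constant added to the reward.  Anchoring at the instrument maximum is
  principled but arbitrary among valid choices, and when the common
  reward level dominates the between-arm signal the *linear* hinge
  minimizer does not converge to the best linear rule as $n$ grows —
  penalty tuning then navigates a bias-variance trade-off rather than
  vanishing bias.  Residualized/augmented OWL removes this at the cost
  of an outcome model; it is out of scope here.
* The bootstrap conditions on the estimated rule (held-out assignment
  vector); it does not propagate rule-estimation uncertainty.
* Linear kernel only, two arms only, no doubly robust augmentation, no
  multiple imputation of outcomes.
* The generator's defaults are stipulations consistent with reported
  marginal summaries, not estimates of the real data's joint
  distribution.
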