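---
title: "Risk-stratified heterogeneous treatment effects by matching and smoothing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-stratified heterogeneous treatment effects by matching and smoothing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htematch)
```

## The problem

A neuroprotective co-treatment given alongside intravenous thrombolysis for
ischemic stroke may help some patients much more than others. A natural
effect modifier is the patient's baseline risk of hemorrhagic
transformation (HT) — bleeding into the infarct after reperfusion — which
can be graded on admission with simple clinical point scores. `htematch`
implements the full analysis chain for asking, in a two-arm cohort, *how
does the treatment effect vary across HT-risk strata?*:

1. clinical risk scoring (DRAGON, SEDAN, HTI) from on-admission data;
2. binary logistic models of each endpoint on treatment plus a score, with
   a complete postestimation battery for choosing among candidate scores;
3. conditional marginal effects of treatment at each score level;
4. propensity-score kernel matching for ATE/ATT/ATC/NATE;
5. generalized ordered logistic regression of the day-90 modified Rankin
   Scale (mRS) under proportional and partial-proportional odds, with the
   Brant test;
6. subgroup-as-"study" meta-analytic heterogeneity (fixed and REML random
   effects, I²/H², Egger test);
7. the matching–smoothing heterogeneous-treatment-effect (HTE) estimator:
   unit-level matched effects smoothed against the propensity index.

Everything runs on synthetic cohorts from the built-in generator or on the
built-in grouped fixture, a 238-patient two-arm MCA-stroke cohort
reconstructed exactly from published arm-by-HTI tables
(`cerehetis_cohort()`). The fixture carries the three binary endpoints
(symptomatic HT, any HT, favorable functional outcome); unit-level mRS
values are not recoverable from published stratum medians, so
mRS-dependent stages are exercised on synthetic data only.

## Risk scores

Each score is an additive sum of banded components; all cut-points are
implemented literally and exercised on both sides by the test suite:

* **DRAGON** (0–10): HMCA sign / ASPECTS < 10 (2/1/0), pre-stroke mRS > 1,
  age (≥80 = 2, 65–79 = 1), glucose > 8 mmol/L, onset-to-treatment time
  strictly > 90 min, NIHSS bands (>15 = 3, 10–15 = 2, 5–9 = 1). Non-integer
  ages are floored; treating exactly 90 minutes as 0 points is a documented
  reading of the ">90 min" band.
* **SEDAN** (0–6): glucose bands implemented as (8.0, 12.0] = 1 and
  (12.0, ∞) = 2 on the measured value without rounding, ASPECTS < 10, HMCA
  sign, age > 75, NIHSS ≥ 10.
* **HTI** (0–8): ASPECTS bands (10–7/6–5/4–3/2–0 = 0/1/2/3), NIHSS bands
  (0–11/12–17/18–23/>23 = 0/1/2/3), HMCA sign, atrial fibrillation on ECG.
  Risk is graded low (HTI = 0), moderate (HTI = 1), high (HTI ≥ 2).

## Logistic models and the postestimation battery

`fit_logit()` fits the Bernoulli likelihood by IRLS (relative tolerance
1e-10, max 100 iterations), always on unit records — frequency weights are
expanded first — so the reported log-likelihood, deviance = −2·logL, AIC
and BIC are on the unit-level scale regardless of whether the data arrived
grouped. Perfect separation is detected and raised as an error rather than
silently penalized: the intended models (treatment plus one low-dimensional
score) do not need penalization, and a quietly penalized fit would be
misleading in this setting.

The battery in `postestimation()` mirrors standard practice: a link test
(refit on the linear predictor and its square), Box–Tidwell augmentation
x·ln(x) per continuous term with a configurable +1 shift inside the
logarithm for score values of zero (the shift is reported in the output),
Hosmer–Lemeshow calibration with bins cut at the order statistics
⌈jn/g⌉ of the fitted probabilities — ties share a bin, so with nine
distinct covariate patterns ten requested bins collapse to eight and
df = 6 — mean variance inflation factor, likelihood-ratio tests, McFadden /
Cox–Snell / Nagelkerke pseudo-R², AIC/BIC, AUC with DeLong intervals, and a
DeLong paired test for AUC differences. Romano–Wolf stepdown adjustment
uses the pairs bootstrap (1,000 resamples by default, seeded): each
resample refits the model family, collects treatment z-statistics centered
at their full-sample values, and the max-T stepdown yields adjusted
p-values that dominate the raw ones.

`conditional_margins()` reports per-arm probabilities at each score level
with intervals formed on the logit scale (hence respecting (0, 1)) and the
treated-minus-control contrast with a delta-method standard error. The
Šidák correction raises the interval level to 1 − (1 − α)^(1/m); by
default m counts the intervals produced by the call, and `family_size`
lets a multi-outcome table use its full interval count, which is the
convention the published probability tables follow.

## Ordered outcomes

`fit_ordered()` maximizes the cumulative-logit likelihood
P(Y > c_j | x) = logit⁻¹(α_j + x'β_j) with analytic gradients (BFGS), with
β_j shared across cutpoints under proportional odds or freed per cutpoint
for a chosen subset of terms under partial proportional odds. Relaxed fits
can imply negative category probabilities at extreme design points — a
known pathology of the parameterization — and the package clips them for
reporting while flagging the fit. Which terms to relax is user-specified,
defaulting to all terms, since per-term Brant p-values are the natural
screen. The Brant test fits one binary logit per cutpoint and Wald-tests
slope equality using the full cross-cutpoint covariance; its df is
(number of tested terms) × (J − 2). The proportional fit is cross-checked
in the tests against an independent ordinal ML routine.

## Kernel matching and the matching–smoothing estimator

The propensity model is a logit of treatment on the risk score; matching
operates on its linear predictor (the log-odds index). On a randomized
cohort this index is nearly degenerate — on the fixture its whole range is
about 0.026 — and that degeneracy drives the numerical design:

* **Matching.** The counterfactual for each unit is the
  Epanechnikov-weighted mean of opposite-arm outcomes over the index
  (degree-0 kernel matching, with replacement, no caliper). The automatic
  bandwidth is the rule of thumb 2.34·min(sd, IQR/1.349)·n^(−1/5),
  floored at the index range, so every unit's window reaches donors across
  the support even when the index barely varies and no stratum is left
  matching into an empty donor pool.
* **Smoothing.** Unit effects d_i (treated: own outcome minus matched
  control mean; controls: matched treated mean minus own outcome) are
  smoothed against the index by a degree-1 local polynomial with
  Epanechnikov weights. The automatic bandwidth is the same rule of thumb
  floored at **twice** the index range: at exactly the range, units at one
  boundary receive zero kernel weight when the curve is evaluated at the
  other, which inflates boundary variance for no inferential gain; at
  twice the range every unit keeps positive weight (|u| ≤ 1/2) everywhere
  and the fit is genuinely near-global, which is the right regime for a
  randomized cohort where index "locality" is not identifiable below the
  stratum spacing.
* **Score-level effects.** Each observed score value maps to its fitted
  index; the curve is evaluated there, and the two-sided p-value is
  computed from the z-score implied by the 95% interval.

Two interval methods are available. The *analytic* bands are the standard
homoscedastic weighted-least-squares pointwise variance of the local
polynomial, conditional on the matched unit effects; they reproduce the
interval conventions of standard local-polynomial smoothers. The
*bootstrap* (the default; 1,000 seeded resamples, normal-based) re-runs
the whole pipeline — propensity fit, matching, bandwidths, smoothing — on
each resample and reads each resample's curve at its own score-to-index
map. The resample-specific map matters: the propensity slope on a
randomized cohort is statistically indistinguishable from zero, so the
index axis rescales (and can flip) across resamples, and evaluating at
the full-sample positions would grossly overstate the variance.

### Calibration, honestly

The two interval methods answer different questions, and the package's
null simulations (run in the test suite) show the difference plainly. The
analytic bands condition on the matched effects and ignore the strong
cross-unit correlation induced by shared counterfactuals; under a true
null they cover far below nominal and should be read as *descriptive*
bands around the smoothed curve — they are retained because they
correspond to the interval convention such smoothers print. The bootstrap
intervals are much better calibrated but still fall somewhat short of
nominal joint coverage at the extreme score levels. The residual gap is a
bias, not a variance, phenomenon: with degree-0 kernel matching, a broad
window, a risk curve that is convex in the score, and unequal arm sizes,
the matched counterfactual at the support boundary is pulled toward the
interior mean (a Jensen-type boundary bias), so the null curve acquires a
small spurious slope. Local-linear regression matching removes this bias
in principle, but it also changes the estimator away from the degree-0
kernel matching this package implements deliberately; users who need
strictly calibrated boundary inference should treat the extreme-score
effects as exploratory. This limitation is flagged here rather than
patched, because the point estimates — and the monotone risk-gradient
pattern they show on the fixture — are unaffected.

## Subgroup meta-analysis

Each score stratum is declared a "study". Binary endpoints use the risk
difference with within-study variance p₁(1−p₁)/n₁ + p₀(1−p₀)/n₀ (no
continuity correction; zero-event cells take their variance from the
other arm), pooled fixed-effects by Mantel–Haenszel with the
Greenland–Robins interval. Continuous endpoints use Hedges' g with the
small-sample factor J = 1 − 3/(4·df − 1) — the convention of the standard
meta-analysis toolchains this analysis follows, rather than the exact
gamma-function correction — pooled by inverse variance. Random effects
use REML (delegated to `metafor`), and I²/H² follow the Higgins–Thompson
typical-within-variance form I² = 100·τ²/(τ² + s²),
s² = (k−1)Σw / ((Σw)² − Σw²): on a four-stratum analysis the Q-based I²
is zero while the REML I² is not, and the typical-variance form is the
one the random-effects output of those toolchains reports. Strata with an
empty arm carry no contrast and are dropped (logged). The Egger test is
the weighted regression of effect on standard error with weights 1/v; it
is refused below three studies and warned below ten.

## The synthetic generator

`generate_cohort()` emulates exactly the structure the analysis assumes:
treatment Bernoulli with the fixture's arm fraction; per-arm HTI stratum
probabilities equal to the fixture's empirical proportions; component
covariates (ASPECTS, NIHSS, HMCA, AF) drawn uniformly over the band
decompositions consistent with the drawn HTI, so `compute_hti()`
reproduces it exactly; any HT from the treatment + HTI logit fitted to
the fixture at call time (never hard-coded); symptomatic HT drawn
hierarchically inside any HT so the marginal symptomatic-HT logit is the
fixture fit and sht ≤ any_ht holds record-wise; and mRS from a
proportional-odds model whose third cutpoint is pinned to the FFO logit
intercept and whose slopes are the negated FFO slopes, making
P(mRS ≤ 2) agree with the FFO model at every design point. The remaining
cutpoints are spaced at (−2.2, −1.0, 0, +1.0, +2.2, +3.5) around that
anchor, chosen once to give a clinically plausible spread of disability
scores. Covariates not entering the HTI (age, sex, glucose, pre-stroke
mRS, onset-to-treatment time) are drawn from plausible admission
distributions independent of the score; the generator therefore does
*not* emulate the joint distribution of DRAGON/SEDAN with HTI, nor
covariate-outcome associations beyond the score — passing tests say
nothing about real-data behavior of those joints.

`generate_null_cohort()` zeroes every treatment coefficient *and* draws
both arms' scores from the pooled stratum distribution. The second part
matters: keeping per-arm stratum proportions would leave the arm label
associated with the score, which is not a null for a matching estimator —
with no treated patients at the top stratum the matched effect there is
biased by construction, and permuting arm labels would not leave the
joint distribution invariant.

## Numerical choices

* Logit convergence: relative deviance change < 1e-10, ≤ 100 iterations.
* Ordered-logit optimization: BFGS with analytic gradient, reltol 1e-12;
  covariance from the numerical Hessian (pseudo-inverse with a warning if
  singular).
* Local-linear systems: solved directly; if the weighted design is
  numerically singular (all effective mass on one index value) the fit
  falls back to the weighted mean at that point.
* Bootstrap: pairs resampling, normal-based intervals, fixed seeds;
  resamples on which a statistic is undefined are redrawn and counted.
* Grid: 50 points over the index range plus every score's index.
* Problem sizes in the test suite were chosen to keep the whole suite in
  the tens of minutes: coefficient-recovery checks at n = 20,000–50,000,
  size/power simulations at 60–200 replicates with Monte-Carlo tolerance
  bands of 2–3 binomial standard errors, and the null-calibration study at
  100 cohorts of n = 238 with 200 bootstrap resamples each.

## Known limitations

* Analytic smoother bands are descriptive, not inferential (above).
* Boundary bias of degree-0 kernel matching at extreme score levels under
  convex risk curves; extreme-score effects should be read with care.
* The Box–Tidwell and link tests are implementation-sensitive in their
  third decimal across toolchains; agreement with published values is
  close but not exact by construction.
* Reported odds-ratio intervals are Wald; profile intervals are not
  implemented.
* The fixture carries binary endpoints only; ordinal analyses on real
  unit-level mRS data require the user's own cohort.
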