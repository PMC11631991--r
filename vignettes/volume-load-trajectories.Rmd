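---
title: "Modelling volume-load trajectories in clinical resistance training"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling volume-load trajectories in clinical resistance training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(vltraj)
```

## The scientific problem

Supervised resistance training in clinical populations — here, breast cancer
patients training on weight machines during adjuvant therapy — produces
session-to-session records of load, sets and repetitions. The product of
load and total repetitions, the **volume-load** (kg·reps), is a comprehensive
proxy for training progression: a change in any constituent moves it. Two
questions drive the analysis this package implements:

1. How does volume-load develop over training sessions, on average and with
   how much variation **between exercises**, **between patients**, and
   **between exercises within a patient**?
2. When does the trajectory **plateau**, and what does that imply for
   progression planning?

## Outcome construction

Raw logs are turned into a standardized outcome in five steps, each exposed
as its own function and assembled by `construct_outcome()`:

* **Familiarization removal** (`drop_familiarization()`): each patient's
  first two sessions are technique learning and are discarded; remaining
  sessions are indexed `t = 0, 1, 2, ...` per patient in attended order.
  Calendar gaps are ignored: `t` counts attended, included sessions. Plateau
  results are therefore on this scale; adding the two familiarization
  sessions converts to raw session counts.
* **Validity filtering** (`is_valid_session()`): a session counts only if
  more than two sets and more than eight repetitions were performed. The
  repetition condition is read as *mean repetitions per set* by default
  (consistent with a 3 × 12 prescription); a total-repetitions reading is
  available via `rule = "total"` since the prescription text admits both.
* **Overshoot equalization** (`equalize_overshoot()`): repetitions beyond 12
  inflate volume-load relative to the planned dose, so such sessions take
  the volume-load of the next valid session. A final-session overshoot has
  no successor and is capped at the 12-rep equivalent
  (`load × sets × 12`) rather than dropped, preserving series length.
  Consecutive overshoots are resolved by a backward pass.
* **Baseline standardization** (`baseline_stats()`, `standardize()`): per
  exercise, the mean and sample SD (n−1) of each patient's *first valid
  post-familiarization* volume-load define the anchors; all volume-loads
  become `z = (vl − mean)/sd`, so coefficients are in baseline-SD units
  (standardized mean differences, SMD). "Baseline" is not further specified
  in the source protocol; first-valid-session is the natural reading and is
  what the generator inverts.
* **Outlier rule** (`construct_outcome(outlier_z = )`): observations with
  `|z| > 4` within a patient × exercise series are removed and counted.
  The rule is configurable and disabled in recovery tests, where the
  generating process is known to be clean.

## The three-level growth model

For patient *i*, exercise *j*, session *t*:

z_ijt = (β₀ + u₀ⱼ + v₀ᵢ + w₀ᵢⱼ)
      + (β₁ + u₁ⱼ + v₁ᵢ + w₁ᵢⱼ)·t
      + (β₂ + u₂ⱼ + v₂ᵢ + w₂ᵢⱼ)·t² + ε_ijt

with Gaussian residual ε and zero-mean group effects: `u` per exercise, `v`
per patient, `w` per patient × exercise, each with its own SD per
coefficient. All three coefficients vary at every level — the defining
feature of the analysis, since the between-SDs *are* the quantities of
interest. A `two_level` option drops `w` for reports restricted to exercise-
and patient-level dispersion; responder classification and within-individual
variability require the three-level form.

Time enters uncentred and 0-based. This anchors the intercept at the first
included session, which is also the standardization anchor — hence a
population intercept near 0 and a patient-level intercept SD near 1 are the
expected pattern, a useful internal consistency check.

### Priors

`default_priors()` provides zero-centred normal(0, 1) priors on the
population coefficients and half-normal(1) priors on all SDs — broad on the
SMD scale — plus a `diffuse` mode (scale 10) for sensitivity reruns and a
`user_supplied` mode taking explicit locations and scales, the hook for
externally elicited evidence (e.g. meta-analytic priors). On synthetic
cohorts of the study's size, refitting with diffuse priors moves the
population means by well under 0.02 SMD, which is the package's
prior-sensitivity check.

### Sampling

The posterior is sampled with Gibbs updates via JAGS, with the `glm` module
enabled: its block samplers update the jointly Gaussian coefficient blocks
together, which removes the slow random walk between population coefficients
and group-effect means that single-site Gibbs exhibits in crossed designs.
At the full study scale (69 patients × 8 exercises × 22 sessions, ~1900
latent effects) two chains of 2400 iterations run in about two minutes with
effective sample sizes near the chain length for the population
coefficients. The first half of each chain is warmup. Split-chain R-hat and
effective sample size are computed for all reported parameters; fits warn
(or error, per `on_nonconvergence`) above the configured threshold.
Chain RNGs derive deterministically from the configured seed, so fits are
reproducible for a fixed sampler version.

Coefficients within a level are modelled as **independent**. A correlation
structure among intercept/linear/quadratic effects would need a prior over
correlation matrices jointly scaled across components whose magnitudes span
three orders of magnitude (patient intercept SD ≈ 1, quadratic SD ≈ 0.002);
with no reported correlations to target, the diagonal model is the more
robust default. The generator *can* produce correlated effects
(`corr_patient` etc.), so the cost of this assumption is testable.

## Derived quantities

All derived quantities are computed **per posterior draw** and summarized
afterwards, so each carries full posterior uncertainty:

* **95% heterogeneity interval** (`heterogeneity_interval()`):
  `β ± 1.96·σ` per draw — the range in which a single group's coefficient is
  expected with 95% probability. At the `full` level σ is the root sum of
  squares of all group SDs; this quadrature convention is the package's
  choice where the construction is otherwise underdetermined.
* **Coefficient of variation** (`coefficient_of_variation()`):
  `σ_exercise/β` per draw, reported as a percentage; median-summarized
  because the ratio is right-skewed; draws with `|β| < 1e−6` are excluded
  and counted.
* **Variance ratio** (`variance_ratio()`): `σ_patient/σ_exercise` per draw —
  "how many times larger is between-patient variation?".
* **Plateau timing** (`plateau_distribution()`): the vertex of a concave
  quadratic, `t* = −β₁/(2β₂)`. (Note the sign: with β₂ < 0 the minus sign
  is what yields positive plateaus.) 10,000 paired values are resampled with
  replacement from the joint posterior — pairing within a draw preserved,
  since β₁ and β₂ are strongly correlated — and pushed through the vertex.
  Pairs with β₂ ≥ 0 define no finite plateau; they are excluded from the
  quantiles and tallied in `prop_nonconcave` (optionally retained as
  +∞-censored), because near-zero quadratic draws make the vertex explode —
  visible in practice for exercises with nearly linear trajectories. The
  **median** is the primary summary; the mean is heavily tail-driven.
* **Per-exercise trajectories** (`exercise_trajectories()`): population +
  exercise effect (+ mean over patients of the interaction effects under a
  three-level fit) per draw.
* **Responder classification** (`classify_responders()`): a patient ×
  exercise combination is a positive responder when the posterior median of
  its total linear slope `β₁ + u₁ + v₁ + w₁` exceeds 0 (strict inequality;
  a median exactly at the threshold is negative). Only this median-sign
  dichotomy is implemented; coarser response taxonomies are framings, not
  computations.
* **Within-individual variability** (`within_individual_variability()`):
  per patient, the SD across exercises of posterior-median total slopes;
  cohort median and range; and the Pearson correlation (Fisher 95% CI)
  between a patient's spread and their mean progression, where "mean
  progression" is the mean over exercises of the posterior-median slopes.

## Model comparison and sensitivity

`fit_exercise_pair()` fits linear and quadratic patient-level models to one
exercise with identical priors, seed and sampler settings;
`compare_loo()` compares them by leave-one-out cross-validation estimated
with Pareto-smoothed importance sampling, implemented in-package: raw
importance ratios per held-out observation have their upper tail replaced by
expected order statistics of a generalized-Pareto distribution fitted to
that tail (profile-posterior shape estimate, regularized toward 0.5), then
truncated at the raw maximum. Tail shapes above 0.7 are reported and a
warning attaches when more than 10% of observations are affected. The
implementation is validated against simulated Pareto tails with known shape
and against the analytic LOO of an iid normal model.

`half_frequencies()` counts load progressions/reductions/holds between
consecutive sessions, split at scheduled session 12 of 24 — the calendar
midpoint, not the attended midpoint, because the intervention is defined by
schedule. An excess of second-half reductions is the data-level signature of
a flattening trajectory. `sensitivity_refit()` refits the model on patients
meeting ≥50% and ≥75% attendance to check for attrition-driven bias.

## Progression planners

`classic_progression()` compounds the load by a fixed percentage,
`initial·(1+pct)^n`. `corrected_progression()` implements the
decay-corrected alternative: the first increment is `pct` of the initial
load and each later *absolute* increment is the previous one shrunk by
`decay`. The decay is applied to the previous increment (geometric decay),
not to the initial increment nor as a percentage of the current load: of
these readings, only geometric decay of the absolute increment reproduces
the 61.5 kg endpoint of the 50 kg / 5% / 4%-decay / 5-progression worked
example (percentage-of-current-load compounding gives 62.7 kg). Arithmetic
is unrounded internally; rounding is presentation-only.

## The synthetic-data generator

Trial-level training logs are not deposited, so every downstream stage is
exercised on synthetic cohorts from `generate_standardized()` (SMD scale)
and `generate_raw_log()` (kg scale, via inversion). The generator *is* the
model: group effects drawn at configured SDs (correlations configurable,
identity by default), Bernoulli attendance per scheduled session, Gaussian
residual noise. Defaults are the study conditions:

* 69 patients, the trial's eight core machine exercises, 24 scheduled
  sessions;
* population coefficients (0.049, 0.093, −0.002) and exercise/patient SDs
  (0.047, 0.043, 0.002)/(1.007, 0.155, 0.008) — the fitted posterior means
  this package's model targets;
* patient × exercise SDs (0.30, 0.113, 0.003): the slope value 0.113 is
  back-solved so the within-patient spread of exercise slopes is
  √(0.043² + 0.113²) ≈ 0.121 SMD, the reported median within-individual
  variability; the intercept value 0.30 is a plausible fraction of the
  patient intercept SD; these components are not separately published;
* residual SD 0.25 SMD: session-to-session noise well below the
  between-patient baseline spread (1 SMD), a realistic figure for
  supervised machine training; not separately published;
* attendance rate 0.49: makes ~53–54% of patients meet the ≥50%-of-24
  criterion, matching the reported 53%;
* overshoot and invalidity rates 5% each — enough to exercise the filter
  rules without dominating the data.

The raw-scale inversion maps a latent `z` to a target volume-load
`M + S·z` with `M = 36·baseline_load_mean`, `S = 36·baseline_load_sd`
(3 sets × 12 reps), and divides back into a load rounded to 0.25 kg —
machine-stack granularity, which bounds the round-trip error at ≈ 0.02 SMD
for the default anchors. Loads are floored at 0.25 kg, so latent values
below −mean/sd (≈ −6.7 SDs at the defaults) are clamped; the raw-load
distribution of the source trials is unpublished and this mapping is a
stand-in that carries no information beyond placing volume-load on a
plausible kilogram scale.

What the generator does **not** emulate: treatment covariates, secular
attendance trends (attendance is independent Bernoulli, i.e. missing
completely at random), protocol-driven load stepping (loads derive from the
latent trajectory, not from a 3-consecutive-sessions progression rule), or
non-Gaussian residuals. Passing recovery tests therefore demonstrates
correctness of the estimation machinery under the model's own assumptions,
not robustness to their violation on real data.

## Numerical and design notes

* Quantile summaries use central 2.5%/97.5% quantiles (type-7).
* The heterogeneity multiplier is the normal 1.96 throughout.
* Baseline SDs use the sample (n−1) denominator; standardization requires
  at least two contributing patients and a positive SD, and errors
  otherwise.
* With a single exercise, exercise-level effects are unidentifiable and are
  folded into the population coefficients; a three-level request on such
  data errors with advice to use `two_level`.
* A patient's attended-session count is taken from distinct session indices
  in raw logs, or distinct `t` plus the two familiarization sessions in
  standardized tables.
* Stage seeds derive from one global seed (`stage_seed()`), so a pipeline
  stage can be rerun in isolation bit-identically.
* Published interval endpoints for the quadratic component differ between
  summary locations in the source report (−0.008 to 0.001 vs −0.003 to
  > −0.001); the package reports its own computed intervals and takes no
  side.

## Problem sizes used in the test suite

The suite exercises full-scale fits where it matters and small cohorts
elsewhere, as the package's own choice of test design: the study-scale
recovery experiment uses 69 × 8 × 22 with two chains of 2400 iterations;
interval-calibration runs 20 replicate cohorts of 20 patients × 4
exercises × 12 sessions with shorter chains (the binomial criterion —
truth covered in at least 15 of 20 — absorbs the extra Monte-Carlo error);
unit and property tests use cohorts of 4–30 patients. A single-seed
recovery experiment inherits the realized noise of only eight exercise-mean
draws (SD 0.043/√8 ≈ 0.015 on the linear component), so its population-level
check is itself a ~95%-coverage event across seeds — that is why the
calibration property, not any single seed, is the package's evidence of
calibration.

## Known limitations

* Coefficients within a level are uncorrelated by assumption (see above).
* The quadratic trajectory is a local description: it necessarily declines
  after the vertex, which real training does not; plateau timing is a
  statement about the fitted curve, and extrapolations beyond the observed
  session range (visible as plateau estimates far past session 24 for
  near-linear exercises) should be read as "no plateau within the
  intervention".
* Residuals are Gaussian and homoscedastic; no session-level covariates are
  modelled — both deliberate scope restrictions.
* LOO comparisons are per-exercise patient-level fits; a joint multi-level
  comparison is out of scope.
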