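---
title: "Models and design choices in wearbio"
author: "wearbio authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in wearbio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wearbio)
```

This vignette explains the models behind each estimator, the tunable
parameters that matter, what the synthetic generators emulate (and do not),
and the numerical choices we made where the design was genuinely open.

## The data model

Everything flows through `bio_series`: a strictly time-ordered,
finite-valued, single-channel series (heart rate in bpm, steps per
interval, glucose in mg/dL) with a nominal sampling interval. Missing data
are absent samples — never sentinel values — so every downstream window
computation is explicit about what it saw. Three conventions are set once
and enforced everywhere:

* **Bins are half-open** `[t, t + interval)` with the timestamp at the left
  edge; lookback windows are half-open `(t − w, t]`.
* **Steps zero-fill, heart rate and glucose do not.** A step counter that
  emits nothing during wear was measuring zero steps; an absent optical-HR
  or CGM sample is a missing measurement. `resample_uniform()` therefore
  fills interior empty bins with 0 only for the steps channel.
* **Duplicate timestamps collapse to their mean** at read time
  (order-independent, logged).

Default plausibility bounds (heart rate 25–250 bpm, steps 0–300/min,
glucose 20–600 mg/dL) reflect physiological and sensor limits and are
configurable.

## Missingness accounting

Completeness is counted per nominal grid slot — a slot is present if at
least one sample falls in it — so oversampling can never exceed 100%.
Per-day fractions always use the full 24-hour day as denominator, including
partial first and last days; this keeps day-by-hour heat grids comparable
across days at the cost of understating completeness on truncated edge
days, which we consider the right trade for visual screening. Deleting
samples can only lower fractions (a tested monotonicity property), and for
series degraded by `degrade_missing()` the recovered fractions equal the
injected mask exactly.

## Resting heart rate

The estimator formalizes "heart rate at rest" as the median of the
low-activity subset selected by two parameters: the trailing window length
*m* (minutes) and the maximum tolerated rolling step sum *n*. The grid
(17 step thresholds × 12 window lengths = 204 candidates) covers sedentary
thresholds up to 50 steps and rest windows up to an hour at 5-minute
granularity without combinatorial blowup.

The penalty we minimize is

$$P(n, m) = \mathrm{SD}(\text{subset}) \;+\; \lambda\,
\mathrm{SD}(\text{all HR}) \cdot
\frac{\max(0,\; fN - |\text{subset}|)}{fN},$$

with $\lambda = 1$ and $f = 0.10$. Minimizing subset SD alone collapses
onto tiny, unrepresentative subsets; the shortfall term charges candidates
that cover less than a fraction $f$ of the data, scaled by the overall SD
so the two terms share units. A subset that is empty or touches fewer than
`min_days` distinct days (3, or the observed span if shorter) is
disqualified with an infinite penalty. Ties break lexicographically toward
smaller *m*, then smaller *n* — deterministic, and favoring stricter rest
definitions. Medians of even-sized subsets are the mean of the central
pair. The penalty lives in one function (`rhr_penalty`) so alternative
functionals can be swapped without touching the search.

Two properties are worth knowing. First, the subset is monotone: at fixed
*m*, raising *n* never removes minutes; at fixed *n*, lengthening *m* never
adds them. Second — a genuine limitation — when light activity recurs
frequently through the waking day, long lookback windows exclude most
waking sedentary minutes and the minimum-SD subset becomes sleep-dominated,
biasing the estimate toward sleeping heart rate (several bpm below wakeful
rest). The estimator measures "heart rate when steps have been absent for a
while", and with dense ambient movement that condition is mostly met during
sleep. Parameter-recovery benchmarks therefore use the generator's
`exercise` bout profile (discrete exercise bouts, quiet otherwise), where
the subset spans the full day; under that condition the estimate recovers
the simulated truth with mean absolute error ≈ 1.2 bpm over 20 weeks
(50–80 bpm range, 3 bpm noise).

## Sleep detection

Five stages, all seeded and deterministic.

**Epoching.** 5-minute epochs; an epoch's mean HR is kept only if at least
half the expected HR samples are present, otherwise the epoch is excluded
from features (and classified wake by default in episode assembly).

**Seed labels.** Likely sleep: maximal runs of at least 120 minutes in
which every epoch has zero steps *and* mean HR below the subject's 40th
percentile — long quiet HR-depressed stretches, chosen for precision, not
recall. Likely wake comes from two sources: stepped epochs
(≥ 50 steps/epoch), and the dual gate *mean HR at or above the 40th
percentile threshold and any steps within ±60 minutes*. The second source
matters more than it looks: without it the wake class contains only
movement epochs with exercise-elevated heart rate, and any margin- or
likelihood-based classifier places the sleep/wake boundary roughly midway
between deep-sleep HR and exercise HR — well above quiet sitting — so
detected sleep swallows the quiet hour before bed and after waking (we
measured ~45–75 min of systematic overextension per night). The dual gate
supplies sedentary wake exemplars without assuming anything about clock
time, so shifted sleep schedules still work; an absolute "high HR quantile"
wake rule was rejected for exactly that reason (sleep at the circadian peak
is not the lowest-HR state in shift workers). An hour without any steps is
our operational definition of "settled"; both the quantile and the window
are configurable.

**Features.** Per epoch: HR z-score against the subject's overall epoch
distribution (0 under zero variance), rolling ±30-min HR mean and SD,
rolling ±30-min step sum, and sin/cos of 24-h clock phase. Clock phase is
deliberately encoded as a point on the circle and left unscaled, and the
other features are scaled by their training SD; with the logistic model
fitted without per-feature standardization and the RBF kernel depending
only on Euclidean distances, a pure time shift of the input rotates the
phase features and changes nothing else — the pipeline is time-shift
equivariant by construction (a tested property, exact up to one epoch).

**Candidates and selection.** A ridge logistic model (`glmnet`, α = 0,
λ = 0.01) and a radial-kernel SVM (`e1071`), both trained with
inverse-frequency class weights so the fit matches the selection metric:
mean stratified 5-fold cross-validated *balanced* accuracy (sleep/wake
counts are always imbalanced). The SVM's probability is a symmetric
logistic squashing of its decision score — monotone, in [0, 1], and mapping
the margin to 0.5, so the fixed 0.5 label threshold coincides with the
balanced decision boundary (Platt-style calibration re-centers ambiguous
scores at the class prior, which systematically mislabels boundary epochs
under imbalance). Selection uses a tolerance rule: the SVM must beat the
logistic model's CV balanced accuracy by more than 0.01 to be chosen —
exact ties and near-ties go to the simpler, better-calibrated linear model.

**Episodes.** A width-5 running median removes isolated flips; sleep runs
separated by under 30 minutes merge; episodes under 60 minutes are dropped.
Episodes are non-overlapping and ordered by construction.

On the synthetic benchmark (7 days, nightly 23:00–07:00 and shifted
08:00–16:00 schedules, 10 seeds each) mean interval IoU between detected
and true sleep is ≈ 0.93 and ≈ 0.91 respectively. The residual error is
concentrated at onset/offset, where a quiet wakeful subject genuinely
resembles early sleep in heart rate and actigraphy.

## Glycemic variability

The 28-metric catalog fixes one published dialect per metric; each formula
lives in exactly one function so a definitional disagreement is locally
fixable.

* SDs use the n − 1 denominator everywhere; quartiles use linear
  interpolation.
* Time in range is boundary-inclusive over the clinical consensus default
  70–180 mg/dL (configurable via `range_config`).
* The risk indices use f(g) = 1.509·((ln g)^1.084 − 5.381) with
  rl = 10f² (f < 0), rh = 10f² (f > 0); LBGI/HBGI are means of rl/rh, ADRR
  is the mean over days of the daily `max rl + max rh` (needs ≥ 2 days),
  and J-index is 0.001·(mean + SD)².
* **MAGE** uses the smoothed-extrema dialect: 9-point moving average,
  local extrema after compressing equal-value runs (endpoints included),
  excursions qualify when the absolute difference of consecutive extrema
  exceeds 1 × the raw trace SD, and MAGE is the mean qualifying amplitude
  in both directions. MAGE has many published dialects; this one is
  documented here and verified against a brute-force oracle in the tests.
* **MODD/CONGA24** pair each sample with the nearest sample 24 h earlier
  within ±2.5 min (half a CGM interval); MODD is the mean absolute paired
  difference, CONGA24 the SD of the paired differences. The CONGA horizon
  is fixed at 24 h to share MODD's pairing.
* Day boundaries are local calendar midnight. Metrics whose preconditions
  fail are reported absent with a reason and still counted in the catalog.
* The LOWESS trend uses `stats::lowess` with span 0.15 on a time axis
  re-centered at the first sample (large epoch offsets otherwise cost
  floating-point precision).

## The synthetic generators

`simulate_hr_steps` emits minute-grid heart rate and steps:
`HR(t) = rhr_true + circadian_amp · sin(2π(h − 9)/24) − sleep_drop·[asleep]
+ hr_rise·[in bout] + N(0, noise_sd²)`, steps zero outside bouts. Defaults:
circadian amplitude 3 bpm peaking at 15:00 (trough 03:00), sleep
23:00–07:00 with a 5 bpm drop, noise 3 bpm, 7 days. With this phase the
4 awake hours of negative circadian phase exactly balance the 8 depressed
sleep hours at the median, so the median of non-bout heart rate equals
`rhr_true` and "true RHR" is a well-defined recovery target rather than a
label on an arbitrary constant. Two bout profiles are provided:
`ambulatory` (light 10-min bouts roughly every 90 minutes across the waking
period plus one exercise bout — the daily-life pattern the sleep detector
is aimed at) and `exercise` (two discrete daily exercise bouts — the
protocol for RHR recovery studies). Bouts are placed inside the waking
period implied by the sleep window, so shifted schedules shift the activity
pattern coherently, including the spillover from the previous evening at
the start of the recording.

`simulate_cgm` emits a 5-min glucose grid: baseline plus one kernel per
meal (linear rise to the peak over 30 min, exponential decay with a 60-min
constant) plus i.i.d. Gaussian sensor noise; three meals/day, amplitude
60 mg/dL, baseline 100, 14 days by default. `degrade_missing` removes an
exact count of samples (uniformly or in contiguous blocks) and returns the
removed-slot mask.

What the generators deliberately do **not** emulate: autocorrelated sensor
noise, motion artefacts, heart-rate recovery transients after exercise,
gradual sleep-onset HR decline, REM/NREM architecture, glucose-insulin
dynamics, or inter-device calibration offsets. Passing the recovery
benchmarks therefore demonstrates correctness of the estimators under
clean, known-truth conditions — not field accuracy on any particular
device. The instant HR step at sleep onset, in particular, makes episode
boundaries sharper than real physiology.

## Numerical and degenerate-input conventions

* SD of a single value is defined as 0 (with a warning where user-facing).
* An empty or under-covered candidate subset gets an infinite penalty
  rather than an error; only a fully disqualified search raises
  a no-resting-data error naming the binding constraint.
* Zero-variance features give hr_z = 0; a training set with no usable
  variance yields a coin-flip classifier rather than a crash.
* All anticipated failures carry condition classes
  (`wearbio_io_error`, `wearbio_contract_error`, `wearbio_empty_input`,
  `wearbio_untrainable_labels`, …) which the CLI maps to exit codes
  (2 for I/O, 1 otherwise).
* Benchmarks in the test suite use 1–7 day series and 10–20 seeds; these
  sizes were chosen so the full suite exercises every pipeline end to end
  in well under a minute of compute per module.

## Known limitations

* The RHR penalty's sleep bias under dense ambient activity, discussed
  above; a wakefulness-aware subset rule would need the sleep module's
  output, which would couple the two estimators.
* Sleep onset/offset carry ~15–30 min of irreducible ambiguity from quiet
  pre-bed wakefulness; reported CV balanced accuracy refers to the seed
  labels, not to ground truth.
* The CGM module is single-unit (mg/dL); mmol/L input must be converted
  upstream (×18.016).
* One subject per call; longitudinal multi-subject modeling is out of
  scope.
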