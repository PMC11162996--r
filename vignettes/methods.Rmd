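---
title: "Quantifying parkinsonism and dystonia from wearable inertial sensors: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying parkinsonism and dystonia from wearable inertial sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and data model

`wearimu` implements an analysis pipeline for body-worn inertial
measurement units (IMUs) recorded while a participant performs
standardized motor tasks — rhythmic upper-limb items such as
pronation–supination rated on ordinal 0–4 severity scales, and
straight walking with ankle-mounted sensors. The pipeline has two
branches:

* a **sensor-based feature branch**: band-limit, cut annotated task
  trials, slide fixed-size windows, extract a registry of time- and
  frequency-domain features per window, and estimate ordinal clinical
  labels with a cost-sensitive random forest under grouped
  cross-validation;
* a **gait branch**: detect initial contact (IC) and final contact
  (FC) from the shank's sagittal angular rate and anteroposterior
  (AP) acceleration, derive stride-level temporal and
  height-normalized spatial parameters, aggregate per trial, and
  compare groups with mixed-effects models.

Both branches feed Sammon projections for visual cluster inspection
and inverse-power-law learning curves for sample-size planning.

The atomic object is an `imu_recording`: six synchronized channels
(tri-axial acceleration in g, tri-axial angular rate in deg/s) at a
nominal 512 Hz with device ranges ±2 g and ±500 deg/s. Timestamps
must be uniform to 1%; irregular recordings are rejected rather than
resampled, because silent resampling would invalidate the frequency
features downstream.

Because no patient recordings are distributed with the package, a
first-class synthetic cohort generator supplies labeled recordings
with analytic ground truth for every stage; all quantitative claims
made by the test suite are claims about this generator's output, not
about clinical data (see *What the simulator does and does not show*).

# Pre-processing

## Zero-phase band-limiting

All channels are filtered with two 6th-order Butterworth designs — a
0.3 Hz high-pass that removes the DC component and slow postural
drift, then a 20 Hz low-pass against high-frequency noise — each
applied forward and backward. We read the stated order as the
per-pass order, so the forward–backward pass squares each magnitude
response (doubling the effective roll-off); the net attenuation at
25 Hz exceeds 22 dB at 512 Hz, and group delay is identically zero.

The numerically delicate part is the high-pass: a normalized cutoff
of 0.3/256 puts all six poles within 1e-3 of the unit circle, and the
expanded transfer-function polynomial loses the stopband entirely in
double precision (the DC residual of a polynomial-form
forward–backward pass is on the order of 10% of the offset). The
package therefore factors each design into second-order sections
(biquads) via the polynomial roots, and runs the cascade with
odd-reflection end padding and per-section steady-state initial
conditions. This brings the DC residual below 1e-11 of the offset.
The inner IIR recursion is implemented in C++ since it cannot be
vectorized.

Edge effects are physical, not numerical: a 0.3 Hz high-pass has an
impulse response spreading over seconds, so roughly `1/low_cut_hz`
seconds at each record end remain contaminated no matter the
implementation. Recordings are filtered whole before segmentation, so
trial segments in the interior are unaffected; tests evaluate in-band
fidelity in the record core for the same reason.

## Segmentation and windowing

Trials are cut from annotations (task, side, trial index, start/end,
turning flag); turning spans are discarded and each remaining trial
is a separate sample. Windows of `window_s = 3` s with 75% overlap
start every `window_s * (1 - overlap)` s; a trailing partial window
is discarded because downstream feature extraction assumes fixed-size
inputs, giving exactly `floor((T - window_s)/hop) + 1` windows for a
trial of duration `T >= window_s` and none otherwise.

# Window features

Features are computed per channel on the six axes plus the two
magnitude channels (Euclidean norms of the filtered accelerometer and
gyroscope axes): nine time-domain statistics (mean, SD, RMS, range,
IQR, skewness, kurtosis, zero-crossing rate about the mean, RMS of
the first difference as a jerk proxy), six inter-axis Pearson
correlations (three per modality), and nine spectral quantities
(dominant frequency and its power, total 0.3–20 Hz power, relative
power in 0.3–3, 3–8, 8–12 and 12–20 Hz, spectral centroid, spectral
entropy normalized to [0, 1]) — 150 features in registry version 1.0.

Spectra come from a single Hann-windowed periodogram of the full 3 s
window: Welch averaging at this window length would destroy the
0.3–1 Hz resolution that separates slow dystonic drift from voluntary
movement rates. The exact feature list is deliberately held in a
versioned registry so that a different list can be swapped in without
touching any downstream stage; the registry shipped here is the
package's own canonical choice, not a reproduction of any published
list.

Degenerate inputs follow fixed conventions rather than propagating
NaN: zero-variance channels report 0 for correlations, zero-crossing
rate, skewness and kurtosis, and zero-power spectra report 0 for all
spectral features. Emitted tables are asserted rectangular and
NA-free.

# Gait analysis

## Event detection

The shank's sagittal angular rate in walking shows a tall positive
mid-swing lobe flanked by sharp negative troughs at IC and FC.
Detection proceeds in three steps:

1. **swing peaks**: local maxima, thresholded at 30% of the maximum
   topographic prominence with a 0.4 s minimum separation — the
   prominence threshold is what keeps low-amplitude trembling during
   freezing episodes from seeding spurious cycles;
2. **troughs**: within each inter-swing interval, negative local
   minima at least 25% as deep as the interval's deepest trough
   qualify; the first is the IC, the last (the one immediately
   preceding the next swing peak) is the FC;
3. **refinement**: each event moves to the nearest salient
   AP-acceleration peak within ±100 ms, anchoring contacts on the
   impact transient, which is sharper than the angular-rate trough
   under noise.

Fewer than two swing peaks raises a "no gait detected" error; an
implied cadence outside 30–180 steps/min sets a warning flag. The
first and last incomplete cycles never produce events because events
only come from complete inter-swing intervals. The specific
thresholds (30% prominence, 25% depth, ±100 ms) are the package's
operational choices, validated against the simulator's ground truth
across a seeded sweep (stride time 0.9–1.6 s, step asymmetry up to
20%, noise up to 30% of signal RMS) rather than against any published
detector's datasets.

## Temporal and spatial parameters

Stride time is same-leg IC→IC, stance IC→FC, swing FC→next IC (so
stance + swing = stride by construction), and step time IC→next
contralateral IC. Strides longer than 1.8× the leg's median stride
time are flagged as spanning a no-gait gap (e.g. a freezing pause)
and excluded from aggregates.

Spatial parameters model the shank as an inverted pendulum with
effective length `l = 0.53 * height` (standard anthropometry). Per
stride the angular rate is drift-corrected by subtracting the
constant that forces zero net rotation over the full stride — the
shank returns to the same orientation each cycle — then integrated
(trapezoid rule) over stance and swing to give excursions
`theta_st`, `theta_sw`, and

```
stride_length = 2 l sin(theta_sw / 2) + 2 l sin(theta_st / 2)
```

normalized by stature. Excursions beyond 90° flag the stride
implausible and drop it from aggregates. The geometry lives in one
function so an alternative model can be swapped in; the simulator
shares it, which is what makes recovery a testable property (and also
what it cannot prove — see below). Cadence is `60 / mean(step time)`
steps/min, equivalent to `120 / stride time` in symmetric gait; only
spatial parameters are height-normalized.

Step and stride regularity are the unbiased normalized autocovariance
of AP acceleration at the lags nearest the mean step and stride time;
step symmetry is their ratio, clipped to [0, 2] with a flag. The
regularity signal here is the ankle AP acceleration — the sensors
this pipeline uses — although autocovariance regularity indices were
originally defined on trunk acceleration; this is a documented
deviation. The ratio (not difference) form of symmetry was chosen
because it is dimensionless and self-normalizing; the alternative
difference form admits the same information.

Trial aggregation emits mean, SD, coefficient of variation and
right/left ratio of leg means per parameter, plus cadence and the
regularity triplet, one row per trial, and is permutation-invariant
in the stride order.

## Group contrasts

Per gait parameter we fit `value ~ group + (1 | participant)` with
Satterthwaite degrees of freedom and report all pairwise group
contrasts flagged at p < 0.01 and p < 0.001. Repeated trials per
participant make the random intercept necessary; designs that cannot
support it (one trial per participant everywhere leaves the intercept
variance unidentified) fall back to ordinary least squares with an
explicit flag rather than failing.

# Modeling

## Feature ranking

Features are ranked by out-of-bag permutation importance (mean
decrease in accuracy) of a random forest. Selection uses random
"probe" features — shuffled copies of real columns, which keep the
marginal distributions but carry no signal — and keeps features whose
importance exceeds **every** probe. With a probe set as large as the
feature set, a null feature clears this shadow-maximum threshold with
probability about `1/(n_probes + 1)`, so null selections are rare; a
percentile-of-probes threshold was considered and rejected because
any fixed percentile q admits a fraction `1 - q` of null features by
exchangeability, which is too permissive for feature sets of this
size. When ranking precedes classification it is refit inside each
training fold — selecting on all data would leak label information
across cross-validation folds.

## Sammon projection

The Sammon stress

```
E = (1 / sum d*) * sum (d* - d)^2 / d*     (sums over pairs i < j)
```

weights each pair's squared discrepancy by the inverse input-space
distance `d*`, preserving local structure. The implementation uses
Sammon's pseudo-Newton update with the conventional step ("magic")
factor 0.3, principal-coordinate (classical MDS) initialization, and
step halving whenever a step would increase the stress, so the
reported stress trace is non-increasing by construction. Zero input
distances (duplicate samples) are regularized at 1e-12, which places
duplicates at coincident output coordinates instead of dividing by
zero; all-identical inputs are an error. The projection axes are
unitless and not interpretable — only cluster structure is — which is
why the result object exposes coordinates, stress and trace but no
axis metadata.

## Cost-sensitive random forest under grouped cross-validation

Class imbalance is handled through an explicit cost matrix:
`cost(i -> j)` for `i != j` proportional to `N_total / (K * N_i)`
(inverse frequency of the true class), zero diagonal, off-diagonal
mean normalized to 1. The costs enter as cost-weighted voting: the
forest's vote fractions are multiplied into the cost matrix and the
predicted class minimizes expected misclassification cost. This
mechanism measurably raises minority recall, which per-class prior
weights inside the tree-growing criterion did not in our experiments;
the contract is the inverse-frequency penalty, not a particular
library mechanism.

Cross-validation folds are groups — one participant
(leave-one-subject-out) or one participant-side
(leave-one-side-out) — so no sample from a held-out group is ever
seen in training; the partition is asserted structurally in every
fold, not checked statistically. The number of trees (100/300/500)
and minimum leaf size (1/3/5/10) are tuned per fold by cost-weighted
out-of-bag error on the training portion only; out-of-bag tuning was
chosen over nested cross-validation because the data regimes targeted
here are small and the out-of-bag estimate is already held-out.
Multiclass sensitivity, specificity and F1 are macro one-vs-rest
means over classes (classes without positives or negatives in a fold
are skipped in the respective mean), and fold summaries are reported
as mean (SD) [min–max]. Window-level samples are the classification
unit; per-trial vote aggregation is deliberately not applied in the
headline report.

Ordinal label classes can be merged before modeling (e.g. scores 3
and 4 into "≥3" when a class has a single participant, which would
make subject-level folds vacuous). Mappings are partial: unmapped
values pass through unchanged, and `strict = TRUE` turns unmapped
observed values into an error. The `control` label is never merged
with a patient score.

## Learning curves

Accuracy as a function of training-set size is modeled as the inverse
power law `acc(n) = a - b n^(-c)`, fit by weighted nonlinear least
squares (weights proportional to n by default, reflecting the lower
variance of accuracies estimated from more data) with a log-linear
warm start and box constraints `a <= 2, b, c >= 0`. `a` may exceed 1
during optimization but predictions are clipped at 1 with a warning.
Constant accuracies short-circuit to a flagged "plateau" fit with
`c = 0`. The smallest n achieving a target accuracy is the analytic
inverse; a 95% confidence band comes from resampling per-n accuracy
replicates.

# The synthetic cohort generator

The generator is first-class, tested code, and its defaults are the
study conditions every quantitative test uses.

**Gait.** Each leg's sagittal angular rate is built stride by stride:
a mild negative stance arc and a tall positive mid-swing lobe whose
sampled integrals are rescaled to the exact pendulum excursion
implied by the per-stride target length, plus sharp negative Gaussian
troughs at IC and FC. AP acceleration carries an impact transient at
each IC, a smaller one at FC, a smaller-still contralateral transient
(which is what gives the signal its step periodicity), and a smooth
step-frequency component. Defaults: 512 Hz, 30 s trials, stride time
1.2 ± 0.04 s, normalized stride length 0.60 ± 0.03, stature 1.70 m,
5% noise. Timing asymmetry shifts the contralateral step phase (step
time ratio `(0.5 + a/2)/(0.5 - a/2)`) while both legs keep a common
stride rate — legs with different stride rates would desynchronize,
which no sustained gait does — and amplitude asymmetry scales the
right stride length. Freezing-of-gait episodes replace whole strides
with 6–8 Hz low-amplitude trembling in place, one recognized freezing
phenotype, chosen as a modeling convenience rather than a clinical
claim; dystonic intrusion adds an irregular amplitude-modulated
1–3 Hz sagittal component. Gaussian sensor noise is parameterized as
a fraction of each channel's demeaned RMS; bias and drift are not
modeled because the 0.3 Hz high-pass removes them anyway.

**Upper limb.** Rhythmic rotation on the task's primary axis
(pronation–supination: the forearm's long axis) at a configured rate,
with severity 0–4 monotonically shrinking amplitude (−15% per step)
and rate (−8% per step) and growing cycle-time jitter (CV
0.02 + 0.045 per step) and per-cycle amplitude decrement (sequence
effect, 1.5% per severity step per cycle). Monotonicity of the
generating parameters in severity is a tested invariant.

**Cohorts.** `simulate_cohort()` draws participants per class with
between-subject variation in stature and gait parameters, several
trials per participant separated by annotated turning spans (gait) or
rests (upper limb), and writes, when asked, the exact CSV dialects
the loaders read plus a JSON manifest of every generating parameter.
Class presets step normalized stride length down by 0.13 and stride
time up by 0.12 s per severity level, add freezing episodes for FoG+
classes and a 35 deg/s dystonic intrusion for dystonia+ classes —
differences chosen large relative to the between-subject spread so
cohorts are separable by construction.

## What passing tests do and do not show

The simulator shares the spatial-parameter pendulum geometry with the
estimator, deliberately: stride-length recovery then tests the event
detection, integration, drift correction and normalization machinery
with an analytic oracle. It therefore does **not** validate the
pendulum model itself against optical motion capture, nor the
detector against clinically annotated recordings; waveforms are
parameterized splines, not recorded templates, and real dystonic and
freezing phenotypes are far more heterogeneous than the single
intrusion and trembling morphologies generated here. Classification
accuracies on simulated cohorts demonstrate the pipeline's
correctness (separable cohorts are separated; permuted labels fall to
chance; held-out groups never leak), not expected clinical
performance.

# Numerical choices and problem sizes

Tolerances and scales used by the test suite, chosen once as the
package's own study conditions: gait recovery is evaluated over 50
sweep draws at 512 Hz (mean stride-time error ≤ 1 sample, normalized
stride-length error ≤ 5%, cadence error ≤ 2 steps/min); Sammon
monotonicity over 100 seeded 20×6 datasets with a 50-iteration cap
and exactness on a 3-D-embeddable 40×50 configuration (stress
< 1e-4); classification on a 12-subject, 3-class gait cohort at
128 Hz with 3 × 20 s trials per subject (the lower rate and short
trials keep the forest retraining loops tractable while all gait
frequencies of interest sit far below the 64 Hz Nyquist); the
permutation null over 50 shuffles with a fixed forest; the
cost-matrix comparison paired over 50 seeds on a 200-sample 9:1 task;
learning-curve recovery over 100 noise replicates with five replicate
accuracy measurements per sample size — the repeated-subsampling
design learning-curve protocols use, and a necessity here: the
linearized information bound for a single noisy accuracy per n on the
{25, 50, 100, 200, 400} design leaves the asymptote with a sampling
SD near 0.05, several times the recovery tolerance; mixed-model power
over 100 and size over 500 replicates of a 10-subject-per-group,
5-trial design. Filter fidelity is measured in the record core
(seconds 10–20 of a 30 s record) because high-pass edge transients
are unavoidable at any implementation quality.

# Known limitations

* Sensor-to-segment calibration, video synchronization and turning
  detection are out of scope; annotations must supply task spans and
  turning flags.
* Irregularly sampled recordings are rejected, not resampled.
* The feature registry is a canonical stand-in, versioned so
  alternative lists can be configured.
* Double-support time, arm-swing metrics and regression-mode score
  estimation are not implemented.
* The mixed-model fallback (ordinary regression) ignores repeated
  measures and should be read as descriptive when triggered.
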