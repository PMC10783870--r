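---
title: "Estimating temporal response functions by boosting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating temporal response functions by boosting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trfboost)
```

## The convolution model

Continuous electrophysiological recordings (EEG/MEG) during naturalistic
stimulation — listening to running speech, say — cannot be analysed by
classical averaging, because responses to successive stimulus events overlap
heavily. trfboost instead models the response at each channel as a linear
convolution of one or several stimulus-derived predictor time series
$x_{i,t}$ with unknown kernels:

$$\hat y_t = \sum_i \sum_{\tau=\tau_{\min}}^{\tau_{\max}} h_{i,\tau}\, x_{i,t-\tau}$$

The kernel $h_{i,\tau}$ is the *temporal response function* (TRF) of
predictor $i$: the stereotyped response that each unit of that predictor
contributes at lag $\tau$. With several predictors, the collection of TRFs
is a multivariate TRF (mTRF) and the model is a time-expanded multiple
regression. Predictors operationalize hypotheses about neural
representations — an acoustic envelope, a spectrogram, an onset spectrogram,
or impulses at word onsets scaled by, e.g., surprisal — and the additivity
assumption lets them compete for the same response.

Conventions used throughout the package:

* Lag windows are half-open, `[tmin, tmax)`, sampled at the response rate.
  A window of (0, 0.5) s at 100 Hz therefore has exactly 50 lag bins. This
  avoids double-counting the boundary and makes lag counts exact.
* Samples of $x$ before the start of the record are treated as zero
  (zero-padding). The estimator and the simulator use the same convention,
  so simulated data follow the fitted model exactly. Predictive-power
  evaluation can optionally exclude the first `tmax - tmin` seconds
  (`exclude_onset` in `boost_config()`), off by default.
* Responses, predictor banks, and kernels carry explicit uniform time axes
  (`time_axis`); operations refuse misaligned inputs rather than guessing.

## The boosting estimator

`boost_fit()` estimates the mTRF by coordinate-descent boosting. Starting
from an all-zero kernel, each iteration examines every (predictor, lag)
coordinate and both signs and applies the step of size `delta` that most
reduces the training error; when no step helps, `delta` is halved until it
falls below `mindelta`. After every accepted step the validation error is
consulted; two consecutive increases end the run, and the kernel with the
smallest validation error in the run's history is returned. Because most
coordinates are never touched before early stopping, unimportant
coefficients remain *exactly* zero — a sparsity prior expressed
algorithmically rather than as a penalty. This makes boosting well suited to
the structured, highly correlated predictor sets typical of auditory models
(adjacent spectrogram bands correlate strongly).

Channels are fitted independently (mass-univariate), and the data are
partitioned into `k` contiguous segments; each of the `k` runs uses a
different validation segment and the reported kernel is the average of the
run kernels, expressed in original units. The per-run kernels are retained
in the result for diagnostics.

Parameters that matter, with defaults:

* `delta = 0.005`, `mindelta = delta/8` (normalized units). The halving
  schedule is part of the algorithm; the initial value trades off step
  resolution against run time and is recorded in the result. Smaller values
  refine kernels slightly at proportionally higher cost.
* `error = "l2"` or `"l1"`. The l1 norm reduces the leverage of outlier
  samples (artifacts); inputs are then scaled by mean absolute deviation
  rather than standard deviation.
* `basis = 0` (seconds). With `basis > 0`, each step adds a unit-sum window
  (`"hamming"` by default; 50 ms is a common choice) centered at the chosen
  lag instead of a single impulse, yielding smoother, more interpretable
  TRFs. Windows are normalized to unit sum *before* truncation at the
  kernel edges, so `delta` keeps its meaning of total added mass per step.
* `selective_stopping = s > 0` replaces global early stopping: a predictor
  whose accepted steps raise the validation error `s` times (counter reset
  when one lowers it) is frozen, and training continues until all predictors
  are frozen. This prevents one overfitting predictor from halting learning
  for the others.
* Ties among equal-error candidate steps are broken deterministically:
  lowest predictor index, then earliest lag, then the positive direction.
  Fits contain no randomness at all — identical inputs give bit-identical
  kernels.

### Normalization and units

Before fitting, each response channel and predictor component is centered
and scaled (`normalize_inputs()`). Centering eliminates the intercept —
essential, because a sparse estimator would otherwise spend coefficient mass
reproducing the mean; per-component scaling makes `delta` comparable across
predictors. Kernels are reported in original units via
`h_orig = h_norm * scale_y / scale_x`, and `predict()` restores the
intercept, so predictions from original-units kernels and normalized
quantities agree to numerical precision.

### Cross-validation

`cross_validate()` splits the record into `k` contiguous segments; run $j$
holds out segment $j$ as a test set, uses the next segment for validation,
and trains on the rest, so every segment is tested exactly once. The
concatenated test predictions cover the whole record, and the reported
*proportion explained*,

$$1 - \frac{E(y - \hat y)}{E(y - \bar y)},$$

is computed on this concatenation — an estimate of *predictive* rather than
explanatory power. $E$ is the sum of squares (l2) or of absolute values
(l1); the value may be negative. The denominator uses deviations from the
mean of the evaluated samples; this choice (rather than raw power) makes 0
the score of the intercept-only model and is stated here because other
definitions are possible.

`compare_models()` re-estimates the mTRF for two predictor sets under
identical partitions and reports the per-channel difference in held-out
power. Differences in predictive power — not differences between TRF
curves — are the conservative basis for claiming that a predictor
contributes unique information, because correlated predictors share
explanatory power in unstable ways.

### Backward models

`fit_backward()` swaps the roles: all response channels jointly predict a
single stimulus feature. Because each response sample reflects the stimulus
*before* it, the lag window must be negative (e.g. `(-0.5, 0)`), which at
100 Hz again gives 50 lags per channel.

### The ridge reference

`ridge_mtrf()` solves the same lagged regression in closed form with
Tikhonov regularization, optionally selecting the penalty by k-fold
cross-validated predictive power. Ridge spreads kernel power smoothly over
all lags and (for $\lambda > 0$) almost surely leaves no coefficient at
exactly zero; it serves as the reference against which boosting's sparsity
(true-negative rate on bands that carry no response) is measured. With
`lambda = 0` on well-conditioned noiseless data it is ordinary least
squares and recovers a generating kernel to machine precision — a useful
oracle for the shared design-matrix machinery.

## Predictor construction

`gammatone_spectrogram()` models the cochlear decomposition with a bank of
4th-order gammatone filters (FIR impulse responses
$t^3 e^{-2\pi b t}\cos 2\pi f t$ with $b = 1.019\,\mathrm{ERB}(f)$,
unit gain at each center frequency) on ERB-rate-spaced centers; per-band
envelopes are frame-averaged magnitudes. The defaults — 256 filters,
20–5000 Hz, 1000 Hz frame rate — give a high-resolution bank meant to be
reduced with `bin_bands()` (eight analysis bands is the usual compromise;
binning conserves total power exactly) and resampled to the analysis rate.
`sgram_envelope()` is the one-band extreme.

`apply_scale()` implements the nonlinear response scales compared in
auditory work: linear, power-law (default exponent 1/3, the conventional
auditory choice, exposed as a parameter), and log (dB re: the spectrogram
maximum, clipped at `floor_db = -50` dB and shifted so the floor maps to 0,
keeping silence finite). Whether the envelope is computed before or after
scaling is not standardized in the literature; here the scale is applied to
whatever spectrogram you pass, so either order is available explicitly.

`onset_spectrogram()` marks rising spectral edges. The default
`rectified_difference` method generalizes the half-wave-rectified
derivative: the largest rectified increase over look-back delays up to
`delay_span` (default 30 ms). The `delayed_inhibition` variant subtracts an
exponentially decaying trace of the recent past before rectifying; it is a
coarse approximation to published neural onset-detection models (whose
exact equations are not reproduced here), and is documented as such. Both
are non-negative and silent on constant input.

`impulse_predictor()` and `step_predictor()` turn event tables (onset,
magnitude, label) into regressors: impulses of magnitude 1 (a shared
response to every event) or of the event's value (responses scaling with,
e.g., surprisal), or values held over an event's duration. Events map to
the nearest sample, ties toward the earlier sample — deterministic and
biased by less than half a sample.

## Group statistics

`paired_t()` wraps the standard related-measures t-test for univariate
summaries (e.g. mean predictive power over sensors, via
`average_sensors()`). For sensor or sensor-by-time maps,
`cluster_permutation_test()` controls the family-wise error of the
mass-univariate t map: suprathreshold elements (default threshold: two-tailed
t at p = 0.05 with n − 1 df, positive and negative clusters formed
separately — a field convention, configurable) are clustered under sensor
adjacency plus temporal contiguity, scored by mass (sum of t), and compared
against the permutation null of the maximum absolute cluster mass under
random sign flips of the subject difference maps. Enumeration is exhaustive
when $2^n$ fits in the permutation budget; otherwise Monte Carlo with
$p = (b+1)/(m+1)$, which cannot return zero. Sensor adjacency is an explicit
neighbor table (`build_adjacency()` constructs one from coordinates by
distance threshold), avoiding any dependence on montage databases.

## The synthetic-data generator

`simulate_dataset()` produces data with exactly the statistical structure
the estimator assumes, so every estimator property is testable without any
external recording:

* *Correlated band predictors*: each band is
  $\sqrt\rho\,L_t + \sqrt{1-\rho}\,\varepsilon_{i,t}$ with a shared
  standardized AR(1) latent series $L$ and band-specific pink noise,
  giving pairwise correlation $\rho$ (default 0.8) — the structured
  collinearity regime that motivates sparse estimation. An event design
  (Poisson onsets, log-normal magnitudes) is available for discrete
  predictors.
* *Ground truth*: `ground_truth_kernel("alternating_bands")` drives the
  response from two adjacent bands with opposite-sign Gabor-like lag
  profiles, alternating in sign across channels; the remaining bands are
  exactly zero so false positives are measurable.
* *Noise*: pink (1/f amplitude shaping of white Gaussian noise, DC removed,
  unit variance per channel) or white, scaled per channel so that
  signal-to-noise variance ratio matches `snr_db` (default 0 dB — an even
  split, a realistic regime for continuous EEG).
* Everything is a pure function of the seed; `simulate_group()` derives
  per-subject seeds deterministically and adds Gaussian kernel perturbations
  for between-subject variability.

What the generator does *not* emulate: realistic scalp topographies and
volume conduction, eye-blink or movement artifacts, non-stationary
attention-dependent kernels, and the rectified, non-Gaussian amplitude
distribution of real band envelopes (bands here are centered mixtures,
which is what the estimator sees after normalization anyway). Passing the
simulation-based tests therefore demonstrates correctness of the estimation
machinery under its own assumptions, not performance on any particular real
dataset.

## Numerical choices and edge cases

* Convolution uses FFTs; equality with the explicit double sum is asserted
  to $10^{-10}$ in the tests. Resampling is Fourier-domain (low-pass at
  0.4× the target rate with a raised-cosine edge, then spectrum
  truncation), which reproduces band-limited signals exactly away from the
  record edges; upsampling is refused. Resampling and convolution do not
  commute in general (aliasing), and no such property is claimed.
* Band-pass filtering uses a linear-phase windowed-sinc FIR applied once
  with exact group-delay compensation — zero phase by construction, so TRF
  latencies survive filtering. The filter family and order are package
  choices (Hamming window; transition band half the lower edge), since
  cortical-band practice varies.
* Zero-variance components are rejected by name during normalization;
  all-zero lag windows, upsampling requests, misaligned axes, and
  mismatched component counts are errors, not warnings.
* Degenerate paired t-tests (all differences zero) return t = 0, p = 1.
* On null data the per-run boosting kernels stay predominantly at exact
  zero, but the *run-averaged* kernel unions the few chance coordinates of
  each run, so its zero fraction is lower than a single run's; calibration
  of the cross-validated predictive power (≤ 0.01 on null data) is the
  quantity that the test suite holds to a hard bound.
* With strongly autocorrelated (1/f) *null* responses, contiguous-segment
  cross-validation retains a small positive bias from slow structure shared
  across segment boundaries; the null-calibration tests therefore use a
  white-noise response, and held-out power near zero for pink-on-pink nulls
  should be interpreted with that bias in mind.

## Problem sizes used in the tests

The simulation studies in the test suite and acceptance script use 60 s
records at 100 Hz (20–30 s for the smaller two-band scenarios), 2 response
channels, 8-band predictor banks with correlation 0.8 at 0 dB pink-noise
SNR, 20 replicate seeds for recovery/robustness studies, 100 replicates for
null calibration, and 200 replicate groups of 12 subjects for family-wise
error calibration — sizes at which the measured properties are stable from
seed to seed while the whole suite runs in well under an hour on a single
core.

## Known limitations

* No source localization, no time-varying (dynamic) TRFs, and no joint
  estimation across channels (channels are strictly independent).
* The candidate-step search follows the training set only, as in the
  published pseudo-code; alternatives (train+validation) are not offered.
* The gammatone bank is FIR-truncated at 250 ms or a 12-time-constant
  decay, whichever is shorter; extremely low center frequencies (< 20 Hz)
  would need longer supports.
* WAV input covers PCM 16/24-bit and float; no vendor EEG formats — import
  arrays through the JSON container or delimited text instead.
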