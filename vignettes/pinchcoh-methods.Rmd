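---
title: "Methods: force steadiness, motor-unit firing and intermuscular coherence"
author: "pinchcoh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: force steadiness, motor-unit firing and intermuscular coherence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pinchcoh)
```

pinchcoh analyzes trapezoidal isometric pinch contractions recorded with
surface EMG and decomposed motor-unit (MU) spike trains: target-referenced
force steadiness, MU firing statistics with a mixed-model group comparison,
intermuscular coherence (IMC) with pooled and chi-squared inference,
shape-based clustering of EMG activity patterns, and bootstrap group
statistics. Because such recordings are rarely shareable, the package also
contains a motor-neuron-pool simulator that generates ground-truthed
cohorts under the same protocol, so every stage is testable end to end.
This vignette records the models, the tunable parameters, and the design
choices made where the underlying methods left the design open.

## The task protocol

A trial is a trapezoid: a 2 s ramp to the target force, a 10 s steady
isometric hold, and a 2 s ramp down, at targets of 15, 35, 55 and 70% of
the maximal voluntary contraction (MVC), three repeats per level (twelve
trials per participant). EMG is sampled at 2222 Hz with a 20--450 Hz
bandwidth (four channels per muscle; channel 1 is analyzed); force at
1000 Hz. Synthetic trials add a 0.5 s pre-ramp baseline and a 1.5 s
post-release rest so that analyses over the first 15 s of a trial (which
span the ramp) are well defined; the trapezoid alone lasts only 14 s.

## Force steadiness

Steadiness is the coefficient of variation of force **referenced to the
target force**, not the observed mean:
`COV = 100 * SD(force) / target`. Two windows are used:

* `steadiness_cov()` uses the 6 s centered on the midpoint of the 10 s
  hold. Hold boundaries come from the protocol timestamps, not from
  force-threshold detection, which would itself be noise-sensitive.
* `find_steadiest_window()` slides a 4 s window in 50 ms steps over the
  whole trial and returns the window with the smallest target-referenced
  COV (ties broken by the earliest start). The search deliberately runs
  over the full trial: ramp windows exclude themselves through their huge
  target-referenced variability, so no explicit ramp masking is needed.

Window and step lengths are converted to samples by rounding half away
from zero, making results bit-stable across sampling rates.

## Motor-unit firing statistics

Spike trains carry a decomposition-accuracy score. `filter_trains()`
retains a train when (i) accuracy >= 90%, (ii) it has at least seven
interpulse intervals (IPIs) inside the steadiest window, and (iii) the COV
of those IPIs is at most 30% (equality is kept: the removal rule is
"> 30%"). `mean_firing_rate()` is the arithmetic mean of reciprocal IPIs,
`mean(1/IPIs)` -- for IPIs {0.1, 0.2} s this is 7.5 Hz, not `2/0.3`.

`firing_threshold()` locates the onset of regular firing: scanning IPIs in
order, the first IPI whose first spike is followed by a 750 ms period in
which the IPIs starting there have COV < 30% marks onset. Two design
points the method statement leaves open: a COV needs at least two IPIs, so
windows with fewer fail the test; and the 750 ms window anchors at each
candidate IPI's first spike (it does not slide freely). Force at onset is
linearly interpolated between samples and expressed in %MVC. A train with
no qualifying IPI returns `NA` ("no regular onset").

`fit_firing_lmm()` fits, by REML,

```
rate ~ group * level * muscle + (1 | participant) + (1 | threshold_bin)
```

A random intercept for a *continuous* recruitment threshold is ill-posed
as a grouping factor, so thresholds are binned into 1 %MVC bins (width
configurable); this preserves the intent of absorbing size-principle
variance in firing rates. Marginal and conditional R-squared follow the
Nakagawa--Schielzeth variance decomposition (fixed-effect variance over
total; fixed plus random over total). Group contrasts are estimated
marginal means within each (level, muscle) cell, with 95% CIs; cells where
either group contributes fewer than 3 MUs are flagged `small_cell` for
cautious interpretation. Singular fits are reported with a warning, the
offending variance component pinned at zero.

## Intermuscular coherence

The coherence chain, per trial, is:

1. clip the steadiest 4 s window from channel 1 of each muscle;
2. high-pass at 20 Hz (4th-order Butterworth, forward--backward so zero
   phase; order configurable);
3. normalize to unit variance (z-scores), which makes estimates poolable
   across participants;
4. rectify and envelope in one operation as the magnitude of the analytic
   signal (FFT construction of the Hilbert transform);
5. split into non-overlapping 460 ms segments -- in samples,
   `floor(0.46 * fs)` = 1022 at 2222 Hz, so a 4 s window yields exactly
   L = 8 whole segments and a 2222/1022 = 2.174 Hz frequency grid;
6. per-segment mean removal and a plain (rectangular-window) DFT; spectra
   averaged across segments.

Squared coherence per frequency bin is
`|R(f)|^2 = |f_xy|^2 / (f_xx * f_yy)`, bounded in [0, 1] by
Cauchy--Schwarz. The 5% confidence limit from L segments is
`CL = 1 - 0.05^(1/(L-1))`. One typographic note: the source formulation of
this limit is sometimes printed as `0.05^(1/L-1)`, which read literally
gives a negative limit for any L >= 2; the package implements the standard
form with the exponent `1/(L-1)`.

Group-level (pooled) coherence sums cross- and auto-spectra across records
weighted by their segment counts and applies the coherence formula to the
pooled spectra; its confidence limit uses the total segment count. Whether
records should instead be pooled as normalized coherencies is a known
estimator choice; segment-weighted spectral pooling is used here and
recorded as an assumption. Trials are pooled directly into the group
(without a per-participant intermediate average).

Inference on differences is done on the variance-stabilized scale
`z = atanh(|R|)`, whose variance is approximately `1/(2L)`:

* within-group heterogeneity: `chi2 = sum 2 L_i (z_i - weighted mean)^2`
  on k - 1 degrees of freedom, flagged at p < 0.05;
* between-group difference of pooled coherence: `z_a - z_b` with 95%
  limits `+/- 1.96 * sqrt(1/(2 L_a) + 1/(2 L_b))`, flagged with direction.

Band summaries average pooled coherence over alpha [8, 16), beta [16, 30)
and gamma [30, 60) Hz; bands are half-open so every bin belongs to exactly
one band (the 2.174 Hz grid puts 15.22 Hz in alpha and 17.39 Hz in beta).
Bins below 8 Hz are computed but annotated unreliable: envelope coherence
at very low frequencies does not accurately reflect low-frequency common
input. A crosstalk QC flag marks spectra whose coherence exceeds 0.8 in
*every* band simultaneously -- the signature of electrode crosstalk rather
than neural drive.

## EMG activity clustering

For the ramp-phase analysis, channel 1 of each muscle is z-normalized,
full-wave rectified, and smoothed with a 500 ms sliding RMS window
(one-sample step; at the edges the window shrinks rather than padding),
then clipped to the first 15 s of the trial and averaged across a
participant's repeats of a level.

The envelopes are then resampled to 20 Hz by linear interpolation before
clustering. After 500 ms RMS smoothing the envelope carries essentially no
content above a few hertz, and the k-shape centroid step solves an
m-by-m eigenproblem in the series length m, so clustering at the raw
2222 Hz would cost enormously more for identical shapes.

Clustering uses the shape-based distance
`SBD(x, y) = 1 - max over shifts of the coefficient-normalized
cross-correlation of the z-normalized series`, and the k-shape algorithm:
seeded random initial assignment, assignment to the nearest centroid by
SBD, centroid update by shape extraction (members aligned to the current
centroid; new centroid is the leading eigenvector of the centered Gram
matrix, z-normalized, sign-matched to the members), iterated to
stabilization with a 100-iteration cap. An update that would increase the
objective (the within-cluster SBD sum) is rejected, so the objective is
non-increasing by construction. Note that with shift maximization the SBD
of a series and its negation is `1 + (minimum lagged autocorrelation)`,
strictly below the nominal maximum of 2, because extreme lags decorrelate.

Cluster count: WCSS (within-cluster sum of squared SBDs) is reported for
k = 1..5 for elbow inspection -- the elbow is inspected, not auto-detected
-- and the average silhouette width (on the SBD matrix) selects k among
2..5. Each k is fitted from 8 seeded restarts, keeping the best objective.
A maximum silhouette below 0.25 flags the data as not supporting
clustering; the threshold is a conventional "weak structure" boundary.

## Bootstrap group statistics

Group comparisons use the percentile bootstrap: 10,000 resamples with
replacement per group, 95% CI of the mean difference and of Cohen's
`d = (mean_a - mean_b) / pooled SD`. Percentile intervals are the
simplest method consistent with resampling inference; no p-values are
produced -- an effect is read as significant when its CI excludes zero.
Effect sizes are labeled on `|d|` with half-open intervals: trivial
[0, 0.2), small [0.2, 0.5), moderate [0.5, 0.8), large [0.8, Inf);
boundary values take the upper class since the conventional ranges overlap
at their edges.

## The synthetic cohort generator

The generator exists so the pipeline can be validated against known ground
truth; it emulates the study protocol, not any particular dataset.

**Pool.** `generate_pool()` draws a rate-coded pool: recruitment
thresholds exponentially spaced over [0, 0.65] MVC (many small, few large
units); twitch amplitudes growing exponentially with threshold (30-fold
range); twitch contraction times 70 ms (smallest) to 30 ms (largest),
typical of hand muscles; biphasic derivative-of-Gaussian MUAPs whose
amplitude and duration (5--15 ms) grow with unit size.

**Rate coding.** A unit fires when pool excitation `D` (in fractional-MVC
units) exceeds its threshold, at
`rate = min_rate + gain * (D - threshold)` capped at its peak rate.
Defaults: `min_rate` 12 Hz, `gain` 100 Hz per unit excitation (about
1 Hz per %MVC, in the range reported for hand muscles), peak 30 Hz
declining by 8 Hz across the pool (onion-skin organization). Inter-spike
intervals carry multiplicative Gaussian jitter (CV 0.15). Units have a
0.02 MVC recruitment hysteresis -- once recruited they keep firing until
excitation falls that far below threshold -- emulating persistent-inward-
current behavior; without it, drive noise makes firing sputter around the
crossing and the regular-onset detector drifts late.

**Drive.** Excitation is the trapezoid plus three Gaussian noise terms:
a band-limited oscillatory component (default 21 +/- 3 Hz, SD 0.012 MVC)
of which a fraction `strength` is one shared realization injected into
both muscles' pools -- the physiologic origin of intermuscular coherence
in the generated data -- plus an independent component in the same band,
plus a slow (< 5 Hz, SD 0.006 MVC) independent component that produces
realistic force unsteadiness (hold-phase COV around 2--3% of target).
Injection-recovery experiments use an explicit strong dose
(`noise_sd = 0.03`) at `strength = 0.8`: they test whether a deliberately
injected input is recovered by the coherence chain, while the default
cohort keeps the modest oscillatory variability typical of steady
contractions. Noise shaping uses squared-magnitude Butterworth responses
applied in the frequency domain (zero-phase by construction).

**Force.** Each spike is convolved with a critically damped twitch; the
summed raw force passes through a static calibration that inverts the
pool's expected force-vs-excitation curve (including a 1% passive-elastic
term that keeps the curve strictly increasing through rate-saturated
stretches), so steady-state calibrated force is linear in excitation and
recruitment thresholds are recoverable from the force trace. Measurement
noise of 0.2% MVC is added.

**EMG.** Per-unit MUAP trains are mixed into four channels (channel gains
1 and then random 0.5--0.9), white noise is added at 15 dB SNR, and the
result is band-limited to 20--450 Hz. There is no volume-conductor model,
no fatigue, no electrode-placement drift, and decomposition "accuracy"
scores are drawn from a Gaussian (mean 94, SD 3) rather than earned from
signal quality -- so passing tests show the *analysis chain* is correct
under protocol-shaped data, not that it is robust to every artifact of
real recordings.

All randomness descends from one master seed through a splittable counter
(participant, level, repeat), so any single trial is reproducible in
isolation.

## Problem sizes and numerical choices

The test-suite and acceptance experiments use cohorts scaled for a
single-CPU run while keeping the protocol intact: 10 simulated
participants with 3 repeats for injected-drive recovery (pooled L = 240
segments, 20 cohort seeds); 500 Monte-Carlo replicates for the null
calibration of the confidence limit at L = 8 and L = 96; 100 simulated
datasets for mixed-model contrast coverage; three participants at all four
levels for firing-threshold recovery; and 20-series two-template cohorts
for cluster recovery.

Numerical conventions: seconds-to-samples conversions round half away
from zero; segment length truncates (`floor`); the DC bin of demeaned
segments is excluded from exceedance summaries; coherence at bins with a
zero auto-spectrum is defined as 0 with a warning; `atanh` arguments are
clipped just below 1; percentile CIs use the empirical quantile; k-shape
ties in assignment go to the lowest cluster index.

## Known limitations

Envelope coherence is an indirect readout of shared drive: its magnitude
depends on preprocessing choices (rectification in particular), and the
generator's injected-drive experiments quantify recovery of frequency
*location*, not of coherence magnitude. The firing-threshold detector
inherits a ramp-speed bias from its regularity criterion: during a steep
ramp the firing rate is still rising inside the 750 ms look-ahead window,
which can delay detected onsets; with the 2 s protocol ramps and the
default pool this stays under 2% MVC on average, but steeper ramps or
slower rate coding would increase it. The mixed model treats %MVC as
categorical, matching the cell-wise contrasts; it does not model
level-continuous trends.
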