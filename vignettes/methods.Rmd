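---
title: "Models and methods behind ictalysis"
author: "ictalysis authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ictalysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ictalysis)
```

## Scope

`ictalysis` analyzes chronic dual-site (dorsal CA1 / medial prefrontal
cortex) local field potential recordings and operant behavior from rodent
models of temporal lobe epilepsy. Its stages are: interictal-discharge
detection and morphometry; multitaper power spectra and coherence; Morlet
spectrograms; phase-amplitude coupling via the normalized-entropy
modulation index; frequency-domain (Geweke) Granger causality;
"sliding-sweeps" peri-event cross-correlograms; discharge-triggered
locomotion averages; and probabilistic-reversal (FED) task metrics with a
bootstrap comparison of learning slopes. A first-class synthetic-data
generator emulates the statistical structure of such sessions so that
every estimator can be validated against known injection parameters.

## Discharge detection

The detection statistic is the z-scored squared high-passed signal: the
channel is filtered above 40 Hz (Butterworth, order 4, applied
forward-backward so event timing is not lag-shifted), squared, and
standardized by the mean and SD of the squared trace. Peaks above 5 SD
mark candidate discharges; candidates closer than 50 ms are merged; the
extent of each event is grown outward from its peak to where a 20-ms
moving average of the statistic stays below 2 SD, and events shorter than
10 ms are discarded as glitches. The instantaneous squared signal of any
oscillatory transient dips to zero twice per carrier cycle, so the extent
boundary is evaluated on the lightly smoothed statistic and tolerates
sub-boundary dips shorter than the merge gap; the raw statistic still
defines threshold crossings, peak times and amplitudes.

### Why the baseline must be re-scored in heavy-discharge recordings

Whole-trace z-scoring has a hard ceiling. Because the z-scored squared
signal has unit variance by construction, the events' share of
$\int z^2\,dt$ cannot exceed the recording length, so at an event rate
$r$ each event can contribute at most $1/r$ (about 2.4 s at 0.41 events/s).
A 29.6-SD peak together with a 2-SD excursion lasting 0.44 s already
exceeds that budget: no waveform can realize the control-group amplitude,
density and duration simultaneously against a whole-trace baseline,
because the events inflate the very SD they are measured in. The detector
therefore offers `rescore = TRUE`: the baseline mean and SD are
re-estimated from samples outside the detected events and detection is
repeated. A single pass is not a fixed point — longer recovered extents
deflate the baseline further — so the refinement iterates (at most three
passes, stopping when the event count and mean amplitude stabilize within
2%). The masked region around each event uses a 0.5-SD low-water-mark
extent rather than the reported 2-SD extent, so that sub-boundary tails do
not leak into the baseline. The default remains whole-session z-scoring;
all parameter-recovery experiments in this package run with
`rescore = TRUE` for the reason above.

## The synthetic session generator

`gen_lfp()` builds three channels (CA1 right/left, PFC) as a sum of

* a 1/f background, synthesized by spectral shaping of white noise
  (default exponent 1, RMS 1);
* band-limited oscillators: hippocampal theta (7 ± 1 Hz, RMS 0.5), a
  prefrontal 4-Hz rhythm, and hippocampal gamma (80 ± 10 Hz, RMS 0.1);
* phase-amplitude coupling: the gamma component's envelope follows
  $1 + d\cos\varphi_\theta$ with depth $d \in [0,1]$ (default 0.6),
  normalized to preserve the gamma RMS — the same measurement model the
  modulation index assumes;
* interictal discharges on CA1-R at 0.41 events/s, copied to CA1-L with
  probability 0.9 at a 30 ± 5 ms lag.

The gamma RMS default (0.1) is deliberately conservative: the generator's
contract requires that a discharge-free background yield fewer than 0.02
false detections per second at 5 SD, and theta-modulated gamma bursts are
exactly the kind of transient that crosses a 5-SD threshold when the band
is made too prominent.

The discharge waveform is a damped fast transient: a 120-Hz cosine under
a flat-topped Tukey envelope (taper fraction 0.12) spanning the stated
support (default 0.44 s), decaying with constant 4x the support, plus a
slow negative sag. Three shape choices matter. The carrier sits above the
gamma band: a carrier inside it beats against the gamma oscillator with a
~50 ms coherence time, carving spurious sub-boundary notches into the
detected extent. The envelope is flat-topped rather than bell-shaped so
the detected 2-SD extent tracks the nominal support (a full-length Hann
envelope concentrates energy centrally and shortens the measured duration
by a third). And inter-discharge intervals are drawn as a 1.1-s dead time
plus an exponential whose rate is adjusted to preserve the nominal
density — physiological refractoriness that also prevents adjacent events
from fusing in the detector.

Amplitude is calibrated iteratively (inject, measure, rescale): the
z-amplitude depends on the whole recording's variance, so no closed-form
scale exists. The loop measures peak z at the known injection sites
against an event-excluded baseline and converges within 2% in a few
iterations; the recovery tests require the detector to reproduce targets
in [10, 40] within 10%.

What the generator does *not* emulate: non-stationary background (drowsy
vs. running states), electrode drift and movement artifacts, spike
waveforms (spike trains are generated directly as inhomogeneous Poisson
processes), and any biophysics of discharge generation. Passing
recoveries demonstrate estimator correctness under the stated statistical
structure, not robustness to every pathology of real recordings.

## Spectral estimation

PSD and coherence use DPSS (Slepian) multitapers. Tapers solve the
standard symmetric tridiagonal eigenproblem; above 1025 samples they are
computed on a 1025-point grid, spline-interpolated and re-orthonormalized
(interpolation error ~1e-7 for the low orders used). Defaults follow the
analysis conventions: 5000-ms segments / 500-ms overlap / TW 3 / 5 tapers
for PSD; 2000-ms segments / 100-ms overlap / TW 5 / 9 tapers for
coherence. "Overlap" is read literally as an overlap length, not a step.
Taper weights are uniform and spectra one-sided on the un-padded segment
grid; the PSD normalization satisfies Parseval (integral = variance)
within the ~5% taper bias on stationary noise. Band means are arithmetic
means over grid frequencies in half-open bands, defaulting to theta
6–10 Hz, slow-gamma 20–40 Hz, fast-gamma 60–80 Hz; the theta band is
reported variously as 4–10, 5–10 or 6–10 Hz in this literature, so the
bands are configurable and no single canonical choice is asserted.
Recordings are downsampled to 1000 Hz (FIR anti-aliasing) and band-passed
0.1–100 Hz before spectral analysis; the 0.1-Hz high-pass is implemented
by subtracting a 10-s moving average because an IIR high-pass with a
normalized cutoff of 2e-4 is numerically fragile.

## Phase-amplitude coupling

The modulation index band-passes the phase and amplitude signals
(zero-phase FIR, transition bands 20% of the band edge), takes the
instantaneous phase and envelope from the analytic signal, averages the
envelope in 18 phase bins of 20 degrees (the convention of the
normalized-entropy index; bins half-open in $[-\pi,\pi)$), and returns
$(\log N - H(P))/\log N$. Half a filter length is trimmed at each end
before binning. Comodulograms scan a 4–8 Hz phase range against 4-Hz-wide
amplitude bands stepped by 2 Hz from 2 to 200 Hz (truncated at Nyquist
with a warning). Significance is assessed against circular time-shift
surrogates of the amplitude series. The binned-entropy core is tested
against a closed-form oracle for cosine-modulated envelopes, and MI is
verified monotone in the generator's coupling depth.

## Granger causality

A bivariate VAR (default order 50 at the 1000-Hz preprocessed rate, i.e.
50 ms of history — the convention declared here, since the estimation
rate is otherwise unstated) is fitted by OLS on demeaned signals, with
stability (companion spectral radius < 1) enforced. The spectral matrix
$S(f) = H \Sigma H^*$ follows from the transfer function
$H = A(f)^{-1}$, and the directed measures are Geweke's
$F_{x \to y}(f) = \ln S_{yy} / (S_{yy} - (\Sigma_{xx} -
\Sigma_{xy}^2/\Sigma_{yy}) |H_{yx}|^2)$ on 1000 points to Nyquist.
The instantaneous term is computed by its own formula, and the
decomposition $F_{x\to y} + F_{y\to x} + F_{x\cdot y} = \ln(S_{xx}S_{yy}/
\det S)$ is verified to numerical precision; the frequency integral is
checked against the time-domain log-ratio of restricted/unrestricted
residual variances. Near-singular spectral matrices are flagged NA, never
clamped. Per-frequency condition comparisons use Benjamini-Hochberg FDR
at q = 0.05 across the grid. Whether such causality should be computed on
whole sessions or only interictal intervals is left to the caller: the
fitting functions accept any segment.

## Correlograms and locomotion

`sliding_sweeps()` bins target timestamps in a window around each
reference onset (defaults: ±0.5 s / 100-ms bins for discharge-discharge,
±1.5 s / 200-ms bins for discharge-spike; reference time zero is the
discharge onset) and averages across references. Normalization to "basal
activity" is deliberately surrogate-based: the target train is circularly
shifted (default 100 seeded shifts) and bins are z-scored against the
surrogate distribution, which calibrates to N(0,1) under independence; a
mean-rate normalization is available behind a flag. References whose
window leaves the recording are dropped and counted.

Speed is the per-frame Euclidean displacement of the 10-point
moving-averaged trajectory times the frame rate (30 fps default), with
linear interpolation across gaps of at most 5 frames and a required
pixel-to-cm scale. Event-triggered averages report pre/post window means
and per-event pairs. Task engagement is segmented as frames inside the
feeder zone whose speed lies within 2 SD of the mean in-zone speed.

## Behavioral metrics

Session metrics count lateral nose pokes and collected pellets, mean
poke-to-collection latency, efficiency (pellets/pokes) and alternance —
defined over consecutive *lateral* pokes only, since center pokes are
collections, not choices. Learning curves are fitted by OLS with Pearson
correlation; slopes are compared by case-resampling bootstrap: (day,
value) pairs are resampled with replacement within each group (1000
iterations), slopes refitted, and the two-sided p-value is the doubled
smaller tail of the slope-difference distribution about zero, capped at
1. Degenerate resamples (a single distinct day) are redrawn and counted.
The test's size under the null is verified to lie in [0.02, 0.09] at
$\alpha = 0.05$ over 200 synthetic pairs. The discrimination index is
$(t_{test} - t_{sample})/(t_{test} + t_{sample})$ on total exploration
times, antisymmetric and bounded in [-1, 1].

The FED simulator rewards the high port at 80% and the low port at 20%,
reversing the high port after a block of 15 ± 2 trials (uniform). The
simulated agent is win-stay/lose-shift — the simplest policy family that
produces non-trivial alternance and efficiency — with an oracle policy
(always the current high port) for calibration: its rewarded fraction
must equal the high-port probability within 1 percentage point over
10,000 trials.

## Problem sizes and reproducibility

Parameter-recovery experiments use ten 600-s three-channel sessions at
1000 Hz for discharge metrics, 50 replicate 10-day series for slopes, and
10,000 trials for the FED calibration; shorter sessions (60–300 s) back
the spectral, coupling and correlogram property tests. These sizes put
every stochastic recovery within a few percent of its injected value
while keeping a full validation run in minutes on one core. All
randomness flows through explicit integer seeds; generators restore the
caller's RNG state.

## Known limitations

Duration-at-boundary is convention-dependent: the reported 2-SD extent of
a calibrated 0.44-s event recovers the support to within ~10%, not
exactly, because the extent crossing happens inside the envelope taper.
Whole-trace z-scoring (the default) saturates in heavy-discharge
recordings, as derived above — use `rescore = TRUE` there. The Granger
implementation is strictly bivariate; conditional or state-space
estimators are out of scope. The comodulogram recomputes the phase band
per cell, which is wasteful for wide scans. A pure tone below the
detection high-pass leaves a near-zero-variance squared residual whose
z-scores are numerically ill-defined; the detector still reports no
events there, but per-sample values of the statistic are not meaningful
on noiseless inputs.
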