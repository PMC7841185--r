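---
title: "Quantitative EEG biomarkers of ischaemic lesion volume: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative EEG biomarkers of ischaemic lesion volume: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

After a focal cortical stroke, the EEG over the lesioned hemisphere slows:
relative delta power rises, alpha (and to a lesser degree theta) falls, and
evoked responses shrink and arrive later. In a photothrombotic rat model of
auditory-cortex infarction, these changes are graded by lesion severity, and a
small set of quantitative EEG biomarkers - relative band powers, the
delta/alpha ratio (DAR), the (delta+theta)/(alpha+beta) ratio (DTABR), and the
peak amplitude and latency of the auditory evoked potential (AEP) - carries
enough information to regress the histological lesion volume (mm^3) from a
single epidural channel.

`eegstroke` implements that analysis end to end and, because the original
recordings are not obtainable, pairs it with a synthetic-cohort generator
whose ground truth is known. Every downstream stage (conditioning, spectral
and evoked features, group statistics, model selection, split validation) is
then testable against the generator's truth rather than against irreproducible
numbers.

## Signal model of the generator

Each synthetic subject owns a lesion volume $V$ (absent for controls), an
evoked amplitude $A$ (uV), an evoked latency $L$ (s), stimulus-condition band
fractions $(f_\delta, f_\theta, f_\alpha, f_\beta)$ summing to 1, and a second
fraction profile for silent periods. A recording at 1200 Hz is

1. **Coloured background**: independent band-limited Gaussian processes for
   delta (1-4 Hz), theta (4-8), alpha (8-12), beta (12-30), plus a *slow*
   component (0.1-0.4 Hz) standing in for the large sub-delta activity of the
   anaesthetised cortex. Their variances are calibrated per subject (below).
2. **Evoked pulses**: a monophasic Gaussian deflection
   $A \exp(-(t - o_k - L)^2 / 2\sigma^2)$, $\sigma = 20$ ms, at every tone
   onset $o_k$. A single positive peak matches the dominant deflection that
   peak-amplitude/latency features are designed for.
3. **White measurement noise** (`noise_sd`, default 5 uV).

The event schedule presents four FM tone types (750 ms) and 2 s silent
periods, 100 of each in random order at a 2 s inter-stimulus interval; with a
one-ISI lead-in the last event ends at exactly 1500 s.

### Why calibration must run through the measurement chain

The spectral features are measured with Welch's method on 1 s post-onset
segments at 600 Hz: eight Hamming-tapered sections of length
$\lfloor 2N/9 \rfloor = 133$ samples with 50% overlap, zero-padded to a
256-point FFT (2.34 Hz grid). A 133-sample window spans only 0.22 s, so its
mainlobe is several hertz wide and narrow-band power smears across band
edges: a pure 1-4 Hz process returns almost as much measured theta as delta.
Two consequences drive the generator design:

* Delta-dominant *measured* profiles (e.g. 0.58/0.23/0.09/0.10) are
  unreachable by any nonnegative mixture of the four in-band processes alone -
  the delta box leaks ~45% of its measured power into theta. Steep sub-delta
  content, which leaks *into* the delta bin far more than into theta, is what
  makes such readings possible; hence the slow 0.1-0.4 Hz component as a
  fifth source. This mirrors real slow-wave-dominant EEG under isoflurane.
* Calibration is therefore empirical: for each subject the generator measures
  each unit-variance source's band-power signature through the package's own
  epoch/baseline/decimate/Welch chain, adds the evoked pulse's band powers,
  and solves a small nonnegative least-squares system for the five source
  variances that make the *measured* relative powers equal the target
  fractions. Because baseline means are taken in the silent-gain region while
  epoch content carries stimulus gains, the one-shot solution is then refined
  by up to five fixed-point iterations measuring the fully assembled signal;
  in practice two or three suffice for residuals below 0.005.

The degenerate target (1, 0, 0, 0) remains instructive: the estimator's
resolution caps the measurable delta share near 0.79 no matter the signal, so
the generator is asserted to reach that bound, not an impossible 0.95.

### Effect maps and dispersion

Stimulus-condition truth follows affine maps of volume fitted through the
study conditions' group medians:

| quantity  | map              | value at V = 3.33 / 4.14 / 4.65 |
|-----------|------------------|---------------------------------|
| amplitude | $310 - 56V$ uV   | 123.5 / 78.2 / 49.6             |
| latency   | $0.025 + 0.0525V$ s | 0.200 / 0.242 / 0.269        |
| $f_\delta$ | $0.263 + 0.068V$ | 0.489 / 0.545 / 0.579          |
| $f_\theta$ | $0.441 - 0.0455V$ | 0.290 / 0.253 / 0.230         |
| $f_\alpha$ | $0.125 - 0.0076V$ | 0.100 / 0.094 / 0.090         |

with $f_\beta = 1 -$ the rest, fractions floored at 0.01 and renormalised.
Controls sit at separate baselines (137.19 uV, 0.16 s, fractions
0.39/0.30/0.14/0.16). Lesion volumes are drawn per group from normals centred
on the published medians (3.33 / 4.14 / 4.65 mm^3) with SD = IQR/1.349,
truncated at zero.

Per-subject jitter SDs are derived from the printed interquartile ranges:
total SD = IQR/1.349, minus (in quadrature) the variance the volume map itself
induces, floored at a small positive value where the subtraction goes
negative. This makes the generated dispersion - not just the medians - match
the study's, at the cost of heteroscedastic groups (e.g. amplitude jitter 37
uV for controls but 5 uV for severe). Silent-condition fractions share one
distribution across groups (medians 0.64/0.19/0.08/0.08, jitter 0.05/0.015/
0.03), so the no-stimulation condition carries no lesion signal by
construction: its group tests should and do come out null.

The amplitude floor (5 uV), latency clamp ([0.02, 0.45] s) and fraction floor
(0.01) keep extreme jitter draws physical. Fractions are additionally kept
inside the estimator's *gamut*: the Welch parameterisation bounds the
measurable delta/theta ratio (no signal, however delta-dominant its true
spectrum, measures a theta/delta band-power ratio below ~0.31 through 0.22 s
Hamming sections with baseline correction), so sampled ground-truth profiles
are capped at delta/theta = 3.2 - indistinguishable from the steepest printed
median ratio (3.3) within its own IQRs, and representable - for the same
reason latencies are clamped inside the epoch window.

`bg_rms` (default 40 uV) sets the approximate square root of the total
measured 1-30 Hz background power. It was chosen so that single-epoch evoked
SNR is realistic (~1-3) while the 100-epoch average leaves ~4 uV of residual
noise, small against the 50-140 uV amplitudes being estimated.

## The measurement chain

* **Filtering**: 0.05-60 Hz Butterworth, 4th order, applied forward and
  backward (zero phase) to the *continuous* recording, so filter transients
  stay away from epoch edges and evoked-peak latencies are undistorted. The
  8-pole transfer-function band-pass is numerically unstable at fs = 1200
  (poles within 4e-5 of the unit circle), so the filter is realised as a
  high-pass/low-pass cascade of 4th-order stages - with edges three decades
  apart the magnitude responses are indistinguishable. Odd-reflection padding
  of 3 x (filter length - 1) = 24 samples suppresses startup transients.
* **Epoching**: pure slicing; sample $k$ (0-based) of an epoch sits at
  $t_{start} + k/f_s$, windows are half-open $[t_{start}, t_{end})$, and the
  onset sample belongs to the post-stimulus side. AEP epochs span (-0.3,
  0.5) s, PSD epochs (-0.3, 1.0) s.
* **Baseline**: subtract the mean of the last 300 ms before onset.
* **Decimation**: keep every 2nd sample (1200 to 600 Hz); the 60 Hz low-pass
  already guarantees a five-fold margin to the new Nyquist frequency, so no
  extra anti-alias stage is used.

Relative powers divide each band's summed PSD bins by the total over the four
defined bands only (1-30 Hz); sub-1 Hz and 30-60 Hz content is excluded from
the normalisation. Band intervals are half-open so the shared edges 4, 8,
12 Hz are counted once. No detrending is applied beyond the baseline
correction. The AEP peak is the *signed* post-onset maximum (an `absolute`
flag exists but is off by default), latency the onset-to-peak time with ties
broken toward the earlier sample.

## Statistics and model selection

Group comparisons are Kruskal-Wallis (chi-square approximation with tie
correction; the all-identical degenerate case is defined as H = 0, p = 1)
with Bonferroni correction across the features tested, and pairwise
Mann-Whitney post-hocs - exact for tie-free groups of at most 8, normal
approximation with continuity and tie correction otherwise (the study's
software does not document its variant; both are standard).

The regression stack reports the study's conventions: unstandardized B with
classical SEs, standardized betas $B_j \,\mathrm{sd}(x_j)/\mathrm{sd}(y)$,
$R^2$, and RMSE in the population form $\sqrt{SSE/n}$ - the residual SD, as
the residual mean of an intercept model is zero (n rather than n-1 chosen and
documented; the two readings differ by that factor alone). AIC and BIC use
the Gaussian forms $n \ln(SSE/n) + 2(k+1)$ and $n \ln(SSE/n) + (k+1)\ln n$
with constants dropped: only rank order across models on the same data is
contractually meaningful, and a numerically exact fit reports $-\infty$ to
preserve that order. Stepwise selection follows the probability-of-F rules
(enter at p < 0.05, remove at p > 0.10, both exposed as arguments), with a
tolerance guard (1e-4) that bars numerically collinear candidates, so exactly
one of a duplicated pair can enter; a model whose $R^2$ is within 1e-12 of 1
stops the search, since further entry p values would be rounding noise.
Controls are excluded from all regressions.

Repeated-split validation re-runs the *full* stepwise selection on each of
1000 random 18/3 train/test splits (selection frequencies are only meaningful
if selection is repeated per split) and scores held-out RMSE, falling back to
the training mean when nothing enters. Splits are uniform without
stratification by default (a stratified option exists); one master seed
spawns a per-iteration seed stream so any iteration is reproducible in
isolation.

## What the generator does and does not emulate

It emulates: the group structure and dispersion of the published biomarker
table, monotone volume-effect maps, evoked pulses time-locked to tone onsets,
condition-dependent spectral profiles, and the event schedule. It does not
emulate: 1/f slope variation and narrow-band oscillatory peaks, artefacts
(muscle, movement), anaesthesia-depth drift, multi-component AEP morphology
(P1/N1 complexes), or any spatial structure (one channel only). Passing tests
therefore demonstrate that the *pipeline* is correct and well calibrated, not
that the published coefficients would be recovered from real recordings -
those depend on the unavailable study data, and the package's regression
checks instead use parameter recovery on tables generated from the published
final equation (coefficients -3.962, 3.217, 6.186, -0.006, intercept 2.312).

## Problem sizes used by the tests and acceptance script

Full-scale synthesis (31 subjects, 500 events, 1500 s at 1200 Hz) is used for
the signal-chain recovery and group-structure checks - three cohorts, a few
minutes each. The regression and validation stages are exercised with 200
synthetic tables (n = 21) for stepwise recovery, 2000 null simulations for
the Kruskal-Wallis size check, and 1000-iteration split evaluations; unit
tests use 10-event schedules (~150 s recordings) to keep each file in
seconds.

## Known limitations

* The Welch parameterisation (0.22 s sections) cannot resolve the delta band;
  measured fractions are a smeared functional of the true spectrum. The
  calibration makes the generator consistent with the measure, but mapping
  measured fractions back to "true" band content is not attempted.
* Near-tied group medians (alpha in the moderate/severe groups) are not
  strictly orderable at n = 7; tests assert only orderings the data support.
* EDF support is deliberately minimal: one channel, 1 s records, no
  annotations.
* The stepwise criteria replicate a legacy selection procedure for fidelity;
  for new analyses, the all-subsets table with BIC ranking (also provided) is
  the better-behaved tool.
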