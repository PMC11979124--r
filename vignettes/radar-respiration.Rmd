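---
title: "Respiratory-rate estimation from CW Doppler radar: model, pipeline, and validation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Respiratory-rate estimation from CW Doppler radar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respiradar)
```

## The measurement problem

Respiration moves the body surface of a small rodent by distances on the
order of a millimetre. A continuous-wave (CW) Doppler radar pointed at the
animal senses this motion without contact: the reflected carrier returns
with a phase shift proportional to the instantaneous distance between
antenna and chest wall. Quadrature demodulation — mixing the received wave
with the carrier and with a 90°-shifted copy — yields two baseband channels,

$$
I(t) = A\,\sin\theta(t), \qquad
Q(t) = A\,\cos\theta(t), \qquad
\theta(t) = \frac{4\pi}{\lambda_c}\bigl(d(t) + d_0\bigr) + \phi,
$$

where $d(t)$ is the chest-wall displacement, $d_0$ the standoff distance,
$\lambda_c$ the carrier wavelength (about 12.4 mm at 24.15 GHz), and
$\phi$ a residual phase set by antennas, wiring and circuits. Because
$d(t) \ll \lambda_c$, each channel is locally an affine function of
$d(t)$ — unless its operating point sits near a null of the sine or
cosine, in which case the respiratory fundamental collapses and the other
channel must be used. This is why the package processes I and Q separately
and selects between them rather than fusing them.

`simulate_iq()` implements exactly this model; `generate_displacement()`
provides the ground-truth $d(t)$; `quantize_adc()` emulates the
acquisition board (1092 Hz, 10-bit mid-rise conversion by default).

## The instantaneous-rate pipeline

`analyze_channel()` converts one channel into a uniformly sampled
breaths-per-minute series:

1. **Low-pass filter** (radar channels only; the displacement reference
   bypasses it). A 4th-order Butterworth with 3.3 Hz cutoff, applied
   forward and backward (`signal::filtfilt`) so the net group delay is
   zero and peak times are not shifted. 3.3 Hz passes respiratory
   fundamentals up to ~200 bpm and rejects cardiac and wideband content.
2. **Peak detection.** Strict local maxima filtered by topographic
   prominence and by a minimum separation. Defaults: separation 0.25 s
   (caps the detectable rate at 240 bpm, above any anesthetized-rodent
   rate) and prominence 0.3× the MAD-based robust standard deviation of
   the filtered signal, which scales the threshold to the breathing-band
   amplitude without being inflated by outliers.
3. **Instantaneous frequency.** The reciprocal interval between
   consecutive peaks, assigned to the left peak of each interval
   ("forward" convention).
4. **Quality index.** For each interior peak $t_m$, the backward and
   forward products $\alpha = (t_m - t_{m-1}) f_m$ and
   $\beta = (t_{m+1} - t_m) f_m$ are 1 for perfectly regular breathing,
   and $Q(t_m) = e^{-(|\ln\alpha| + |\ln\beta|)} \in (0,1]$ decays as
   either interval deviates. Under the forward convention $\beta \equiv 1$
   identically, so the index reduces to the ratio of adjacent intervals;
   because the defining recursion is ambiguous on this point, a
   "centered" convention $f_m = 2/(t_{m+1}-t_{m-1})$, under which both
   factors are informative, is implemented as well. The convention used is
   recorded in every result; neither is asserted to be the original
   authors' intent, and the two agree on all regular stretches. First and
   last peaks lack a neighbour and are dropped.
5. **Abnormal-point removal.** Points with quality below 0.5 are
   discarded. 0.5 corresponds to adjacent intervals differing by a factor
   of two — a double-detected peak or a missed breath — which is the
   failure mode the gate exists to catch.
6. **Uniform resampling.** Linear interpolation of frequency and quality
   onto a 10 Hz grid spanning the retained events (no extrapolation), then
   bpm $= 60 f$. 10 Hz is far above the bandwidth of rate variability, so
   the grid choice does not smooth real structure; monotone cubic
   interpolation is available where undershoot between knots matters.

`select_channel()` keeps the series with the higher mean event quality,
resolving ties toward Q.

## Validation statistics

`pair_series()` resamples a radar-derived and a reference-derived series
onto their common time overlap (1 Hz pairing grid by default — roughly one
pair per breath at anesthetized-rat rates). `agreement_report()` then
computes Bland–Altman mean difference and 95% limits of agreement
(mean ± 1.96 sample SD, sign convention reference − radar, recorded in
the output), RMSE, MAPE (error as a percentage of the radar value by
default), and Pearson correlation.

`kruskal_posthoc()` compares rate distributions across anesthesia protocol
levels: a Kruskal–Wallis rank test followed by Dunn's pairwise z tests
with tie correction and Holm adjustment (Bonferroni available). Dunn's
test is implemented in the package — written against its standard
rank-statistic definition and cross-checked in the test suite against the
Kruskal–Wallis statistic, to which it reduces for two tie-free groups.

## What the synthetic generator emulates — and what it does not

`resp_scenario()` defines the study conditions: piecewise-constant rate
schedules (the stepped-isoflurane preset uses four 8-minute levels at
90, 85, 55 and 80 bpm, tracking the respiratory depression at deep
anesthesia and the recovery after lightening), millimetre displacement
amplitude, optional i.i.d. Gaussian cycle-to-cycle rate jitter (2 bpm in
the anesthesia presets, a few percent CV as seen in regular anesthetized
breathing), additive channel noise, and 10-bit quantization at 1092 Hz.
The default cycle shape is a raised cosine — smooth, bounded,
peak-detectable; a zero-mean sinusoid is available as the simplest mode.

The generator deliberately omits: cardiac motion superimposed on the
chest wall, sighs and apneas, posture shifts and other motion artefacts,
multipath and clutter, amplitude drift, and slow within-level rate trends.
Consequently, passing tests demonstrate the pipeline's correctness and
noise robustness under quasi-periodic breathing — they do not certify
performance against gross motion artefacts, which real recordings contain.

## Numerical choices and degenerate inputs

* Filtering is numerically stable at the 3.3 Hz / 1092 Hz operating point;
  forward–backward application squares the magnitude response, giving
  ≪ −20 dB at 10 Hz. Edge transients of zero-phase filtering can create a
  spurious peak near the record boundaries; the quality gate removes such
  a peak when its interval ratio falls below the factor-two band, and mean
  rates over tens of seconds are insensitive to it.
* ADC quantization uses a mid-rise grid over ±(A + 4·noise SD), clips
  out-of-range samples to the extreme levels, and is idempotent.
* Fewer than two detected peaks, duplicate peak times, or fewer than two
  events surviving the quality gate raise stage-labelled errors (an empty
  gated series is a warning state, since it is a legitimate outcome on
  pathological input).
* Ties in the rank tests are handled by the standard correction; on
  identical groups the Kruskal–Wallis p-value is 1 and all post-hoc
  contrasts are "ns".
* All randomness is seeded: identical (scenario, config, seed) triples
  produce bit-identical traces, and fixtures written twice are
  byte-identical.

## Problem sizes used in the checks

The packaged checks run the accuracy sweep on twenty 60-second recordings
spanning 40–120 bpm at 5% channel noise; spectral cross-checks on
40-second stationary recordings; the full 32-minute stepped-anesthesia
preset for the protocol and agreement analyses (~1900 one-hertz pairs);
and 1000 replicates of a four-group null for the size of the rank test.
These sizes give sub-bpm Monte-Carlo error on every reported quantity
while keeping a full run in well under a minute.

## Known limitations

* With the stepped preset's true medians of 90 vs 85 bpm and hundreds of
  paired samples per level, the rank test detects the 5 bpm step
  essentially always. A non-significant contrast between adjacent shallow
  levels — as reported for real animals — arises only when the two levels'
  observed medians nearly coincide (or at much smaller effective sample
  sizes); it is not reproducible from a generator whose level medians
  genuinely differ by 5 bpm. The packaged checks document this: the
  corresponding expectation is listed and fails under these conditions.
* Rate samples on the 10 Hz (or even 1 Hz) grid are strongly
  autocorrelated within a breath, so nominal p-values of the group tests
  overstate independence; no repeated-measures correction is applied,
  matching standard practice for this analysis.
* The arctangent (joint I/Q) demodulation route is intentionally not
  implemented: channels are analyzed separately and selected by quality.
* Heart-rate extraction, motion-artefact classification and real-time
  streaming are out of scope.
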