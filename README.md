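# respiradar

Contactless respiratory-rate monitoring with a continuous-wave (CW)
Doppler radar, for physiologists and veterinary researchers who need
stress-free vital-sign measurement of small laboratory animals — typically
rodents under anesthesia, where breathing rate tracks anesthetic depth and
must be watched continuously without touching the animal.

The package provides three things:

1. **A physics-based simulator.** Respiration moves the body surface by
   ~1 mm; a 24 GHz CW radar sees that motion as a phase shift of the
   reflected carrier. Quadrature demodulation gives two baseband channels

   *I(t) = A sin θ(t)*, *Q(t) = A cos θ(t)*, with
   *θ(t) = (4π/λc)(d(t) + d₀) + φ*,

   where *d(t)* is chest-wall displacement, *d₀* the standoff distance,
   *λc* the carrier wavelength and *φ* the residual phase of the front
   end. The simulator generates *d(t)* from a piecewise-constant rate
   schedule (with optional cycle-to-cycle jitter and noise), applies this
   model, and emulates the acquisition board (1092 Hz sampling, 10-bit
   ADC).

2. **An instantaneous-rate pipeline** (`analyze_channel()`): zero-phase
   3.3 Hz Butterworth low-pass (radar channels only), prominence-based
   peak detection, peak-interval instantaneous frequency, a signal-quality
   index *Q(tₘ) = exp{−(|ln α| + |ln β|)}* that flags inconsistent
   intervals, quality-gated removal of abnormal points, and linear
   resampling to a uniform breaths-per-minute series.

3. **Validation statistics**: Bland–Altman limits of agreement, Pearson
   correlation, RMSE and MAPE between radar- and reference-derived rate
   series (`agreement_report()`), and Kruskal–Wallis with Dunn post-hoc
   comparisons of rates across anesthesia protocol levels
   (`kruskal_posthoc()`).

## Worked example

Simulate two minutes of breathing that drops from 90 to 55 bpm (an
anesthesia-deepening step), estimate the rate from the radar, and compare
against the co-registered displacement reference:

```r
library(respiradar)

sc  <- resp_scenario(rbind(c(60, 90), c(60, 55)), rate_jitter_sd = 2, seed = 42)
rec <- simulate_recording(sc, radar_config(noise_sd = 0.05))

fit <- analyze_recording(rec, channel = "auto")
summary(fit)
#> Respiratory rate summary (Q channel)
#>   peaks 144 | events 142 | removed 0 | mean quality 0.974
#>   bpm: mean 72.57, median 85.31, sd 17.74, range [51.2, 93.6]

refr  <- analyze_recording(rec, channel = "R")
pairs <- pair_series(fit, refr, grid_rate = 1)
agreement_report(pairs)
#> Radar vs reference agreement
#>   n pairs                         117
#>   Root mean square error (RMSE)   0.63 bpm
#>   Mean absolute % error (MAPE)    0.53% (of radar)
#>   Correlation coefficient         0.999
#>   95% limits of agreement         -1.31 to 1.16 bpm
#>   Mean difference (reference - radar) -0.076 bpm

g <- split_by_level(fit, level_schedule(c(60, 60), c("light", "deep")))
kruskal_posthoc(g)
#> Respiratory rate by protocol level
#>   levels: light, deep (n = 587, 578)
#>   Kruskal-Wallis chi-squared = 872.568, df = 1, p = 9.02e-192
#>   Post-hoc (Dunn, holm-adjusted):
#>      light
#> deep 9.02e-192 ***
```

Reading it: the radar-derived series tracks the true step (mean 72.6 bpm
across the two halves, median 85.3 in the first), agrees with the
reference to within a fraction of a breath per minute (RMSE 0.63 bpm,
limits of agreement ±1.3 bpm), and the two anesthesia levels separate
decisively in the rank test.

The same workflow is scriptable from a shell via the installed
`exec/respiradar` entry point
(`respiradar simulate | analyze | validate | compare-groups`), which
reads/writes CSV traces with YAML column-mapping manifests — the same
route used to analyze real recordings such as the openly deposited
four-rat radar/laser dataset
(<https://data.mendeley.com/datasets/swk27btvgd/1>); see
`inst/extdata/mendeley-rat-a-manifest-template.yaml`.

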