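# hrvbands

Long-term heart rate variability (HRV) analysis for populations whose
respiration does not fit the textbook high-frequency band — toddlers and
active adults — with strict signal preprocessing and respiration-adjusted
band definitions.

## The problem

The high-frequency (HF) component of HRV captures respiratory sinus
arrhythmia, the vagally mediated, respiration-locked modulation of the
R-R interval (RRI = 60000/HR in ms). The canonical adult HF band,
0.15–0.40 Hz, assumes respiration between 9 and 24 breaths/min. Toddlers
breathe at 18–35 min⁻¹ (up to ~0.6 Hz) and adults exceed 24 min⁻¹ during
activity, so fixed narrow bands miss respiration-driven variability, and
several wider (0.15–0.80, 0.24–1.04, 0.15–1.04 Hz) or dynamically
respiration-adjusted bands compete. `hrvbands` is written for researchers
analysing multi-hour ambulatory single-lead ECG who need to choose and
defend an HF band — or to verify that the time-domain short-term metrics
(RMSSD, SD1 = RMSSD/√2) already capture what they want.

The package implements, as tidyverse-style functions over tibbles:

- **Synthetic cohort generator** — 25–33 h single-lead ECG with schedule-
  driven heart/respiration rates for toddler and adult parameterizations,
  respiration-locked RSA with state-dependent vagal depth, R-amplitude
  modulation (for ECG-derived respiration), ectopics/dropouts/noise from
  Poisson processes, accelerometer traces, activity logs, and full ground
  truth.
- **Beat processing** — Pan-Tompkins-style QRS detection; three-criterion
  artifact handling (QRS template correlation and timing, Hilbert-envelope
  individual physiological limits, successive-change vs local SD); 4 Hz
  cubic-spline resampling with an interpolation mask.
- **Respiration (EDR)** — baseline-corrected R-amplitude features, band-pass
  filtered and window-normalized; cycle detection with age/activity
  validity windows; per-segment median rate and time coverage.
- **Segmentation** — 180 s windows at 30 s steps; validity gating
  (≤ 9 s interpolated, ≤ 3.6 s in a row; quasi-stationarity
  0.8 ≤ STD₂/STD₀ ≤ 1.1; Parseval accuracy ≥ 95%; respiration coverage
  ≥ 1/3); schedule exclusions (night sleep, 12:00–14:00 nap window);
  activity classification; 30%-and-4-h participant inclusion.
- **HRV metrics** — SDNN/RMSSD, SD1/SD2, Burg AR(24) spectra of the
  quadratically detrended series, band power in HF1–HF6 (HF5/HF6 slide
  with the segment's median respiration frequency:
  lower = 0.15 + max(0, f_resp − 0.32) Hz, widths 0.25/0.65 Hz, HF6
  clamped at 0.93 Hz), prevalent-frequency fractions, and the
  differenced-series spectrum that displays the high-pass character of
  RMSSD/SD1.
- **Accordance statistics** — per participant and condition, Pearson r
  between ln SD1 and ln HF power across valid segments, Fisher
  Z′ = 0.5·ln((1+r)/(1−r)), group-by-condition summary tables, and
  three-way mixed (split-plot) ANOVAs with broom-style `tidy()`/`glance()`.

## Worked example

```r
library(hrvbands)

cfg <- cohort_config("toddler", duration_h = 2, seed = 1, fs = 250,
                     artifact_rates = list(ectopic_per_h = 0,
                                           dropout_per_h = 0,
                                           noise_per_h = 0))
p   <- simulate_participant(cfg, 1)
rec <- process_recording(p$ecg, p$log)
rec
#> <hrv_recording> toddler participant 1: 235 segments (226 valid, 96%)

rec$segments |>
  dplyr::filter(overall_valid) |>
  dplyr::select(segment_start, mean_hr, median_resp_rate, ln_sd1,
                ln_hf1, ln_hf4) |>
  head(4)
#> # A tibble: 4 × 6
#>   segment_start mean_hr median_resp_rate ln_sd1 ln_hf1 ln_hf4
#>           <dbl>   <dbl>            <dbl>  <dbl>  <dbl>  <dbl>
#> 1             0    130.             27.9   2.40   1.58   4.90
#> 2            30    130.             28.0   2.40   1.19   4.91
#> 3            60    130.             28.2   2.39   1.22   4.90
#> 4            90    130.             28.0   2.39   1.26   4.90
```

This toddler breathes at ~28 min⁻¹ (0.47 Hz) during high activity, so the
adult band HF1 (0.15–0.40 Hz) misses the respiratory peak almost entirely
(ln HF1 ≈ 1.2) while the broad band HF4 (0.15–1.04 Hz) captures it
(ln HF4 ≈ 4.9) — the package's central phenomenon. The dynamic 0.25 Hz-wide
band for this segment:

```r
hf_dynamic_band(resp_rate_to_freq(27), width = 0.25)
#> # A tibble: 1 × 2
#>   lower upper
#> 1  0.28  0.53
```

Cohort-level analysis chains the same verbs:

```r
configs <- list(toddler = cohort_config("toddler", n_participants = 6,
                                        duration_h = 6, seed = 23, fs = 250),
                adult   = cohort_config("adult", n_participants = 6,
                                        duration_h = 6, seed = 23, fs = 250))
cohort <- analyze_cohort(configs)
acc    <- participant_accordance(cohort$segments)
summarize_tables(acc)          # mean ± SD of Z' per band × group × condition
fit <- mixed_anova(acc, dv = "fisher_z", within = c("band", "condition"),
                   between = "group")
tidy(fit)                      # effect, F(df1, df2), p
plot_accordance(acc)
```

See `vignette("hrv-methods", package = "hrvbands")` for the models,
parameter choices, and validation strategy.

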