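---
title: "Long-term HRV with respiration-adjusted high-frequency bands: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Long-term HRV with respiration-adjusted high-frequency bands: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvbands)
```

## The problem

Heart rate variability (HRV) summarizes the beat-to-beat fluctuation of the
R-R interval (RRI), the time between successive ECG R peaks. Its
high-frequency (HF) component is dominated by respiratory sinus arrhythmia
(RSA), the respiration-locked modulation of heart rate by the vagus nerve.
The canonical adult HF band, 0.15--0.40 Hz, assumes respiration between 9
and 24 breaths per minute. That assumption fails for young children
(toddlers breathe at 18--35 min^-1^, i.e. up to ~0.6 Hz) and for adults
during exercise, so several wider bands have been proposed for children
(0.15--0.80 Hz, 0.24--1.04 Hz) along with bands adjusted dynamically to the
individual's current respiration rate.

`hrvbands` implements a complete long-term (25--33 h) single-lead ECG
analysis pipeline around this question: strict artifact handling of the
interval series, segment-level quality gating, ECG-derived respiration,
six HF band definitions, time-domain and Poincaré metrics, and the
per-participant *accordance* analysis — how closely the log band power in
each HF band tracks log SD1 (the Poincaré short-axis dispersion, an
equivalent of RMSSD) across all valid 180 s segments of a recording.
Because no public long-term recordings accompany the design, the package
ships a synthetic cohort generator whose defaults emulate the two study
populations; every pipeline stage is validated against that generator's
ground truth.

## Pipeline and models

### Interval model of the synthetic generator

Beats are placed by cumulative summation of

$$RRI_n = \frac{60000}{HR(t_n)} + A_{RSA}(t_n)\,\sin(2\pi\,\phi_{resp}(t_n))
  + A_{LF}\sin(2\pi\,\phi_{LF}(t_n)) + \varepsilon_n ,$$

where $HR(t)$ and the respiration rate follow a piecewise episode schedule
(night sleep, toddler nap, alternating low/high-activity daytime blocks,
60 s linear ramps), $\phi_{resp}$ is the integral of the instantaneous
respiration frequency, and $\varepsilon_n$ is white beat-to-beat noise.
An additive sinusoidal model was chosen over integral-pulse-frequency
modulation because its spectrum is analytically known, which makes the
frequency-recovery tests exact.

Two realism choices matter downstream:

* **Respiration is a band, not a line.** The instantaneous respiration
  frequency carries a slow fractional wobble (`resp_variability`, default
  4%, two incommensurate slow sinusoids) and the RSA amplitude a fixed 15%
  slow modulation. A zero-bandwidth sinusoid would give the Burg spectrum a
  pathologically narrow line that no finite frequency grid integrates
  reliably; real breathing varies by a few percent breath to breath.
* **Vagal tone is state-dependent.** The RSA depth is an episode profile
  (toddler defaults 42/25/16 ms for sleep/low/high activity; adult
  50/34/16 ms), falling from sleep to high activity. This reproduces the
  characteristic drop of short-term variability with activity and gives the
  pooled-daytime accordance analysis genuine between-state dynamic range.

Schedule defaults place the recording start at 08:00 with 30 h duration;
mean heart rates (toddler 95/115/130 bpm for sleep/low/high; adult
60/82/107 bpm) and respiration rates (toddler 22/26/28 min^-1^; adult
15.5/19.5/22.5 min^-1^) sit at the centres of the groups' physiological
ranges. Artifact events (ectopic beats with 55% coupling interval and
compensatory pause, zeroed dropouts of 3--10 s, 1--5 s noise bursts) follow
homogeneous Poisson processes; the defaults (6, 1 and 2 events/h) are
chosen as plausible for ambulatory recordings — no empirical artifact-rate
statistics exist to fit them to. The ECG itself is a fixed PQRST template
of summed Gaussian bumps; the R-wave amplitude is multiplied by
$1 + d\,\sin(2\pi\phi_{resp})$ (default depth $d = 0.1$), which is the
signal ECG-derived respiration recovers. Baseline wander is kept at 0.12
and 0.05 Hz, below the physiological respiration bands, so it cannot
masquerade as EDR.

### Artifact handling

Three criteria mark an interval invalid:

1. **QRS morphology and timing** — each beat's band-passed QRS window is
   correlated against a running-median template (window 101 beats); beats
   with correlation below 0.9 (below 0.5: artifact) or closing an interval
   shorter than 0.75 of the local median RRI are non-normal. Both
   thresholds are configurable; no published values exist for this
   "semi-automatic" step, so fixed defaults replace manual review.
2. **Individual physiological limits** — the winsorized interval series
   minus its rolling-median level is passed through the FFT analytic
   signal; the smoothed envelope magnitude gives a slowly varying corridor
   `level ± 3 × envelope` (floor 50 ms half-width), clipped to absolute
   age-dependent bounds. The bounds are deliberately wider than awake
   resting ranges (toddler 250--1000 ms, adult 333--1500 ms) because the
   corridors must admit sleep bradycardia and exercise tachycardia that
   the resting ranges exclude; the envelope, not the clamp, is the
   operative criterion.
3. **Successive change** — an interval differing from its predecessor by
   more than 3 local standard deviations (5 min window, computed on the
   envelope-clipped series so an outlier cannot inflate its own
   acceptance threshold) is invalid.

Flags are recomputed from the series alone, making the rules idempotent.
Valid intervals are resampled to a 4 Hz grid by natural cubic splines;
every grid sample replacing invalid data is masked, and gaps longer than
3.6 s are held at the last valid value rather than splined (a cubic
bridge across a long gap would invent low-frequency power).

### Segment gating

Analysis uses 180 s segments at 30 s steps. A segment is valid only if all
four criteria hold:

* at most 9 s of interpolated data in total and 3.6 s in a row (the 95% /
  2% beat-validity criterion expressed on the time grid; the run limit is
  compared inclusively at 3.6 s);
* quasi-stationarity: $0.8 \le STD_2/STD_0 \le 1.1$, where $STD_0$ is the
  SD after mean removal and $STD_2$ after least-squares quadratic
  detrending (the ratio cannot exceed 1; the 1.1 ceiling is a numerical
  guard);
* Parseval accuracy $\min(P,V)/\max(P,V) \ge 0.95$ between the Burg
  spectrum integrated over 0--1.04 Hz and $STD_2^2$;
* a usable respiration estimate covering at least one third of the
  segment.

Criteria are independent filters and validity is their conjunction, so
dropping any one criterion can only increase the valid count. Participant
inclusion requires, separately for daytime and sleep, at least 30% valid
time and at least 4 h of it, counted as distinct coverage (overlapping
windows are unioned, never double-counted). The 12:00--14:00 wall-clock
window is excluded for both groups by default (`exclude_nap_window`
disables it), as are logged daytime sleep periods.

### ECG-derived respiration

The per-beat respiratory feature is the R amplitude relative to the median
of the PR segment 0.30--0.12 s before the peak (QRS area is retained as a
secondary feature). Features of normal beats are splined to the 4 Hz grid,
band-pass filtered to the group's plausible respiration range (toddler
0.15--1.04 Hz, adult 0.10--0.75 Hz) and z-normalized in sliding 60 s
windows, making the EDR invariant to the ECG amplitude scale. Cycles are
upward zero crossings; a cycle is valid iff its implied rate falls in the
group/state window. The spec-level baselines (adult 12--18 min^-1^ at
rest) describe *resting* physiology, but ambulatory daytime medians run
near 20--21 min^-1^ in adults, so the validity windows are wider: adult
rest 8--22, awake 8--33; toddler rest 14--40, awake 14--55 min^-1^ — the
awake upper bounds carrying the ~+50% activity widening. The segment
estimate is the **median** rate over valid cycles (robust to residual
detection artifacts); coverage is time-based — the summed duration of
valid cycles over 180 s — because "possible in at least one third of the
segment" reads as time, not cycle counts.

### Spectra and bands

Each valid segment's detrended 4 Hz series is fitted with an AR(24) model
by Burg's recursion and the one-sided density evaluated on a uniform grid
of 12001 points over 0--2 Hz (step 1/6000 Hz). The step keeps every fixed
band edge on a grid node for stable trapezoidal integrals; it is ten times
finer than the minimum needed for the band edges because an AR(24) fit of
a strongly periodic segment concentrates its power in very narrow peaks.
Band powers are trapezoidal integrals with linear interpolation at
non-node edges, log-transformed after a 1 ms² × 10^-6^ floor (flagged when
triggered).

The six HF definitions: HF1 0.15--0.40, HF2 0.15--0.80, HF3 0.24--1.04,
HF4 0.15--1.04 Hz, and two dynamic bands of widths 0.25 (HF5) and 0.65 Hz
(HF6) whose lower edge is `0.15 + max(0, f_resp − 0.32)` with `f_resp` the
segment's median respiration frequency. HF6's upper edge is clamped at
0.93 Hz by truncation — the lower edge stays at `0.15 + shift` and the
band narrows; shifting the whole band down instead is selectable via
`clamp_upper`/`center_ref` arguments. HF5 is left unclamped, as only the
wide band has stated limits.

Prevalent-frequency fractions divide band integrals (0.04--0.15,
0.15--0.24, 0.24--0.40, 0.40--0.80, 0.80--1.04 Hz) by the total over
1/180--1.04 Hz. The same fractions computed on the spectrum of the
*differenced* series (successive differences of valid intervals, splined
to 4 Hz, Burg AR(24) without trend correction) display the intrinsic
high-pass filter of RMSSD/SD1: first differencing multiplies power at
frequency $f$ by $2 - 2\cos(2\pi f\,\Delta t)$, which at a typical 0.8 s
beat spacing suppresses a 0.05 Hz oscillation ~29-fold relative to a
0.40 Hz one.

### Time-domain and Poincaré metrics

SDNN and RMSSD are computed on the valid beat-to-beat intervals inside the
segment (not the resampled grid, which would smooth them); successive
pairs interrupted by an invalid interval are skipped. SD1 is computed as
the root mean square of successive differences divided by $\sqrt 2$, which
makes the identity $SD1 = RMSSD/\sqrt 2$ hold to machine precision on
every segment — the mean successive difference is negligible in practice,
and keeping the estimator uncentred preserves the exact identity that an
$n-1$ centred estimator would only approximate. SD2 is the centred SD of
$(RRI_n + RRI_{n+1})/\sqrt 2$. All other SDs in the package use the usual
sample ($n-1$) denominator.

### Accordance and inference

Per participant, Pearson correlations between ln SD1 and ln HF band power
are computed across all valid segments for each band × condition (sleep,
total daytime, low- and high-activity daytime — the activity conditions
are carved out of daytime by the within-participant median split on
segment heart rate and accelerometer dynamics, each class requiring 90 min
of distinct coverage). Correlations are clamped at $1 - 10^{-12}$ in
magnitude before the Fisher transform $Z' = 0.5\ln((1+r)/(1-r))$; cells
with fewer than 10 valid segments (configurable — no published floor
exists) or zero variance are missing. The three-way mixed ANOVA
(band × condition within, age group between) uses the classical univariate
split-plot decomposition via `aov` error strata; no sphericity correction
is applied by default, matching the uncorrected degrees-of-freedom
convention $F(5, 5(N-2))$ for the band × group interaction, with
Greenhouse–Geisser-style correction out of scope. Participants with any
missing within-cell are dropped listwise.

## A worked example

```{r example, eval = FALSE}
cfg <- cohort_config("toddler", duration_h = 2, seed = 1, fs = 250,
                     artifact_rates = list(ectopic_per_h = 0,
                                           dropout_per_h = 0,
                                           noise_per_h = 0))
p <- simulate_participant(cfg, 1)
rec <- process_recording(p$ecg, p$log)
rec$segments |>
  dplyr::filter(overall_valid) |>
  dplyr::select(segment_start, mean_hr, median_resp_rate, ln_sd1, ln_hf1,
                ln_hf4)
```

## Verification strategy and problem sizes

Every operation is tested against an independent oracle: FFT periodograms
for Burg peak locations, direct polynomial regression for detrending,
closed-form band integrals for flat spectra, the generator's ground truth
for detection, classification and respiration recovery, and simulation for
the ANOVA's type-I error (targeting the nominal 5% level) and power. The
test suite and the verification runs use 0.5--6 h recordings at
250--500 Hz sampling and cohorts of six participants per group — sizes
chosen so that the full suite exercises every code path, including the
cohort-level direction checks (toddlers' daytime 0.40--0.80 Hz share
exceeding adults'; HF4 out-according HF1 in toddler daytime), at desk
scale. The package defaults remain 1 kHz and 30 h.

## What the synthetic cohort does and does not show

The generator reproduces the *statistical structure* the pipeline assumes:
schedule-driven heart and respiration rates with the groups' physiological
separation, respiration-locked RSA with state-dependent depth, R-amplitude
modulation for EDR, low-frequency oscillations, and Poisson artifacts with
ground truth. It does not emulate pathological morphology (bundle-branch
block, atrial fibrillation), periodic breathing, electrode-motion artifact
spectra, circadian drift within episodes, or the device-specific EDF
quirks of real recorders. Passing tests therefore demonstrate correctness
of the algorithms under the stated model, and directional agreement of the
cohort-level analyses — not empirical reproduction of any real cohort's
table values, which would require the original (undeposited) recordings.

## Known limitations

* QRS detection is tuned for clean single-lead ambulatory ECG at
  >= 250 Hz; it is not an arrhythmia detector.
* The EDR uses R amplitude (plus QRS area) only; at very low modulation
  depths (< ~2%) cycle detection degrades, which is flagged through the
  respiration-coverage criterion rather than hidden.
* The accordance Z' values on clean synthetic data are higher than those
  of real recordings (correlations near 1), because the generator's HF
  power and SD1 share a single RSA source; directional comparisons between
  bands and groups are meaningful, absolute Z' levels are not.
* Long recordings at the 1 kHz default are memory-hungry in R (~1 GB per
  30 h channel); the config exposes `fs` down to 250 Hz.
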