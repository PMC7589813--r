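Package: hrvbands
Title: Long-Term Heart Rate Variability with Respiration-Adjusted
    High-Frequency Bands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete pipeline for heart rate variability (HRV) analysis of
    long-term single-lead ECG recordings in populations with widely differing
    heart and respiration rates (toddlers versus adults). Provides strict
    R-R interval artifact handling (QRS template classification, Hilbert
    envelope based individual physiological limits, successive-change
    criterion), 4 Hz cubic-spline resampling with interpolation masks,
    ECG-derived respiration (EDR), 180 s segment validity gating
    (interpolation budget, quasi-stationarity, Parseval accuracy, respiration
    coverage), time-domain and Poincare metrics (SDNN, RMSSD, SD1/SD2), Burg
    autoregressive spectra (order 24) with six high-frequency band
    definitions including bands dynamically adjusted to the segment's median
    respiration frequency, prevalent-frequency fractions of the R-R series
    and of its successive differences, per-participant accordance (Pearson r,
    Fisher Z') between ln(SD1) and ln(HF band power), and three-way mixed
    analyses of variance. Includes a synthetic long-term ECG cohort generator
    with ground-truth annotations for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    zoo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
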