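# Shared fixtures, built once per test run. Recordings are generated at
# reduced sampling rates and durations to keep the suite fast; the detector
# supports anything >= 250 Hz.

.fx <- new.env(parent = emptyenv())

fx_memo <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# clean half-hour adult recording (no artifacts), 500 Hz
fx_clean_adult <- function() {
  fx_memo("clean_adult", function() {
    cfg <- cohort_config(
      "adult", duration_h = 0.5, seed = 101, fs = 500,
      artifact_rates = list(ectopic_per_h = 0, dropout_per_h = 0,
                            noise_per_h = 0))
    p <- simulate_participant(cfg, 1)
    p$config <- cfg
    p
  })
}

fx_clean_adult_processed <- function() {
  fx_memo("clean_adult_proc", function() {
    p <- fx_clean_adult()
    process_recording(p$ecg, p$log)
  })
}

# 20-minute adult recording with a high ectopic rate, for classifier checks
fx_ectopic_adult <- function() {
  fx_memo("ectopic_adult", function() {
    cfg <- cohort_config(
      "adult", duration_h = 1 / 3, seed = 202, fs = 500,
      artifact_rates = list(ectopic_per_h = 60, dropout_per_h = 0,
                            noise_per_h = 0))
    p <- simulate_participant(cfg, 1)
    p$config <- cfg
    p
  })
}

# constant-rate beat series as an rri_series tibble
fx_rri_series <- function(rri_ms, n = NULL, times = NULL) {
  if (is.null(times)) times <- cumsum(rep(rri_ms, n)) / 1000
  if (length(rri_ms) == 1) rri_ms <- rep(rri_ms, length(times))
  tibble::tibble(time_s = times, rri_ms = rri_ms,
                 beats_normal = TRUE, valid = TRUE)
}

# beat series with sinusoidally modulated intervals (mean_ms + amp*sin(2pi f t))
fx_sine_rri <- function(mean_ms, amp_ms, freq_hz, duration_s,
                        noise_ms = 0, seed = 1) {
  set.seed(seed)
  t <- 0
  times <- c()
  vals <- c()
  while (t < duration_s) {
    v <- mean_ms + amp_ms * sin(2 * pi * freq_hz * t) + rnorm(1, 0, noise_ms)
    t <- t + v / 1000
    if (t >= duration_s) break
    times <- c(times, t)
    vals <- c(vals, v)
  }
  tibble::tibble(time_s = times, rri_ms = vals,
                 beats_normal = TRUE, valid = TRUE)
}

# flat-schedule config: one constant HR/respiration level everywhere,
# no artifacts; `rsa`, `lf`, `noise` control the interval model terms
cfg_flat <- function(group = "adult", hr = 60, resp = 15, duration_h = 0.1,
                     rsa = 0, lf = 0, noise = 0, seed = 1, rv = 0, ...) {
  lev <- c(sleep = 1, nap = 1, low_activity = 1, high_activity = 1)
  cohort_config(group, duration_h = duration_h, seed = seed,
                hr_profile = hr * lev, resp_profile = resp * lev,
                rsa_amplitude_ms = rsa, lf_amplitude_ms = lf,
                rri_noise_ms = noise, resp_variability = rv,
                artifact_rates = list(ectopic_per_h = 0, dropout_per_h = 0,
                                      noise_per_h = 0), ...)
}

# beat series carrying two interval tones of equal amplitude
fx_two_tone_rri <- function(mean_ms = 800, amp_ms = 30, f1 = 0.05, f2 = 0.40,
                            duration_s = 900) {
  t <- 0
  times <- c(); vals <- c()
  while (t < duration_s) {
    v <- mean_ms + amp_ms * sin(2 * pi * f1 * t) +
      amp_ms * sin(2 * pi * f2 * t)
    t <- t + v / 1000
    if (t >= duration_s) break
    times <- c(times, t); vals <- c(vals, v)
  }
  tibble::tibble(time_s = times, rri_ms = vals,
                 beats_normal = TRUE, valid = TRUE)
}

# FFT periodogram argmax -- independent oracle for spectral peak location
oracle_periodogram_peak <- function(x, fs, fmin = 0, fmax = fs / 2) {
  x <- x - mean(x)
  n <- length(x)
  sp <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1) * fs / n
  sel <- f >= fmin & f <= fmax & f <= fs / 2
  f[sel][which.max(sp[sel])]
}
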