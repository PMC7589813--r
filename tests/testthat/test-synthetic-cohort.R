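test_that("deterministic schedule gives the exact interval identity", {
  truth <- generate_rri_ground_truth(cfg_flat(hr = 60), 1)
  rri <- diff(truth$beat_times) * 1000
  expect_equal(rri, rep(1000, length(rri)), tolerance = 1e-9)

  truth2 <- generate_rri_ground_truth(cfg_flat("toddler", hr = 120,
                                               noise = 3), 1)
  rri2 <- diff(truth2$beat_times) * 1000
  expect_equal(mean(rri2), 500, tolerance = 3 * 3 / sqrt(length(rri2)) / 500 + 1e-3)
})

test_that("generation is bit-identical under the same seed and differs across participants", {
  cfg <- cohort_config("toddler", duration_h = 0.05, seed = 9, fs = 250)
  a <- simulate_participant(cfg, 1)
  b <- simulate_participant(cfg, 1)
  expect_identical(a$truth$beat_times, b$truth$beat_times)
  expect_identical(a$ecg$samples, b$ecg$samples)
  expect_identical(a$truth$artifact_windows, b$truth$artifact_windows)
  c <- simulate_participant(cfg, 2)
  expect_false(identical(a$truth$beat_times, c$truth$beat_times))
})

test_that("generated intervals are always physiological (> 200 ms)", {
  for (g in c("toddler", "adult")) {
    cfg <- cohort_config(g, duration_h = 0.3, seed = 3)
    tr <- generate_rri_ground_truth(cfg, 1)
    expect_true(all(diff(tr$beat_times) * 1000 > 200))
    expect_false(is.unsorted(tr$beat_times, strictly = TRUE))
  }
  expect_error(generate_rri_ground_truth(cfg_flat(hr = 400), 1),
               "non-physiological")
})

test_that("toddler heart rate exceeds adult in every episode type (default configs)", {
  # beat-level ground truth over a full 26 h so that sleep, nap and both
  # activity levels are all present
  hrs <- lapply(c(toddler = "toddler", adult = "adult"), function(g) {
    cfg <- cohort_config(g, duration_h = 26, seed = 4)
    tr <- generate_rri_ground_truth(cfg, 1)
    mid <- tr$beat_times[-1] - diff(tr$beat_times) / 2
    ep <- tr$episodes
    lab <- ep$label[findInterval(mid, ep$begin_s, rightmost.closed = TRUE)]
    tapply(60000 / (diff(tr$beat_times) * 1000), lab, mean)
  })
  for (lab in c("sleep", "low_activity", "high_activity")) {
    expect_gt(hrs$toddler[[lab]], hrs$adult[[lab]])
  }
  expect_true("nap" %in% names(hrs$toddler))
})

test_that("programmed RSA frequency is recovered from the interval spectrum", {
  cfg <- cfg_flat(hr = 70, resp = 15, duration_h = 1 / 6, rsa = 30, rv = 0)
  tr <- generate_rri_ground_truth(cfg, 1)
  rri <- tibble::tibble(time_s = tr$beat_times[-1],
                        rri_ms = diff(tr$beat_times) * 1000,
                        beats_normal = TRUE, valid = TRUE)
  g <- resample_to_4hz(rri)
  x <- detrend2(g$rri_ms[41:2088])  # contiguous inner stretch, away from edges
  psd <- burg_psd(x)
  hf <- psd[psd$freq_hz >= 0.15 & psd$freq_hz <= 1.04, ]
  peak_burg <- hf$freq_hz[which.max(hf$density)]
  peak_fft <- oracle_periodogram_peak(x, GRID_FS, 0.15, 1.04)
  expect_equal(peak_burg, 0.25, tolerance = 0.02 / 0.25)
  expect_equal(peak_burg, peak_fft, tolerance = 0.02 / 0.25)
  # spectral concentration: >= 95% of HF-range power within +-0.05 Hz
  p_all <- integrate_psd(psd, 0.15, 1.04)
  p_near <- integrate_psd(psd, 0.20, 0.30)
  expect_gte(p_near / p_all, 0.95)
})

test_that("R-wave amplitude carries the respiration signal at the programmed depth", {
  cfg <- cfg_flat(hr = 70, resp = 18, duration_h = 0.15, fs = 250,
                  edr_depth = 0.1)
  p <- simulate_participant(cfg, 1)
  beat_amps_4hz <- function(p) {
    bt <- p$truth$beat_times
    keep <- bt > 0.3 & bt < p$ecg$duration_s - 0.5
    bt <- bt[keep]
    a <- p$ecg$samples[round(bt * p$ecg$fs) + 1]
    gr <- seq(min(bt), max(bt), by = 0.25)
    stats::approx(bt, a, xout = gr)$y
  }
  f_peak <- oracle_periodogram_peak(beat_amps_4hz(p), 4, 0.1, 1)
  expect_equal(f_peak, 0.30, tolerance = 0.02 / 0.30)

  # with zero depth there is no concentration at the respiration frequency
  cfg0 <- cfg_flat(hr = 70, resp = 18, duration_h = 0.15, fs = 250,
                   edr_depth = 0)
  p0 <- simulate_participant(cfg0, 1)
  amp_band_power <- function(p) {
    x <- beat_amps_4hz(p)
    x <- x - mean(x)
    sp <- Mod(stats::fft(x))^2
    f <- (seq_along(x) - 1) * 4 / length(x)
    sum(sp[f >= 0.28 & f <= 0.32]) / sum(sp[f >= 0.05 & f <= 2])
  }
  expect_gt(amp_band_power(p), 10 * amp_band_power(p0))
})

test_that("the rendered R peak sits at the ground-truth beat time", {
  p <- fx_clean_adult()
  fs <- p$ecg$fs
  bt <- p$truth$beat_times
  bt <- bt[bt > 0.3 & bt < p$ecg$duration_s - 0.4][1:200]
  err <- vapply(bt, function(t0) {
    i0 <- round((t0 - 0.05) * fs); i1 <- round((t0 + 0.05) * fs)
    t_max <- (i0 + which.max(abs(p$ecg$samples[i0:i1])) - 2) / fs
    abs(t_max - t0)
  }, numeric(1))
  expect_lt(median(err) * 1000, 5)   # ms
})

test_that("artifact injection follows the programmed Poisson rates and is recorded", {
  cfg0 <- cfg_flat(hr = 70, duration_h = 0.1)
  tr0 <- generate_rri_ground_truth(cfg0, 1)
  tr0b <- inject_artifacts(tr0, cfg0, 1)
  expect_identical(tr0b$beat_times, tr0$beat_times)
  expect_identical(tr0b$beat_labels, tr0$beat_labels)
  expect_equal(nrow(tr0b$artifact_windows), 0)

  cfg <- cohort_config("adult", duration_h = 2, seed = 30,
                       artifact_rates = list(ectopic_per_h = 12,
                                             dropout_per_h = 0,
                                             noise_per_h = 0))
  counts <- vapply(1:30, function(i) {
    tr <- generate_rri_ground_truth(cfg, i)
    sum(inject_artifacts(tr, cfg, i)$beat_labels == "ectopic")
  }, numeric(1))
  # mean of 30 Poisson(24) draws: SE ~ 0.9
  expect_equal(mean(counts), 24, tolerance = 4 * sqrt(24 / 30) / 24)
  expect_gt(var(counts), 0)
})

test_that("dropout windows are rendered as exact zeros", {
  cfg <- cohort_config("adult", duration_h = 0.2, seed = 7, fs = 250,
                       artifact_rates = list(ectopic_per_h = 0,
                                             dropout_per_h = 20,
                                             noise_per_h = 0))
  p <- simulate_participant(cfg, 1)
  w <- p$truth$artifact_windows
  expect_gt(nrow(w), 0)
  for (j in seq_len(nrow(w))) {
    i0 <- floor(w$begin_s[j] * p$ecg$fs) + 2
    i1 <- ceiling(w$end_s[j] * p$ecg$fs) - 1
    expect_true(all(p$ecg$samples[i0:i1] == 0))
  }
})

test_that("activity log is ordered, non-overlapping, and includes the toddler nap", {
  cfg <- cohort_config("toddler", duration_h = 8, seed = 2)
  tr <- generate_rri_ground_truth(cfg, 1)
  log <- generate_activity_log(tr)
  expect_true(all(diff(log$begin_s) > 0))
  expect_true(all(log$end_s[-nrow(log)] <= log$begin_s[-1] + 1e-9))
  expect_true(all(log$end_s > log$begin_s))
  # nap row intersecting 12:00-14:00 wall clock (recording starts 08:00)
  nap <- log[log$label == "nap", ]
  expect_gte(nrow(nap), 1)
  expect_true(any(nap$begin_s < 6 * 3600 & nap$end_s > 4 * 3600))

  cfga <- cohort_config("adult", duration_h = 26, seed = 2)
  loga <- generate_activity_log(generate_rri_ground_truth(cfga, 1))
  expect_true(any(loga$label == "sleep" & loga$is_sleep))
  expect_false(any(loga$label == "nap"))
})
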