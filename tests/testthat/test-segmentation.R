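test_that("segment grid: maximal 180 s windows at 30 s steps", {
  expect_equal(make_segments(300)$segment_start, c(0, 30, 60, 90, 120))
  expect_equal(nrow(make_segments(180)), 1)
  expect_equal(nrow(make_segments(179)), 0)
  g <- resample_to_4hz(fx_rri_series(1000, n = 400))
  s <- make_segments(g)
  expect_true(all(diff(s$segment_start) == 30))
})

test_that("interpolation budget: 9 s total, 3.6 s in a row", {
  m0 <- rep(FALSE, 720)
  r <- check_beat_validity(m0)
  expect_equal(r$interpolated_total_s, 0)
  expect_true(r$beat_validity_ok)

  # 36 masked samples (9 s) scattered with a longest run of 8 (2 s): passes
  m1 <- rep(FALSE, 720)
  m1[c(seq(1, 136, by = 5)[1:28], 300:307)] <- TRUE
  r1 <- check_beat_validity(m1)
  expect_equal(r1$interpolated_total_s, 9)
  expect_equal(r1$max_interpolated_run_s, 2)
  expect_true(r1$beat_validity_ok)

  # a single run of 15 samples (3.75 s) exceeds the in-a-row limit
  m2 <- rep(FALSE, 720)
  m2[100:114] <- TRUE
  r2 <- check_beat_validity(m2)
  expect_equal(r2$max_interpolated_run_s, 3.75)
  expect_false(r2$beat_validity_ok)

  # 40 masked samples (10 s) in short runs exceed the total budget
  m3 <- rep(FALSE, 720)
  m3[seq(1, 400, by = 10)[1:40]] <- TRUE
  expect_false(check_beat_validity(m3)$beat_validity_ok)
})

test_that("quasi-stationarity ratio behaves like a trend detector", {
  set.seed(5)
  wn <- rnorm(720)
  r <- stationarity_ratio(wn)
  expect_lte(r$stationarity_ratio, 1)         # least-squares projection
  expect_gte(r$stationarity_ratio, 0.99)      # only 2 d.o.f. removed
  expect_true(r$stationarity_ok)
  # oracle: direct polynomial regression residuals
  t <- seq_len(720)
  res <- residuals(lm(wn ~ t + I(t^2)))
  expect_equal(r$std2, sd(res), tolerance = 1e-10)

  ramp <- seq(0, 100, length.out = 720) + rnorm(720, 0, 0.1)
  r2 <- stationarity_ratio(ramp)
  expect_lt(r2$stationarity_ratio, 0.1)
  expect_false(r2$stationarity_ok)

  r3 <- stationarity_ratio(rep(5, 720))
  expect_false(r3$stationarity_ok)
  expect_true(is.na(r3$stationarity_ratio))
})

test_that("Parseval gate compares spectral and time-domain power", {
  # flat synthetic density: integral over 0-1.04 Hz is known exactly
  f <- seq(0, 2, length.out = 12001)
  psd <- structure(tibble::tibble(freq_hz = f, density = rep(10, 12001)),
                   class = c("psd_estimate", class(tibble::tibble())))
  p0 <- integrate_psd(psd, 0, 1.04)
  expect_equal(p0, 10.4, tolerance = 1e-9)
  expect_equal(parseval_check(psd, sqrt(p0))$parseval_accuracy, 1)
  r <- parseval_check(psd, sqrt(p0 / 0.94))
  expect_equal(r$parseval_accuracy, 0.94, tolerance = 1e-9)
  expect_false(r$parseval_ok)
  expect_false(parseval_check(psd, 0)$parseval_ok)

  # beat-domain white noise through the pipeline: median accuracy >= 0.95
  acc <- vapply(1:12, function(i) {
    rri <- fx_rri_series(0, times = cumsum(rep(0.8, 300)))
    set.seed(i)
    rri$rri_ms <- 800 + rnorm(300, 0, 20)
    g <- resample_to_4hz(rri)
    x <- g$rri_ms[41:760]
    st <- stationarity_ratio(x)
    parseval_check(burg_psd(detrend2(x)), st$std2)$parseval_accuracy
  }, numeric(1))
  expect_gte(median(acc), 0.95)
})

test_that("schedule exclusions: night sleep, nap window, majority overlap", {
  log <- tibble::tibble(
    begin_s = c(0, 14 * 3600),
    end_s = c(14 * 3600, 23 * 3600),
    label = c("awake", "sleep"),
    is_sleep = c(FALSE, TRUE))
  segs <- make_segments(23 * 3600)
  out <- apply_schedule_exclusions(segs, log, start_clock_s = 8 * 3600)
  cond_at <- function(s) out$condition[out$segment_start == s]
  # 12:30 wall clock = 4.5 h into the recording: inside the nap window
  expect_equal(cond_at(4.5 * 3600), "excluded")
  # 18:00 into the recording = 02:00 wall clock of the logged sleep
  expect_equal(cond_at(18 * 3600), "sleep")
  # plain afternoon daytime
  expect_equal(cond_at(6.5 * 3600), "daytime")
  # boundary straddling: majority overlap decides
  expect_equal(cond_at(14 * 3600 - 60), "sleep")    # 120/180 s in sleep
  expect_equal(cond_at(14 * 3600 - 120), "daytime") # 60/180 s in sleep
})

test_that("activity split uses within-participant medians and a 90 min floor", {
  n <- 200
  segs <- tibble::tibble(
    segment_start = seq(0, by = 180, length.out = n),  # disjoint segments
    condition = "daytime",
    mean_hr = c(rep(80, n / 2), rep(110, n / 2)),
    accel_sd = c(rep(0.02, n / 2), rep(0.3, n / 2)))
  out <- classify_activity(segs)
  expect_true(all(out$activity[1:(n / 2)] == "low"))
  expect_true(all(out$activity[(n / 2 + 1):n] == "high"))
  expect_true(attr(out, "activity_ok"))

  # constant heart rate and accelerometer: ties, nothing labelled
  segs2 <- segs
  segs2$mean_hr <- 90
  segs2$accel_sd <- 0.1
  out2 <- classify_activity(segs2)
  expect_true(all(is.na(out2$activity)))
  expect_false(attr(out2, "activity_ok"))

  # only 80 min of high-activity coverage: participant fails the floor
  n3 <- 100
  segs3 <- tibble::tibble(
    segment_start = seq(0, by = 180, length.out = n3),
    condition = "daytime",
    mean_hr = c(rep(80, 73), rep(110, 27)),     # 27 * 180 s = 81 min
    accel_sd = c(rep(0.02, 73), rep(0.3, 27)))
  out3 <- classify_activity(segs3, min_minutes = 90)
  expect_false(attr(out3, "activity_ok"))
})

test_that("inclusion needs 30% valid and 4 h in both day and sleep", {
  mk <- function(n_day, v_day, n_sleep, v_sleep) {
    tibble::tibble(
      segment_start = seq(0, by = 180, length.out = n_day + n_sleep),
      condition = rep(c("daytime", "sleep"), c(n_day, n_sleep)),
      overall_valid = c(rep(c(TRUE, FALSE), c(v_day, n_day - v_day)),
                        rep(c(TRUE, FALSE), c(v_sleep, n_sleep - v_sleep))))
  }
  # 60% day (6 h), 86% sleep (6 h): included
  r1 <- decide_inclusion(mk(200, 120, 140, 120))
  expect_true(r1$included)
  expect_equal(r1$valid_fraction_day, 0.6)
  expect_equal(r1$valid_hours_day, 6)
  # 29% valid during the day: excluded even with ample hours
  r2 <- decide_inclusion(mk(300, 87, 140, 120))
  expect_false(r2$included)
  # 87% of sleep valid but only 3.5 h of it: excluded
  r3 <- decide_inclusion(mk(200, 120, 80, 70))
  expect_equal(r3$valid_hours_sleep, 3.5)
  expect_false(r3$included)
})

test_that("overlapping valid segments never double-count coverage", {
  # 10 consecutive segments at 30 s stride span 180 + 9*30 = 450 s
  segs <- tibble::tibble(
    segment_start = seq(0, by = 30, length.out = 10),
    condition = "daytime",
    overall_valid = TRUE)
  r <- decide_inclusion(segs)
  expect_equal(r$valid_hours_day * 3600, 450)
})

test_that("dropping any criterion can only increase the valid count", {
  rec <- fx_clean_adult_processed()
  s <- rec$segments
  n_all <- sum(s$overall_valid)
  for (crit in c("beat_validity_ok", "stationarity_ok", "parseval_ok",
                 "resp_ok")) {
    others <- setdiff(c("beat_validity_ok", "stationarity_ok",
                        "parseval_ok", "resp_ok"), crit)
    n_without <- sum(Reduce(`&`, s[others]))
    expect_gte(n_without, n_all)
  }
  # criterion 1 alone admits at least as many segments as all four
  expect_gte(sum(s$beat_validity_ok), n_all)
})
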