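# Synthetic long-term ECG cohort generator.
#
# The generator emulates the statistical structure the analysis assumes for
# two populations: toddlers (high heart and respiration rates, an afternoon
# nap) and young adults. The R-R interval model is additive sinusoidal
# modulation of the schedule-driven mean interval:
#
#   RRI_n = 60000/HR(t_n) + A_rsa sin(2 pi phi_resp(t_n))
#                         + A_lf sin(2 pi f_lf t_n) + eps_n
#
# with beats placed by cumulative summation. The spectrum of this model is
# analytically known, which makes frequency-recovery tests exact.

#' Configuration for a synthetic cohort
#'
#' Bundles the physiological schedule and noise/artifact parameters used by
#' [generate_rri_ground_truth()], [synthesize_ecg()] and friends. Defaults
#' reflect the two study populations: toddlers sleep ~20:00-06:30 with a
#' post-lunch nap and run awake heart rates within 80-140 bpm and respiration
#' 18-35 breaths/min; adults sleep ~23:00-07:00 with heart rates within
#' 40-100 bpm at rest and respiration 12-18 breaths/min at rest. Recordings
#' start at 08:00 and last 30 h by default.
#'
#' @param group `"toddler"` or `"adult"`.
#' @param n_participants Number of participants the cohort should contain.
#' @param duration_h Recording duration in hours (default 30).
#' @param seed Integer seed; together with the participant index it fully
#'   determines every generated sample.
#' @param hr_profile Named numeric vector of mean heart rates (bpm) per
#'   episode type (`sleep`, `nap`, `low_activity`, `high_activity`).
#' @param resp_profile Named numeric vector of respiration rates
#'   (breaths/min) per episode type.
#' @param rsa_amplitude_ms Depth of the respiratory sinus arrhythmia
#'   modulation of the R-R interval, ms. Either a single number or a named
#'   vector per episode type; the defaults fall from sleep (high vagal
#'   tone) to high activity (vagal withdrawal), which is what makes
#'   short-term variability state-dependent.
#' @param lf_amplitude_ms Depth of the low-frequency modulation, ms.
#' @param lf_freq_hz Frequency of the low-frequency modulation (within
#'   0.04-0.15 Hz).
#' @param rri_noise_ms Standard deviation of white beat-to-beat noise, ms.
#' @param resp_variability Fractional slow modulation of the instantaneous
#'   respiration frequency (default 0.04): real breathing is not a pure
#'   tone, and this spreads the respiratory sinus arrhythmia line into a
#'   physiological band. The RSA amplitude is co-modulated by a fixed 15%
#'   and the low-frequency oscillation frequency by 5%.
#' @param edr_depth Fractional modulation of the R-wave amplitude by
#'   respiration (drives ECG-derived respiration).
#' @param artifact_rates Named list of per-hour rates: `ectopic_per_h`,
#'   `dropout_per_h`, `noise_per_h`.
#' @param fs ECG sampling rate, Hz (device default 1000).
#' @param accel_fs Accelerometer sampling rate, Hz.
#' @return A list of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config("toddler", n_participants = 2, duration_h = 2, seed = 1)
#' cfg$hr_profile
cohort_config <- function(group = c("toddler", "adult"),
                          n_participants = 1L,
                          duration_h = 30,
                          seed = 1L,
                          hr_profile = NULL,
                          resp_profile = NULL,
                          rsa_amplitude_ms = NULL,
                          lf_amplitude_ms = 15,
                          lf_freq_hz = 0.1,
                          rri_noise_ms = 4,
                          resp_variability = 0.04,
                          edr_depth = 0.10,
                          artifact_rates = list(ectopic_per_h = 6,
                                                dropout_per_h = 1,
                                                noise_per_h = 2),
                          fs = 1000,
                          accel_fs = 25) {
  group <- match.arg(group)
  if (duration_h <= 0) stop("`duration_h` must be positive", call. = FALSE)
  if (fs < 250) stop("`fs` must be at least 250 Hz", call. = FALSE)
  defaults <- if (group == "toddler") {
    list(
      hr = c(sleep = 95, nap = 95, low_activity = 115, high_activity = 130),
      resp = c(sleep = 22, nap = 22, low_activity = 26, high_activity = 28),
      rsa = c(sleep = 42, nap = 42, low_activity = 25, high_activity = 16)
    )
  } else {
    list(
      hr = c(sleep = 60, nap = 60, low_activity = 82, high_activity = 107),
      resp = c(sleep = 15.5, nap = 15.5, low_activity = 19.5,
               high_activity = 22.5),
      rsa = c(sleep = 50, nap = 50, low_activity = 34, high_activity = 16)
    )
  }
  hr_profile <- hr_profile %||% defaults$hr
  resp_profile <- resp_profile %||% defaults$resp
  rsa_amplitude_ms <- rsa_amplitude_ms %||% defaults$rsa
  if (length(rsa_amplitude_ms) == 1L && is.null(names(rsa_amplitude_ms))) {
    rsa_amplitude_ms <- c(sleep = rsa_amplitude_ms, nap = rsa_amplitude_ms,
                          low_activity = rsa_amplitude_ms,
                          high_activity = rsa_amplitude_ms)
  }
  stopifnot(
    all(c("sleep", "low_activity", "high_activity") %in% names(hr_profile)),
    all(c("sleep", "low_activity", "high_activity") %in% names(resp_profile)),
    all(c("sleep", "low_activity", "high_activity") %in%
          names(rsa_amplitude_ms)),
    all(rsa_amplitude_ms >= 0), lf_amplitude_ms >= 0, rri_noise_ms >= 0,
    edr_depth >= 0, resp_variability >= 0, all(unlist(artifact_rates) >= 0)
  )
  if (!"nap" %in% names(hr_profile)) hr_profile["nap"] <- hr_profile["sleep"]
  if (!"nap" %in% names(resp_profile)) resp_profile["nap"] <- resp_profile["sleep"]
  if (!"nap" %in% names(rsa_amplitude_ms)) {
    rsa_amplitude_ms["nap"] <- rsa_amplitude_ms["sleep"]
  }
  structure(list(
    group = group,
    n_participants = as.integer(n_participants),
    duration_h = duration_h,
    seed = as.integer(seed),
    hr_profile = hr_profile,
    resp_profile = resp_profile,
    rsa_amplitude_ms = rsa_amplitude_ms,
    lf_amplitude_ms = lf_amplitude_ms,
    lf_freq_hz = lf_freq_hz,
    rri_noise_ms = rri_noise_ms,
    resp_variability = resp_variability,
    edr_depth = edr_depth,
    artifact_rates = artifact_rates,
    fs = fs,
    accel_fs = accel_fs,
    start_clock_s = 8 * 3600    # recordings start at 08:00
  ), class = "cohort_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic per-participant, per-stage RNG seed (kept below 2^31).
stage_seed <- function(config, participant_index, stage) {
  s <- (as.double(config$seed) * 1000003 +
          as.double(participant_index) * 7919 + stage * 131) %% 2147483647
  as.integer(s)
}

# Episode schedule in seconds since recording start. Awake stretches are
# subdivided into alternating low/high activity blocks (30-60 min, jittered
# per participant so cohorts are not clones).
episode_schedule <- function(config, participant_index) {
  set.seed(stage_seed(config, participant_index, 0L))
  dur <- config$duration_h * 3600
  start <- config$start_clock_s
  day <- 86400
  # Wall-clock anchors (seconds of day, possibly spanning into the next day).
  if (config$group == "toddler") {
    anchors <- list(
      c(start, 12.5 * 3600, "awake"),
      c(12.5 * 3600, 13.75 * 3600, "nap"),
      c(13.75 * 3600, 20 * 3600, "awake"),
      c(20 * 3600, day + 6.5 * 3600, "sleep"),
      c(day + 6.5 * 3600, day + 15 * 3600, "awake")
    )
  } else {
    anchors <- list(
      c(start, 23 * 3600, "awake"),
      c(23 * 3600, day + 7 * 3600, "sleep"),
      c(day + 7 * 3600, day + 15 * 3600, "awake")
    )
  }
  ep <- purrr::map_dfr(anchors, function(a) {
    tibble(begin_s = as.numeric(a[1]) - start,
           end_s = as.numeric(a[2]) - start,
           label = a[3])
  })
  # clip to recording span
  ep <- dplyr::filter(ep, .data$begin_s < dur, .data$end_s > 0)
  ep$begin_s <- pmax(ep$begin_s, 0)
  ep$end_s <- pmin(ep$end_s, dur)
  # subdivide awake stretches into low/high blocks
  out <- purrr::map_dfr(seq_len(nrow(ep)), function(i) {
    row <- ep[i, ]
    if (row$label != "awake") return(row)
    t0 <- row$begin_s
    blocks <- list()
    state <- if (runif(1) < 0.5) "low_activity" else "high_activity"
    while (t0 < row$end_s) {
      len <- if (state == "low_activity") runif(1, 2400, 3600) else runif(1, 1500, 2400)
      t1 <- min(t0 + len, row$end_s)
      blocks[[length(blocks) + 1L]] <- tibble(begin_s = t0, end_s = t1,
                                              label = state)
      t0 <- t1
      state <- if (state == "low_activity") "high_activity" else "low_activity"
    }
    dplyr::bind_rows(blocks)
  })
  dplyr::arrange(out, .data$begin_s)
}

# Piecewise schedule value with linear 60 s ramps between episodes,
# evaluated on a uniform grid.
schedule_on_grid <- function(episodes, profile, grid, ramp_s = 60) {
  vals <- profile[episodes$label]
  knots_t <- c()
  knots_v <- c()
  for (i in seq_len(nrow(episodes))) {
    a <- episodes$begin_s[i]
    b <- episodes$end_s[i]
    half <- (b - a) / 2
    r <- min(ramp_s / 2, half)
    knots_t <- c(knots_t, a + r, b - r)
    knots_v <- c(knots_v, vals[i], vals[i])
  }
  approx(knots_t, knots_v, xout = grid, rule = 2)$y
}

#' Generate ground-truth beat times and respiration schedule
#'
#' Places heartbeats by cumulative summation of the additive R-R interval
#' model: the schedule-driven mean interval `60000/HR(t)` plus a respiratory
#' sinus arrhythmia sinusoid locked to the instantaneous respiration phase,
#' a low-frequency sinusoid, and white beat-to-beat noise.
#'
#' @param config A [cohort_config()].
#' @param participant_index 1-based participant index; part of the seed.
#' @return A list of class `hrv_truth` with `beat_times` (s),
#'   `beat_labels` (all `"normal"` at this stage), `resp` (tibble of
#'   `time_s`, `rate_min`), `resp_phase` (tibble of `time_s`, `phase` in
#'   cycles, for phase-locked rendering), `episodes`, `artifact_windows`
#'   (empty), `duration_s`, `start_clock_s` and `group`.
#' @export
#' @examples
#' cfg <- cohort_config("adult", duration_h = 0.2, seed = 42)
#' truth <- generate_rri_ground_truth(cfg, 1)
#' head(diff(truth$beat_times)) * 1000  # RRI in ms
generate_rri_ground_truth <- function(config, participant_index = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  episodes <- episode_schedule(config, participant_index)
  set.seed(stage_seed(config, participant_index, 1L))
  dur <- config$duration_h * 3600
  dt <- 0.25
  grid <- seq(0, dur + dt, by = dt)
  hr_g <- schedule_on_grid(episodes, config$hr_profile, grid)
  resp_g <- schedule_on_grid(episodes, config$resp_profile, grid)
  if (any(60000 / hr_g <= 250)) {
    stop("hr_profile yields non-physiological (<= 250 ms) R-R intervals",
         call. = FALSE)
  }
  # instantaneous respiration frequency: schedule value with slow
  # fractional wobble (two incommensurate slow sinusoids) -- breathing is
  # a band, not a line
  rv <- config$resp_variability %||% 0
  w1 <- sin(2 * pi * grid / 67 + runif(1, 0, 2 * pi))
  w2 <- sin(2 * pi * grid / 203 + runif(1, 0, 2 * pi))
  resp_g <- resp_g * (1 + rv * (0.7 * w1 + 0.3 * w2))
  # respiration phase in cycles: integral of f_resp(t) dt
  phase_g <- cumsum(resp_g / 60) * dt
  # episode-dependent RSA depth with slow amplitude modulation, and LF
  # frequency wobble
  rsa_g <- schedule_on_grid(episodes, config$rsa_amplitude_ms, grid) *
    (1 + 0.15 * sin(2 * pi * grid / 97 + runif(1, 0, 2 * pi)))
  lf_phase_g <- cumsum(config$lf_freq_hz *
    (1 + 0.05 * sin(2 * pi * grid / 149 + runif(1, 0, 2 * pi)))) * dt

  n_est <- ceiling(dur / (60 / max(hr_g)) * 1.05) + 16L
  eps <- rnorm(n_est, 0, config$rri_noise_ms)
  beat_times <- numeric(n_est)
  t <- 0
  n <- 0L
  two_pi <- 2 * pi
  a_lf <- config$lf_amplitude_ms
  while (t < dur) {
    i0 <- floor(t / dt)
    w <- t / dt - i0
    hr_t <- (1 - w) * hr_g[i0 + 1L] + w * hr_g[i0 + 2L]
    ph_t <- (1 - w) * phase_g[i0 + 1L] + w * phase_g[i0 + 2L]
    rsa_t <- (1 - w) * rsa_g[i0 + 1L] + w * rsa_g[i0 + 2L]
    lfph_t <- (1 - w) * lf_phase_g[i0 + 1L] + w * lf_phase_g[i0 + 2L]
    rri <- 60000 / hr_t +
      rsa_t * sin(two_pi * ph_t) +
      a_lf * sin(two_pi * lfph_t) +
      eps[n + 1L]
    if (rri <= 200) rri <- 201  # hard physiological floor, never reached by defaults
    t <- t + rri / 1000
    if (t >= dur) break
    n <- n + 1L
    beat_times[n] <- t
  }
  beat_times <- beat_times[seq_len(n)]
  structure(list(
    beat_times = beat_times,
    beat_labels = rep("normal", n),
    resp = tibble(time_s = grid, rate_min = resp_g),
    resp_phase = tibble(time_s = grid, phase = phase_g),
    episodes = episodes,
    artifact_windows = tibble(begin_s = numeric(), end_s = numeric(),
                              type = character()),
    duration_s = dur,
    start_clock_s = config$start_clock_s,
    group = config$group
  ), class = "hrv_truth")
}

#' Inject artifacts into a ground-truth recording
#'
#' Draws ectopic beats, signal dropouts, and high-amplitude noise bursts from
#' homogeneous Poisson processes (per-hour rates in
#' `config$artifact_rates`) and records every event in the ground truth.
#' Ectopic beats are made premature (coupling interval 55% of the preceding
#' interval) with a compensatory pause, and are rendered with an aberrant
#' wide-QRS morphology by [synthesize_ecg()]. With all rates zero the truth
#' is returned unchanged.
#'
#' @param truth An `hrv_truth` from [generate_rri_ground_truth()].
#' @param config The [cohort_config()].
#' @param participant_index Participant index (seeding).
#' @return The modified `hrv_truth`; `beat_labels` marks ectopics and
#'   `artifact_windows` lists dropout/noise intervals.
#' @export
inject_artifacts <- function(truth, config, participant_index = 1L) {
  stopifnot(inherits(truth, "hrv_truth"), inherits(config, "cohort_config"))
  rates <- config$artifact_rates
  set.seed(stage_seed(config, participant_index, 2L))
  dur_h <- truth$duration_s / 3600
  bt <- truth$beat_times
  labels <- truth$beat_labels

  n_ect <- rpois(1, (rates$ectopic_per_h %||% 0) * dur_h)
  if (n_ect > 0 && length(bt) > 4) {
    cand <- sort(sample(3:(length(bt) - 2), min(n_ect, length(bt) - 4)))
    # avoid adjacent picks: a premature beat needs intact neighbours
    keep <- c(TRUE, diff(cand) > 2)
    cand <- cand[keep]
    for (i in cand) {
      bt[i] <- bt[i - 1] + 0.55 * (bt[i] - bt[i - 1])
      labels[i] <- "ectopic"
    }
  }

  draw_windows <- function(rate_per_h, min_s, max_s, type) {
    k <- rpois(1, rate_per_h * dur_h)
    if (k == 0) {
      return(tibble(begin_s = numeric(), end_s = numeric(), type = character()))
    }
    begin <- sort(runif(k, 0, truth$duration_s))
    len <- runif(k, min_s, max_s)
    tibble(begin_s = begin, end_s = pmin(begin + len, truth$duration_s),
           type = type)
  }
  wins <- dplyr::bind_rows(
    draw_windows(rates$dropout_per_h %||% 0, 3, 10, "dropout"),
    draw_windows(rates$noise_per_h %||% 0, 1, 5, "noise")
  )
  truth$beat_times <- bt
  truth$beat_labels <- labels
  truth$artifact_windows <- dplyr::arrange(
    dplyr::bind_rows(truth$artifact_windows, wins), .data$begin_s)
  truth
}

# PQRST template as summed Gaussian bumps. Returns the respiration-invariant
# part and the R bump separately so the R amplitude can be modulated.
pqrst_template <- function(fs, type = c("normal", "ectopic")) {
  type <- match.arg(type)
  tt <- seq(-0.25, 0.35, by = 1 / fs)
  g <- function(amp, mu, sigma) amp * exp(-0.5 * ((tt - mu) / sigma)^2)
  if (type == "normal") {
    fixed <- g(0.15, -0.20, 0.025) + g(-0.10, -0.028, 0.010) +
      g(-0.25, 0.028, 0.010) + g(0.30, 0.25, 0.060)
    rwave <- g(1.00, 0, 0.012)
  } else {
    # aberrant wide complex: no P wave, broad tall R, deep slurred S
    fixed <- g(-0.45, 0.060, 0.030) + g(0.25, 0.28, 0.070)
    rwave <- g(1.40, 0, 0.040)
  }
  list(t = tt, fixed = fixed, rwave = rwave,
       r_index = which.min(abs(tt)))
}

#' Render a synthetic single-lead ECG from ground truth
#'
#' Places a fixed PQRST template (summed Gaussian bumps) at every beat. The
#' R-wave amplitude is multiplied by `1 + edr_depth * sin(2 pi phase_resp)`,
#' giving the respiration modulation that ECG-derived respiration recovers.
#' Baseline wander and measurement noise are added; dropout windows are
#' zeroed and noise-burst windows get high-amplitude noise. A 3-axis
#' accelerometer trace with variance switching by activity episode is
#' attached.
#'
#' @param truth An `hrv_truth` (artifact-injected or not).
#' @param config The [cohort_config()].
#' @param participant_index Participant index (seeding).
#' @return An `ecg_record`: list with `samples` (mV), `fs`, `accel` (3-column
#'   matrix, g), `accel_fs`, `start_clock_s`, `group`, `id`.
#' @export
synthesize_ecg <- function(truth, config, participant_index = 1L) {
  stopifnot(inherits(truth, "hrv_truth"), inherits(config, "cohort_config"))
  if (is.unsorted(truth$beat_times)) {
    stop("beat times must be increasing", call. = FALSE)
  }
  set.seed(stage_seed(config, participant_index, 3L))
  fs <- config$fs
  n <- round(truth$duration_s * fs)
  if (any(diff(truth$beat_times) < 0.30)) {
    warning("some R-R intervals are shorter than the PQRST template; ",
            "overlapping complexes are summed")
  }
  # measurement noise plus slow baseline wander (kept below the
  # physiological respiration bands so it cannot masquerade as EDR)
  ecg <- rnorm(n, 0, 0.01) +
    0.05 * sin(2 * pi * 0.12 * (seq_len(n) / fs) + runif(1, 0, 2 * pi)) +
    0.03 * sin(2 * pi * 0.05 * (seq_len(n) / fs) + runif(1, 0, 2 * pi))

  tpl_n <- pqrst_template(fs, "normal")
  tpl_e <- pqrst_template(fs, "ectopic")
  phase_at <- approxfun(truth$resp_phase$time_s, truth$resp_phase$phase,
                        rule = 2)
  edr_factor <- 1 + config$edr_depth * sin(2 * pi * phase_at(truth$beat_times))
  off <- length(tpl_n$t) - tpl_n$r_index  # samples after R in template
  for (i in seq_along(truth$beat_times)) {
    tpl <- if (truth$beat_labels[i] == "ectopic") tpl_e else tpl_n
    ridx <- round(truth$beat_times[i] * fs)
    i0 <- ridx - (tpl$r_index - 1L)
    i1 <- ridx + (length(tpl$t) - tpl$r_index)
    s0 <- max(1L, i0); s1 <- min(n, i1)
    if (s0 > s1) next
    seg <- (s0 - i0 + 1L):(s1 - i0 + 1L)
    ecg[s0:s1] <- ecg[s0:s1] + tpl$fixed[seg] + edr_factor[i] * tpl$rwave[seg]
  }

  for (j in seq_len(nrow(truth$artifact_windows))) {
    w <- truth$artifact_windows[j, ]
    i0 <- max(1L, floor(w$begin_s * fs) + 1L)
    i1 <- min(n, ceiling(w$end_s * fs))
    if (i0 > i1) next
    if (w$type == "dropout") {
      ecg[i0:i1] <- 0
    } else if (w$type == "noise") {
      ecg[i0:i1] <- ecg[i0:i1] + rnorm(i1 - i0 + 1L, 0, 1.2)
    }
  }

  # Accelerometer: variance-switching Gaussian noise per activity episode.
  afs <- config$accel_fs
  na <- round(truth$duration_s * afs)
  at <- seq_len(na) / afs
  sd_by <- c(sleep = 0.01, nap = 0.01, low_activity = 0.08,
             high_activity = 0.30)
  ep <- truth$episodes
  idx <- findInterval(at, ep$begin_s, rightmost.closed = TRUE)
  idx[idx < 1] <- 1
  sds <- sd_by[ep$label[idx]]
  accel <- cbind(
    x = rnorm(na, 0, 1) * sds,
    y = rnorm(na, 0, 1) * sds,
    z = 1 + rnorm(na, 0, 1) * sds
  )

  structure(list(
    samples = ecg,
    fs = fs,
    accel = accel,
    accel_fs = afs,
    start_clock_s = truth$start_clock_s,
    duration_s = truth$duration_s,
    group = config$group,
    id = participant_index
  ), class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %s participant %s: %.2f h at %g Hz (%d samples)\n",
              x$group, x$id, x$duration_s / 3600, x$fs, length(x$samples)))
  invisible(x)
}

#' Activity log for a synthetic recording
#'
#' Produces the simple tabular activity log a caregiver would keep: begin and
#' end wall-clock times (ISO-8601) with a dominant-activity label and a sleep
#' flag. Toddler schedules include the afternoon nap overlapping 12:00-14:00.
#'
#' @param truth An `hrv_truth`.
#' @param date Calendar date of the recording start (used only to format
#'   timestamps).
#' @return A tibble with `begin`, `end` (ISO-8601 strings), `begin_s`,
#'   `end_s` (seconds from recording start), `label` and `is_sleep`.
#' @export
generate_activity_log <- function(truth, date = "2026-01-05") {
  stopifnot(inherits(truth, "hrv_truth"))
  origin <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC") +
    truth$start_clock_s
  iso <- function(s) format(origin + s, "%Y-%m-%dT%H:%M:%S")
  ep <- truth$episodes
  tibble(
    begin = iso(ep$begin_s),
    end = iso(ep$end_s),
    begin_s = ep$begin_s,
    end_s = ep$end_s,
    label = ep$label,
    is_sleep = ep$label %in% c("sleep", "nap")
  )
}

#' Simulate one participant of a synthetic cohort
#'
#' Convenience wrapper chaining [generate_rri_ground_truth()],
#' [inject_artifacts()], [synthesize_ecg()] and [generate_activity_log()].
#'
#' @inheritParams generate_rri_ground_truth
#' @return A list with `ecg` (an `ecg_record`), `truth` (an `hrv_truth`) and
#'   `log` (the activity-log tibble).
#' @export
#' @examples
#' cfg <- cohort_config("adult", duration_h = 0.1, seed = 7,
#'                      artifact_rates = list(ectopic_per_h = 0,
#'                                            dropout_per_h = 0,
#'                                            noise_per_h = 0))
#' p <- simulate_participant(cfg, 1)
#' p$ecg
simulate_participant <- function(config, participant_index = 1L) {
  truth <- generate_rri_ground_truth(config, participant_index)
  truth <- inject_artifacts(truth, config, participant_index)
  ecg <- synthesize_ecg(truth, config, participant_index)
  list(ecg = ecg, truth = truth, log = generate_activity_log(truth))
}
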