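# ECG-derived respiration (EDR): per-beat respiratory feature, band-pass
# filtered and normalized continuous signal, cycle detection with
# age/activity-dependent physiological validity, per-segment summaries.

#' Extract an ECG-derived respiration signal
#'
#' The single-lead EDR concept: respiration modulates the QRS complex, so a
#' per-beat respiratory feature is formed from the R-peak amplitude relative
#' to the local isoelectric baseline (with the QRS area as secondary
#' feature). Features of normal beats are spline-interpolated onto the 4 Hz
#' grid, band-pass filtered to the group's physiological respiration range,
#' and z-normalized in sliding windows, making the result invariant to the
#' overall ECG amplitude scale.
#'
#' @param ecg An `ecg_record` or numeric vector (with `fs`).
#' @param annotation A `beat_annotation` from [classify_beats()].
#' @param group `"toddler"` or `"adult"`; sets the band-pass edges
#'   (toddler 0.15-1.04 Hz, adult 0.10-0.75 Hz).
#' @param fs Sampling rate when `ecg` is a bare vector.
#' @param norm_window_s Sliding z-normalization window, seconds (default 60).
#' @param band Optional numeric length-2 override of the band-pass edges, Hz.
#' @return A tibble (`edr_signal`) with `time_s` (4 Hz grid) and `edr`
#'   (normalized, dimensionless). The per-beat features are attached as
#'   attribute `"features"` (tibble `time_s`, `r_amplitude`, `qrs_area`).
#' @export
compute_edr <- function(ecg, annotation, group = c("toddler", "adult"),
                        fs = NULL, norm_window_s = 60, band = NULL) {
  group <- match.arg(group)
  if (inherits(ecg, "ecg_record")) {
    fs <- ecg$fs
    x <- ecg$samples
  } else {
    if (is.null(fs)) stop("`fs` required for a bare sample vector", call. = FALSE)
    x <- as.numeric(ecg)
  }
  nb <- annotation[annotation$label == "normal", ]
  if (nrow(nb) < 30) stop("need at least 30 normal beats", call. = FALSE)

  idx <- round(nb$time_s * fs) + 1L
  n <- length(x)
  idx <- pmin(pmax(idx, 1L), n)

  # baseline: median of the PR-segment window 0.30-0.12 s before the R peak
  b0 <- round(0.30 * fs); b1 <- round(0.12 * fs)
  baseline <- vapply(idx, function(i) {
    s <- max(1L, i - b0); e <- max(1L, i - b1)
    median(x[s:e])
  }, numeric(1))
  r_amp <- x[idx] - baseline

  # secondary feature: rectified QRS area over +-60 ms
  hw <- round(0.06 * fs)
  qrs_area <- vapply(seq_along(idx), function(j) {
    i <- idx[j]
    s <- max(1L, i - hw); e <- min(n, i + hw)
    sum(abs(x[s:e] - baseline[j])) / fs
  }, numeric(1))

  features <- tibble(time_s = nb$time_s, r_amplitude = r_amp,
                     qrs_area = qrs_area)

  grid <- seq(0, floor(max(nb$time_s) / GRID_DT) * GRID_DT, by = GRID_DT)
  f <- splinefun(nb$time_s, r_amp, method = "natural")(grid)
  f[grid < nb$time_s[1]] <- r_amp[1]
  f[grid > max(nb$time_s)] <- r_amp[length(r_amp)]

  edges <- band %||% (if (group == "toddler") c(0.15, 1.04) else c(0.10, 0.75))
  bp <- signal::butter(2, edges / (GRID_FS / 2), type = "pass")
  f <- signal::filtfilt(bp, f - mean(f))

  k <- round(norm_window_s * GRID_FS)
  mu <- roll_mean(f, k)
  s <- pmax(roll_sd(f, k), 1e-12)
  edr <- (f - mu) / s

  structure(
    tibble(time_s = grid, edr = edr),
    features = features,
    class = c("edr_signal", "tbl_df", "tbl", "data.frame")
  )
}

#' Segment an EDR signal into respiration cycles
#'
#' Cycle boundaries are the upward zero crossings of the normalized EDR
#' signal (located by linear interpolation). A cycle is valid if and only if
#' its implied rate lies within the physiological window for the age group
#' and activity state (awake windows carry the activity widening of the
#' upper bound).
#'
#' @param edr An `edr_signal` from [compute_edr()].
#' @param group `"toddler"` or `"adult"`.
#' @param state `"awake"` or `"rest"` -- selects the validity window.
#' @return A tibble (`resp_cycles`) with `begin_s`, `end_s`, `duration_s`,
#'   `rate_min` and `valid`.
#' @export
detect_cycles <- function(edr, group = c("toddler", "adult"),
                          state = c("awake", "rest")) {
  group <- match.arg(group)
  state <- match.arg(state)
  stopifnot(is.data.frame(edr), all(c("time_s", "edr") %in% names(edr)))
  y <- edr$edr
  t <- edr$time_s
  up <- which(y[-length(y)] < 0 & y[-1] >= 0)
  if (length(up) < 2) {
    return(structure(
      tibble(begin_s = numeric(), end_s = numeric(), duration_s = numeric(),
             rate_min = numeric(), valid = logical()),
      class = c("resp_cycles", "tbl_df", "tbl", "data.frame")
    ))
  }
  frac <- -y[up] / (y[up + 1L] - y[up])
  cross <- t[up] + frac * (t[up + 1L] - t[up])
  dur <- diff(cross)
  rate <- 60 / dur
  win <- resp_validity_window(group, state)
  structure(
    tibble(begin_s = cross[-length(cross)], end_s = cross[-1],
           duration_s = dur, rate_min = rate,
           valid = rate >= win[1] & rate <= win[2]),
    class = c("resp_cycles", "tbl_df", "tbl", "data.frame")
  )
}

#' Median respiration rate and cycle coverage of a segment
#'
#' The segment's respiration estimate is the median rate over valid cycles
#' inside the window -- the median, not the mean, to resist residual
#' detection artifacts. Coverage is the fraction of the segment covered by
#' valid cycles; the estimate is usable only when coverage reaches at least
#' one third.
#'
#' @param cycles A `resp_cycles` tibble.
#' @param segment_start Segment start time, seconds.
#' @param segment_length Segment length, seconds (default 180).
#' @param min_coverage Minimum usable coverage (default 1/3).
#' @return A one-row tibble with `median_rate_min`, `median_freq_hz`
#'   (`= median_rate_min / 60`), `coverage` and `resp_ok`.
#' @export
summarize_segment_respiration <- function(cycles, segment_start,
                                          segment_length = SEGMENT_LENGTH_S,
                                          min_coverage = 1 / 3) {
  stopifnot(is.data.frame(cycles))
  a <- segment_start
  b <- segment_start + segment_length
  if (nrow(cycles) == 0) {
    return(tibble(median_rate_min = NA_real_, median_freq_hz = NA_real_,
                  coverage = 0, resp_ok = FALSE))
  }
  ov_begin <- pmax(cycles$begin_s, a)
  ov_end <- pmin(cycles$end_s, b)
  ov <- pmax(0, ov_end - ov_begin)
  sel <- cycles$valid & ov > 0
  coverage <- sum(ov[sel]) / segment_length
  med <- if (any(sel)) median(cycles$rate_min[sel]) else NA_real_
  tibble(
    median_rate_min = med,
    median_freq_hz = med / 60,
    coverage = coverage,
    resp_ok = is.finite(med) && coverage >= min_coverage
  )
}
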