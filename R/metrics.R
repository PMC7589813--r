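# Time-domain and Poincare metrics, and the per-segment metrics driver.

# adjacent pairs of valid intervals within a segment slice
valid_pairs <- function(rri_ms, valid) {
  n <- length(rri_ms)
  if (n < 2) return(list(x1 = numeric(), x2 = numeric()))
  ok <- valid[-n] & valid[-1]
  list(x1 = rri_ms[-n][ok], x2 = rri_ms[-1][ok])
}

#' Time-domain HRV metrics of a segment
#'
#' SDNN is the standard deviation of the valid R-R intervals in the
#' segment; RMSSD the square root of the mean squared differences of
#' successive valid intervals (pairs interrupted by an invalid interval are
#' skipped); mean heart rate is `60000 / mean(RRI)`.
#'
#' @param rri A tibble with `rri_ms` and `valid` columns (a segment slice of
#'   an `rri_series`), or a numeric vector of intervals (all taken valid).
#' @return A one-row tibble with `sdnn`, `rmssd`, `mean_hr`, `n_intervals`.
#' @export
#' @examples
#' time_domain(c(800, 810, 800, 810))  # rmssd 10
time_domain <- function(rri) {
  if (is.numeric(rri)) rri <- tibble(rri_ms = rri, valid = TRUE)
  x <- rri$rri_ms[rri$valid]
  if (length(x) < 2) stop("need at least 2 valid intervals", call. = FALSE)
  p <- valid_pairs(rri$rri_ms, rri$valid)
  d <- p$x2 - p$x1
  tibble(
    sdnn = sd(x),
    rmssd = if (length(d) > 0) sqrt(mean(d^2)) else NA_real_,
    mean_hr = 60000 / mean(x),
    n_intervals = length(x)
  )
}

#' Poincare plot metrics of a segment
#'
#' SD1 and SD2 are the dispersions of the scatter of successive R-R
#' interval pairs perpendicular to and along the line of identity. SD1 is
#' computed as the root mean square of the successive differences divided by
#' `sqrt(2)`, which makes the identity `SD1 = RMSSD / sqrt(2)` exact; SD2 is
#' the standard deviation of `(RRI_n + RRI_{n+1}) / sqrt(2)` about its mean.
#' Both are natural-log transformed (with a small floor against degenerate
#' segments).
#'
#' @inheritParams time_domain
#' @param ln_floor Floor applied before the log (default 1e-6 ms).
#' @return A one-row tibble with `sd1`, `sd2`, `ln_sd1`, `ln_sd2`,
#'   `n_pairs`.
#' @export
poincare <- function(rri, ln_floor = 1e-6) {
  if (is.numeric(rri)) rri <- tibble(rri_ms = rri, valid = TRUE)
  p <- valid_pairs(rri$rri_ms, rri$valid)
  if (length(p$x1) < 2) stop("need at least 3 valid intervals", call. = FALSE)
  d <- (p$x2 - p$x1) / sqrt(2)
  s <- (p$x2 + p$x1) / sqrt(2)
  sd1 <- sqrt(mean(d^2))
  sd2 <- sd(s)
  tibble(
    sd1 = sd1, sd2 = sd2,
    ln_sd1 = log(max(sd1, ln_floor)),
    ln_sd2 = log(max(sd2, ln_floor)),
    n_pairs = length(d)
  )
}

#' Per-segment HRV metrics and validity for a processed recording
#'
#' The workhorse of the pipeline: for every 180 s segment it evaluates the
#' four validity criteria (interpolation budget, quasi-stationarity,
#' Parseval accuracy, respiration coverage) and computes mean heart rate,
#' SDNN/RMSSD, SD1/SD2, the Burg spectrum of the quadratically detrended
#' 4 Hz series, band power in HF1-HF6 (HF5/HF6 adjusted to the segment's
#' median respiration frequency), prevalent-frequency fractions and --
#' optionally -- the fractions of the differenced-series spectrum.
#'
#' @param grid An `rri_grid` from [resample_to_4hz()].
#' @param rri The validated `rri_series` (for beat-domain metrics).
#' @param segments Tibble with `segment_start` and `condition` (from
#'   [make_segments()] + [apply_schedule_exclusions()]); a bare
#'   [make_segments()] result is accepted (all segments treated as daytime).
#' @param cycles Respiration cycles: either a single `resp_cycles` tibble or
#'   a named list with elements `awake` and `rest` (sleep segments use
#'   `rest`).
#' @param accel Optional accelerometer matrix (columns x/y/z) for
#'   activity dynamics.
#' @param accel_fs Accelerometer sampling rate, Hz.
#' @param include_diff Also compute the differenced-series spectrum
#'   fractions (default TRUE).
#' @param ar_order Burg model order (default 24).
#' @return A tibble with one row per segment: validity columns
#'   (`..._ok`, `overall_valid`), `mean_hr`, `sdnn`, `rmssd`, `sd1`, `sd2`,
#'   `ln_sd1`, `ln_sd2`, `median_resp_rate`, `coverage`, `hf1..hf6`,
#'   `ln_hf1..ln_hf6`, prevalent fractions (`frac_*`, and `diff_frac_*` when
#'   requested) and `accel_sd`.
#' @export
segment_metrics <- function(grid, rri, segments, cycles = NULL,
                            accel = NULL, accel_fs = NULL,
                            include_diff = TRUE, ar_order = 24) {
  stopifnot(is.data.frame(grid), is.data.frame(rri), is.data.frame(segments))
  if (!"condition" %in% names(segments)) segments$condition <- "daytime"
  if (is.data.frame(cycles)) cycles <- list(awake = cycles, rest = cycles)

  nseg_samples <- SEGMENT_LENGTH_S * GRID_FS
  gvals <- grid$rri_ms
  gmask <- grid$interpolated
  ng <- nrow(grid)

  dgrid <- NULL
  if (include_diff) {
    dgrid <- tryCatch(
      diff_series_grid(rri, duration_s = max(grid$time_s)),
      error = function(e) NULL)
  }

  amag_sd <- function(a, b) {
    if (is.null(accel) || is.null(accel_fs)) return(NA_real_)
    i0 <- max(1L, floor(a * accel_fs) + 1L)
    i1 <- min(nrow(accel), ceiling(b * accel_fs))
    if (i1 - i0 < 8) return(NA_real_)
    m <- sqrt(rowSums(accel[i0:i1, , drop = FALSE]^2))
    sd(m)
  }

  rt <- rri$time_s
  one_segment <- function(s, condition) {
    i0 <- round(s * GRID_FS) + 1L
    i1 <- i0 + nseg_samples - 1L
    if (i1 > ng) return(NULL)
    vals <- gvals[i0:i1]
    bv <- check_beat_validity(gmask[i0:i1])
    st <- stationarity_ratio(vals)

    psd <- NULL
    pv <- tibble(parseval_accuracy = NA_real_, parseval_ok = FALSE)
    if (isTRUE(is.finite(st$std2))) {
      resid <- detrend2(vals)
      psd <- tryCatch(burg_psd(resid, order = ar_order), error = function(e) NULL)
      if (!is.null(psd)) pv <- parseval_check(psd, st$std2)
    }

    state <- if (condition == "sleep") "rest" else "awake"
    resp <- if (!is.null(cycles)) {
      summarize_segment_respiration(cycles[[state]], s)
    } else {
      tibble(median_rate_min = NA_real_, median_freq_hz = NA_real_,
             coverage = NA_real_, resp_ok = TRUE)
    }

    sel <- rt > s & rt <= s + SEGMENT_LENGTH_S
    seg_rri <- rri[sel, c("rri_ms", "valid")]
    td <- po <- NULL
    if (sum(seg_rri$valid) >= 3) {
      td <- tryCatch(time_domain(seg_rri), error = function(e) NULL)
      po <- tryCatch(poincare(seg_rri), error = function(e) NULL)
    }

    bands <- hf_bands(resp$median_freq_hz)
    bp <- purrr::map2(bands$lower, bands$upper, function(lo, hi) {
      if (is.null(psd)) return(tibble(absolute = NA_real_, ln_value = NA_real_))
      band_power(psd, lo, hi)
    })
    hf_abs <- purrr::map_dbl(bp, "absolute")
    hf_ln <- purrr::map_dbl(bp, "ln_value")

    fr <- if (!is.null(psd)) {
      tryCatch(prevalent_fractions(psd), error = function(e) NULL)
    }
    if (is.null(fr)) {
      fr <- as_tibble(setNames(as.list(rep(NA_real_, 6)),
                               c(PREVALENT_BANDS$name, "frac_below_004")))
    }

    dfr <- NULL
    if (include_diff) {
      empty <- as_tibble(setNames(as.list(rep(NA_real_, 6)),
                                  c(PREVALENT_BANDS$name, "frac_below_004")))
      dfr <- empty
      if (!is.null(dgrid) && i1 <= nrow(dgrid)) {
        dvals <- dgrid$rri_ms[i0:i1]
        if (sd(dvals) > 0) {
          dpsd <- tryCatch(burg_psd(dvals, order = ar_order),
                           error = function(e) NULL)
          if (!is.null(dpsd)) {
            dfr <- tryCatch(prevalent_fractions(dpsd), error = function(e) empty)
          }
        }
      }
      names(dfr) <- paste0("diff_", names(dfr))
    }

    out <- tibble(
      segment_start = s,
      condition = condition,
      interpolated_total_s = bv$interpolated_total_s,
      max_interpolated_run_s = bv$max_interpolated_run_s,
      beat_validity_ok = bv$beat_validity_ok,
      std0 = st$std0, std2 = st$std2,
      stationarity_ratio = st$stationarity_ratio,
      stationarity_ok = st$stationarity_ok,
      parseval_accuracy = pv$parseval_accuracy,
      parseval_ok = pv$parseval_ok,
      median_resp_rate = resp$median_rate_min,
      median_resp_freq = resp$median_freq_hz,
      resp_coverage = resp$coverage,
      resp_ok = resp$resp_ok,
      mean_hr = if (is.null(td)) NA_real_ else td$mean_hr,
      sdnn = if (is.null(td)) NA_real_ else td$sdnn,
      rmssd = if (is.null(td)) NA_real_ else td$rmssd,
      sd1 = if (is.null(po)) NA_real_ else po$sd1,
      sd2 = if (is.null(po)) NA_real_ else po$sd2,
      ln_sd1 = if (is.null(po)) NA_real_ else po$ln_sd1,
      ln_sd2 = if (is.null(po)) NA_real_ else po$ln_sd2,
      accel_sd = amag_sd(s, s + SEGMENT_LENGTH_S)
    )
    out[paste0("hf", 1:6)] <- as.list(hf_abs)
    out[paste0("ln_hf", 1:6)] <- as.list(hf_ln)
    out <- dplyr::bind_cols(out, fr)
    if (!is.null(dfr)) out <- dplyr::bind_cols(out, dfr)
    out$overall_valid <- isTRUE(bv$beat_validity_ok) &&
      isTRUE(st$stationarity_ok) && isTRUE(pv$parseval_ok) &&
      isTRUE(resp$resp_ok)
    out
  }

  rows <- purrr::map2(segments$segment_start, segments$condition, one_segment)
  dplyr::bind_rows(rows)
}
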