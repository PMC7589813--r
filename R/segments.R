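# 180 s segmentation, the four validity criteria, schedule-based
# exclusions, activity classification and participant inclusion.

#' Slice a 4 Hz series into 180 s segments at 30 s steps
#'
#' @param grid An `rri_grid` (or anything with a `time_s` column on the 4 Hz
#'   grid), or a recording duration in seconds.
#' @return A tibble with `segment_start` (s) for every maximal 180 s window
#'   fully inside the recording, starting at multiples of 30 s from the
#'   recording start. A series shorter than 180 s yields zero rows.
#' @export
#' @examples
#' make_segments(300)  # starts 0, 30, 60, 90, 120
make_segments <- function(grid) {
  dur <- if (is.data.frame(grid)) max(grid$time_s) else as.numeric(grid)
  if (dur < SEGMENT_LENGTH_S) return(tibble(segment_start = numeric()))
  starts <- seq(0, dur - SEGMENT_LENGTH_S, by = SEGMENT_STRIDE_S)
  tibble(segment_start = starts)
}

#' Interpolation budget of a segment (beat-validity criterion)
#'
#' On the 4 Hz grid, 95% valid data in a 180 s segment means at most 9 s of
#' interpolated (replaced) samples in total, and at most 3.6 s (2%) in a
#' row.
#'
#' @param mask Logical interpolation mask of the segment's 720 grid samples
#'   (`TRUE` = replaced data).
#' @return A one-row tibble with `interpolated_total_s`,
#'   `max_interpolated_run_s` and `beat_validity_ok`.
#' @export
check_beat_validity <- function(mask) {
  mask <- as.logical(mask)
  total <- sum(mask) * GRID_DT
  max_run <- if (any(mask)) {
    r <- rle(mask)
    max(r$lengths[r$values]) * GRID_DT
  } else 0
  tibble(
    interpolated_total_s = total,
    max_interpolated_run_s = max_run,
    beat_validity_ok = total <= interpolation_budget_s() &&
      max_run <= max_run_budget_s()
  )
}

#' Quasi-stationarity ratio STD2/STD0 of a segment
#'
#' STD0 is the standard deviation of the segment after mean removal; STD2
#' the standard deviation of the residuals after removing a least-squares
#' second-order (quadratic) trend. Their ratio is close to 1 for trend-free
#' data and can never exceed 1 (the quadratic fit nests the mean); only
#' ratios between 0.8 and 1.1 count as quasi-stationary, the upper limit
#' being a numerical guard.
#'
#' @param values Numeric segment values (720 samples on the 4 Hz grid).
#' @return A one-row tibble with `std0`, `std2`, `stationarity_ratio` and
#'   `stationarity_ok`. A constant segment has an undefined ratio and is
#'   invalid.
#' @export
stationarity_ratio <- function(values) {
  x <- as.numeric(values)
  std0 <- sd(x)
  if (!is.finite(std0) || std0 == 0) {
    return(tibble(std0 = std0, std2 = NA_real_,
                  stationarity_ratio = NA_real_, stationarity_ok = FALSE))
  }
  std2 <- sd(detrend2(x))
  ratio <- std2 / std0
  tibble(std0 = std0, std2 = std2, stationarity_ratio = ratio,
         stationarity_ok = is.finite(ratio) && ratio >= 0.8 && ratio <= 1.1)
}

#' Parseval accuracy of a segment's spectral estimate
#'
#' Compares the integral of the power spectral density over 0-1.04 Hz with
#' the time-domain variance of the detrended segment (STD2 squared). The
#' accuracy is `min(P, V) / max(P, V)`; the segment passes when the two
#' agree to at least 95%, i.e. the spectral estimate carries (almost) the
#' same information content as the time series.
#'
#' @param psd A `psd_estimate` from [burg_psd()].
#' @param std2 STD2 of the same segment, ms.
#' @return A one-row tibble with `parseval_accuracy` and `parseval_ok`.
#' @export
parseval_check <- function(psd, std2) {
  v <- std2^2
  if (!is.finite(v) || v <= 0) {
    return(tibble(parseval_accuracy = NA_real_, parseval_ok = FALSE))
  }
  p <- integrate_psd(psd, 0, 1.04)
  acc <- min(p, v) / max(p, v)
  tibble(parseval_accuracy = acc, parseval_ok = is.finite(acc) && acc >= 0.95)
}

# overlap of segment [start, start+180) with a set of [begin, end) windows
overlap_s <- function(start, begin, end, seg_len = SEGMENT_LENGTH_S) {
  if (length(begin) == 0) return(rep(0, length(start)))
  vapply(start, function(s) {
    sum(pmax(0, pmin(end, s + seg_len) - pmax(begin, s)))
  }, numeric(1))
}

#' Assign segments to sleep/daytime and apply schedule-based exclusions
#'
#' Segments are assigned by majority overlap: logged night sleep makes a
#' segment `sleep`; the 12:00-14:00 nap window and any other logged daytime
#' sleep make it `excluded`; everything else is `daytime`. Time not covered
#' by the log defaults to daytime with a warning.
#'
#' @param segments Tibble with `segment_start` from [make_segments()].
#' @param log Activity log tibble with `begin_s`, `end_s`, `label`,
#'   `is_sleep` (see [generate_activity_log()]).
#' @param start_clock_s Wall-clock time of recording start, seconds after
#'   midnight (default 08:00); needed to place the 12:00-14:00 window.
#' @param exclude_nap_window Apply the 12:00-14:00 exclusion (default TRUE
#'   for both groups; can be disabled, e.g. for adult-only protocols).
#' @return `segments` with a `condition` column
#'   (`sleep`/`daytime`/`excluded`).
#' @export
apply_schedule_exclusions <- function(segments, log,
                                      start_clock_s = 8 * 3600,
                                      exclude_nap_window = TRUE) {
  stopifnot(is.data.frame(segments), "segment_start" %in% names(segments))
  s <- segments$segment_start
  seg_len <- SEGMENT_LENGTH_S

  night <- log[log$is_sleep & log$label == "sleep", , drop = FALSE]
  day_sleep <- log[log$is_sleep & log$label != "sleep", , drop = FALSE]

  covered <- overlap_s(s, log$begin_s, log$end_s)
  if (any(covered < seg_len - 1e-9)) {
    warning("activity log does not cover the full recording; ",
            "uncovered time treated as daytime")
  }

  ov_night <- overlap_s(s, night$begin_s, night$end_s)
  ov_nap_log <- overlap_s(s, day_sleep$begin_s, day_sleep$end_s)

  # 12:00-14:00 wall-clock windows expressed in recording time, every day
  ov_nap_clock <- rep(0, length(s))
  if (exclude_nap_window) {
    dur <- max(s) + seg_len
    day0 <- -start_clock_s  # recording time of the first midnight before start
    k <- 0
    repeat {
      a <- day0 + k * 86400 + 12 * 3600
      b <- day0 + k * 86400 + 14 * 3600
      if (a > dur) break
      ov_nap_clock <- ov_nap_clock + overlap_s(s, a, b)
      k <- k + 1
    }
  }

  half <- seg_len / 2
  condition <- rep("daytime", length(s))
  condition[ov_night >= half] <- "sleep"
  condition[pmin(ov_nap_log + ov_nap_clock, seg_len) >= half] <- "excluded"
  # any sleep overlap at all outside the majority rule: resolve by majority
  dplyr::mutate(segments, condition = condition)
}

#' Classify daytime segments into low and high activity
#'
#' Per participant, a daytime segment is `high` activity when both its mean
#' heart rate and its accelerometer dynamics (standard deviation of the
#' acceleration magnitude) lie above the participant's daytime medians, and
#' `low` when both lie below; mixed segments stay unlabelled. The relative,
#' within-participant split mirrors how activity periods are selected from
#' heart rate, acceleration dynamics and the reported activities. Each class
#' must reach at least `min_minutes` of distinct coverage for the
#' participant to enter the activity analysis.
#'
#' @param segments Tibble with `segment_start`, `condition`, `mean_hr` and
#'   `accel_sd` columns.
#' @param min_minutes Minimum distinct coverage per class, minutes
#'   (default 90).
#' @return `segments` with an `activity` column (`low`/`high`/`NA`), plus
#'   attribute `"activity_ok"` saying whether both classes reached the
#'   floor.
#' @export
classify_activity <- function(segments, min_minutes = 90) {
  stopifnot(all(c("segment_start", "condition", "mean_hr", "accel_sd")
                %in% names(segments)))
  day <- segments$condition == "daytime" & is.finite(segments$mean_hr) &
    is.finite(segments$accel_sd)
  med_hr <- median(segments$mean_hr[day])
  med_ac <- median(segments$accel_sd[day])
  activity <- rep(NA_character_, nrow(segments))
  hi <- day & segments$mean_hr > med_hr & segments$accel_sd > med_ac
  lo <- day & segments$mean_hr < med_hr & segments$accel_sd < med_ac
  activity[hi] <- "high"
  activity[lo] <- "low"
  out <- dplyr::mutate(segments, activity = activity)
  cov <- function(sel) distinct_coverage_s(segments$segment_start[sel]) / 60
  attr(out, "activity_ok") <-
    isTRUE(cov(hi) >= min_minutes && cov(lo) >= min_minutes)
  out
}

# union length of 180 s windows at the given starts (no double counting of
# the 30 s stride overlap)
distinct_coverage_s <- function(starts, seg_len = SEGMENT_LENGTH_S) {
  if (length(starts) == 0) return(0)
  starts <- sort(starts)
  ends <- starts + seg_len
  total <- 0
  cur_a <- starts[1]; cur_b <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= cur_b) {
      cur_b <- max(cur_b, ends[i])
    } else {
      total <- total + (cur_b - cur_a)
      cur_a <- starts[i]; cur_b <- ends[i]
    }
  }
  total + (cur_b - cur_a)
}

#' Decide participant inclusion from per-segment validity
#'
#' A participant enters the analysis only if, separately for daytime and
#' sleep, at least 30% of the evaluable time is valid and at least 4 h of
#' valid data are available. Time is counted as distinct coverage of the
#' overlapping 180 s windows.
#'
#' @param segments Tibble with `segment_start`, `condition` and
#'   `overall_valid` columns.
#' @param min_fraction Minimum valid fraction (default 0.30).
#' @param min_hours Minimum valid hours per condition (default 4).
#' @return A one-row tibble with the fractions, hours, and `included`.
#' @export
decide_inclusion <- function(segments, min_fraction = 0.30, min_hours = 4) {
  stopifnot(all(c("segment_start", "condition", "overall_valid")
                %in% names(segments)))
  one <- function(cond) {
    sel <- segments$condition == cond
    tot <- distinct_coverage_s(segments$segment_start[sel])
    val <- distinct_coverage_s(
      segments$segment_start[sel & segments$overall_valid])
    tibble(fraction = if (tot > 0) val / tot else 0, hours = val / 3600)
  }
  d <- one("daytime")
  s <- one("sleep")
  tibble(
    valid_fraction_day = d$fraction,
    valid_fraction_sleep = s$fraction,
    valid_hours_day = d$hours,
    valid_hours_sleep = s$hours,
    included = d$fraction >= min_fraction && s$fraction >= min_fraction &&
      d$hours >= min_hours && s$hours >= min_hours
  )
}
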