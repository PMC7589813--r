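# Individual physiological limits (Hilbert envelope), artifact rules,
# and 4 Hz resampling of the R-R interval series.

# Envelope (magnitude of the analytic signal) of a real series, via the
# one-sided FFT construction.
analytic_envelope <- function(x) {
  n <- length(x)
  if (n < 4) return(abs(x))
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

# Beat-count window approximating a time window of `window_s` seconds.
beats_per_window <- function(rri_ms, window_s) {
  max(5L, round(window_s / (median(rri_ms, na.rm = TRUE) / 1000)))
}

#' Individual physiological R-R interval limits from the Hilbert envelope
#'
#' Implements the second artifact criterion: physiological limits on an
#' individual, age-dependent basis. The beat series is winsorized to the
#' group's absolute bounds, a slowly varying local level is removed, and the
#' magnitude of the analytic signal (Hilbert transform) of the residual
#' yields a smooth local variability envelope. The limits are
#' `local level +- k * envelope`, clipped to the absolute age-dependent
#' bounds. A degenerate (near-constant) series falls back to the absolute
#' bounds.
#'
#' @param rri An `rri_series` tibble from [beats_to_rri()].
#' @param group `"toddler"` or `"adult"` (sets the absolute bounds).
#' @param k Envelope multiplier (default 3).
#' @param window_s Smoothing window for the local level and envelope,
#'   seconds (default 300).
#' @param min_halfwidth_ms Lower bound on the half-width of the acceptance
#'   corridor, ms (default 50).
#' @return The input tibble with `envelope_low` and `envelope_high` columns
#'   (ms).
#' @export
compute_individual_limits <- function(rri, group = c("toddler", "adult"),
                                      k = 3, window_s = 300,
                                      min_halfwidth_ms = 50) {
  group <- match.arg(group)
  stopifnot(is.data.frame(rri), "rri_ms" %in% names(rri))
  x <- rri$rri_ms
  if (sum(x, na.rm = TRUE) < 5 * 60 * 1000 / 3) {
    # require roughly >= 5 min of intervals (generous at fast heart rates)
    if (length(x) < 200) stop("need at least ~5 min of intervals", call. = FALSE)
  }
  bounds <- rri_absolute_bounds(group)
  xw <- pmin(pmax(x, bounds[1]), bounds[2])
  nwin <- beats_per_window(x, window_s)
  level <- roll_median(xw, nwin)
  env <- analytic_envelope(xw - level)
  env_s <- roll_mean(env, nwin)
  if (max(env_s) < 1) {
    # degenerate, essentially constant series: absolute bounds only
    rri$envelope_low <- bounds[1]
    rri$envelope_high <- bounds[2]
    return(rri)
  }
  hw <- pmax(k * env_s, min_halfwidth_ms)
  rri$envelope_low <- pmax(level - hw, bounds[1])
  rri$envelope_high <- pmin(level + hw, bounds[2])
  rri
}

#' Apply the three artifact criteria to an R-R interval series
#'
#' An interval is invalid if (a) either bounding beat is non-normal
#' (QRS morphology/timing, criterion 1), (b) it leaves the individual
#' physiological envelope (criterion 2), or (c) its change from the
#' preceding interval exceeds `c_change` local standard deviations of the
#' series (criterion 3). Flags are recomputed from scratch, so the operation
#' is idempotent.
#'
#' @param rri An `rri_series` with envelope columns from
#'   [compute_individual_limits()].
#' @param c_change Successive-change multiplier (default 3).
#' @param window_s Window for the local standard deviation, seconds.
#' @return The tibble with `valid` updated and per-criterion logical columns
#'   `ok_beats`, `ok_envelope`, `ok_change`.
#' @export
apply_artifact_rules <- function(rri, c_change = 3, window_s = 300) {
  stopifnot(is.data.frame(rri),
            all(c("rri_ms", "beats_normal", "envelope_low", "envelope_high")
                %in% names(rri)))
  x <- rri$rri_ms
  ok_beats <- rri$beats_normal
  ok_envelope <- x >= rri$envelope_low & x <= rri$envelope_high

  nwin <- beats_per_window(x, window_s)
  # local SD on the envelope-clipped series so single huge intervals do not
  # inflate their own acceptance threshold
  xc <- pmin(pmax(x, rri$envelope_low), rri$envelope_high)
  sd_local <- pmax(roll_sd(xc, nwin), 1)
  ok_change <- c(TRUE, abs(diff(x)) <= c_change * sd_local[-1])

  rri$ok_beats <- ok_beats
  rri$ok_envelope <- ok_envelope
  rri$ok_change <- ok_change
  rri$valid <- ok_beats & ok_envelope & ok_change
  rri
}

#' Resample a validated R-R interval series to a uniform 4 Hz grid
#'
#' Piecewise cubic-spline interpolation through the valid (time, RRI) points
#' onto a 0.25 s grid anchored at the recording start. Grid samples whose
#' value replaces invalid source data are marked in the interpolation mask;
#' gaps between valid points longer than `max_gap_s` are not bridged by the
#' spline (the last valid value is held) and are masked as well.
#'
#' @param rri An `rri_series` with `valid` flags.
#' @param max_gap_s Longest gap the spline may bridge, seconds (default 3.6,
#'   the in-a-row interpolation budget).
#' @param duration_s Optional recording length; the grid runs from 0 to this
#'   time (default: last beat time).
#' @return A tibble (`rri_grid`) with `time_s`, `rri_ms`, `interpolated`.
#' @export
resample_to_4hz <- function(rri, max_gap_s = max_run_budget_s(),
                            duration_s = NULL) {
  stopifnot(is.data.frame(rri),
            all(c("time_s", "rri_ms", "valid") %in% names(rri)))
  tv <- rri$time_s[rri$valid]
  vv <- rri$rri_ms[rri$valid]
  if (length(tv) < 2) stop("need at least 2 valid intervals", call. = FALSE)
  dup <- duplicated(tv)
  tv <- tv[!dup]; vv <- vv[!dup]

  t_end <- duration_s %||% max(rri$time_s)
  grid <- seq(0, floor(t_end / GRID_DT) * GRID_DT, by = GRID_DT)

  sf <- splinefun(tv, vv, method = "natural")
  vals <- sf(grid)

  mask <- logical(length(grid))
  # outside the span of valid data: hold edge value, mask
  lo <- grid < tv[1]
  hi <- grid > tv[length(tv)]
  vals[lo] <- vv[1]
  vals[hi] <- vv[length(vv)]
  mask[lo | hi] <- TRUE

  # spans of invalid source intervals: (opening beat, closing beat]
  inv <- !rri$valid
  if (any(inv)) {
    open_t <- rri$time_s - rri$rri_ms / 1000
    r <- rle(inv)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      a <- open_t[starts[j]]
      b <- rri$time_s[ends[j]]
      mask[grid > a & grid <= b] <- TRUE
    }
  }

  # long gaps between consecutive valid points: hold, mask
  gap <- diff(tv)
  long <- which(gap > max_gap_s)
  for (j in long) {
    inside <- grid > tv[j] & grid < tv[j + 1]
    vals[inside] <- vv[j]
    mask[inside] <- TRUE
  }

  structure(
    tibble(time_s = grid, rri_ms = vals, interpolated = mask),
    class = c("rri_grid", "tbl_df", "tbl", "data.frame")
  )
}
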