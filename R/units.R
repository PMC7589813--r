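#' Convert heart rate to R-R interval length
#'
#' The cycle-length identity `RRI (ms) = 60000 / HR (bpm)`. Because the
#' relation is hyperbolic, a 2 bpm acceleration shortens the R-R interval far
#' more at a slow heart rate (60 -> 62 bpm: 32.26 ms) than at a fast one
#' (100 -> 102 bpm: 11.76 ms) -- the reason faster-beating hearts have "less
#' time for variability".
#'
#' @param hr Heart rate in beats per minute. Must be positive.
#' @return R-R interval in milliseconds.
#' @seealso [rri_to_hr()]
#' @export
#' @examples
#' hr_to_rri(60)                     # 1000 ms
#' hr_to_rri(60) - hr_to_rri(62)     # 32.26 ms
hr_to_rri <- function(hr) {
  if (any(!is.finite(hr)) || any(hr <= 0)) {
    stop("`hr` must be positive and finite", call. = FALSE)
  }
  60000 / hr
}

#' Convert R-R interval length to heart rate
#'
#' @param rri R-R interval in milliseconds. Must be positive.
#' @return Heart rate in beats per minute.
#' @export
rri_to_hr <- function(rri) {
  if (any(!is.finite(rri)) || any(rri <= 0)) {
    stop("`rri` must be positive and finite", call. = FALSE)
  }
  60000 / rri
}

#' Convert between respiration rate (breaths per minute) and frequency (Hz)
#'
#' @param rate Respiration rate in breaths per minute.
#' @return `resp_rate_to_freq()`: frequency in Hz (`rate / 60`).
#' @export
#' @examples
#' resp_rate_to_freq(21.7)  # 0.36 Hz (the toddler sleep median)
resp_rate_to_freq <- function(rate) rate / 60

#' @rdname resp_rate_to_freq
#' @param freq Respiration frequency in Hz.
#' @return `resp_freq_to_rate()`: rate in breaths per minute (`freq * 60`).
#' @export
resp_freq_to_rate <- function(freq) freq * 60

# Fixed analysis geometry: 180 s windows every 30 s on a 4 Hz grid.
SEGMENT_LENGTH_S <- 180
SEGMENT_STRIDE_S <- 30
GRID_FS <- 4
GRID_DT <- 1 / GRID_FS

#' Segment validity budgets implied by the beat-validity criterion
#'
#' A 180 s segment must consist of at least 95% valid (non-interpolated)
#' data, which on a time basis is a budget of 9 s of replaced samples in
#' total; at most 2% (3.6 s) of interpolated data may occur in a row.
#' These helpers derive the budgets from the fractions so the arithmetic is
#' computed, not hard-coded, wherever it is used.
#'
#' @param segment_s Segment length in seconds (default 180).
#' @param valid_fraction Minimum fraction of valid data (default 0.95).
#' @return Budget in seconds.
#' @export
#' @examples
#' interpolation_budget_s()  # 9
#' max_run_budget_s()        # 3.6
interpolation_budget_s <- function(segment_s = SEGMENT_LENGTH_S,
                                   valid_fraction = 0.95) {
  segment_s * (1 - valid_fraction)
}

#' @rdname interpolation_budget_s
#' @param run_fraction Maximum fraction of interpolated data in a row
#'   (default 0.02).
#' @export
max_run_budget_s <- function(segment_s = SEGMENT_LENGTH_S,
                             run_fraction = 0.02) {
  segment_s * run_fraction
}

#' Physiological reference ranges per age group
#'
#' Awake resting ranges: toddlers (16-37 months) have heart rates of roughly
#' 80-140 bpm and respiration rates of 18-35 breaths per minute; healthy
#' young adults 40-100 bpm and 12-18 breaths per minute.
#'
#' @param group `"toddler"` or `"adult"`.
#' @return A list with `hr_bpm` and `resp_min` two-element ranges.
#' @export
physiological_ranges <- function(group = c("toddler", "adult")) {
  group <- match.arg(group)
  switch(group,
    toddler = list(hr_bpm = c(80, 140), resp_min = c(18, 35)),
    adult   = list(hr_bpm = c(40, 100), resp_min = c(12, 18))
  )
}

# Outer absolute clamps for the individual RRI envelope (ms). Wider than the
# awake resting ranges to allow sleep bradycardia and exercise tachycardia.
rri_absolute_bounds <- function(group = c("toddler", "adult")) {
  group <- match.arg(group)
  switch(group,
    toddler = c(250, 1000),
    adult   = c(333, 1500)
  )
}

# Respiration cycle validity windows (breaths/min) by group and activity
# state. The awake window carries the ~+50% upper-bound widening for active
# periods; rest windows bracket the sleep medians.
resp_validity_window <- function(group = c("toddler", "adult"),
                                 state = c("awake", "rest")) {
  group <- match.arg(group)
  state <- match.arg(state)
  if (group == "toddler") {
    if (state == "rest") c(14, 40) else c(14, 55)
  } else {
    if (state == "rest") c(8, 22) else c(8, 33)
  }
}
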