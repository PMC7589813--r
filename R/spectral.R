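# Frequency-domain machinery: quadratic detrending, Burg autoregressive
# spectra, HF band definitions (fixed and respiration-adjusted), band
# integration, prevalent-frequency fractions, differenced-series spectra.

# memoized orthonormal quadratic basis per series length
.detrend_cache <- new.env(parent = emptyenv())

quad_basis <- function(n) {
  key <- as.character(n)
  q <- .detrend_cache[[key]]
  if (is.null(q)) {
    t <- seq(-1, 1, length.out = n)
    q <- qr.Q(qr(cbind(1, t, t^2)))
    .detrend_cache[[key]] <- q
  }
  q
}

#' Remove a second-order trend from a uniformly sampled series
#'
#' Least-squares quadratic fit over the sample grid; the residuals are
#' orthogonal to the constant, linear and quadratic basis and have zero
#' mean.
#'
#' @param x Numeric series (a 180 s segment is 720 samples at 4 Hz).
#' @return The residual series.
#' @export
detrend2 <- function(x) {
  x <- as.numeric(x)
  q <- quad_basis(length(x))
  as.numeric(x - q %*% crossprod(q, x))
}

#' Burg autoregressive power spectral density
#'
#' Fits an AR model by Burg's recursion (forward-backward prediction error
#' minimization, via [stats::ar.burg()]) at model order 24 and evaluates the
#' one-sided spectral density on a uniform grid over 0 to 2 Hz (the Nyquist
#' frequency of the 4 Hz series). The grid step of 1/600 Hz puts all fixed
#' band edges on grid nodes so trapezoidal band integrals are stable. The
#' integral of the density over 0-2 Hz matches the series variance (that is
#' Parseval's theorem for the AR model; the per-segment gate checks it on
#' 0-1.04 Hz).
#'
#' @param x Numeric series on the 4 Hz grid (detrended for the standard
#'   R-R analysis; differenced series are analysed without trend removal).
#' @param order AR model order (default 24).
#' @param fs Sampling rate, Hz (default 4).
#' @param n_freq Number of frequency grid points over 0-`fs/2` (default
#'   12001, i.e. a 1/6000 Hz step that keeps every band edge on a grid node
#'   and resolves the narrow peaks an AR(24) model puts on strongly
#'   periodic segments).
#' @return A tibble (`psd_estimate`) with `freq_hz` and `density`
#'   (ms^2/Hz), attributes `ar_order`, `fs`.
#' @export
burg_psd <- function(x, order = 24, fs = GRID_FS, n_freq = 12001) {
  x <- as.numeric(x)
  if (length(x) <= order) stop("series shorter than AR order", call. = FALSE)
  freq <- seq(0, fs / 2, length.out = n_freq)
  if (sd(x) == 0) {
    out <- tibble(freq_hz = freq, density = rep(0, n_freq))
  } else {
    fit <- ar.burg(x, aic = FALSE, order.max = order, demean = TRUE)
    a <- fit$ar
    if (any(!is.finite(a))) {
      stop("Burg recursion produced non-finite reflection coefficients",
           call. = FALSE)
    }
    # one-sided density: 2 * sigma^2 * dt / |1 - sum a_k e^{-i 2 pi f k dt}|^2,
    # |A| evaluated by FFT of the AR polynomial on the full circle
    dt <- 1 / fs
    nfft <- 2L * (n_freq - 1L)
    A <- fft(c(1, -a, rep(0, nfft - order - 1L)))[seq_len(n_freq)]
    dens <- 2 * fit$var.pred * dt / Mod(A)^2
    out <- tibble(freq_hz = freq, density = dens)
  }
  structure(out, ar_order = order, fs = fs,
            class = c("psd_estimate", "tbl_df", "tbl", "data.frame"))
}

#' Integrate a spectral density over a frequency band
#'
#' Trapezoidal integration on the PSD grid with linear interpolation at band
#' edges that fall between grid nodes.
#'
#' @param psd A `psd_estimate`.
#' @param lower,upper Band edges, Hz.
#' @return Band power (ms^2).
#' @export
integrate_psd <- function(psd, lower, upper) {
  f <- psd$freq_hz
  d <- psd$density
  lower <- max(lower, f[1])
  upper <- min(upper, f[length(f)])
  if (upper <= lower) return(0)
  dlo <- approx(f, d, xout = lower)$y
  dhi <- approx(f, d, xout = upper)$y
  inside <- which(f > lower & f < upper)
  ff <- c(lower, f[inside], upper)
  dd <- c(dlo, d[inside], dhi)
  sum(diff(ff) * (dd[-1] + dd[-length(dd)]) / 2)
}

#' Respiration-adjusted high-frequency band edges
#'
#' The dynamic band keeps the width of its fixed counterpart but slides with
#' the segment's median respiration frequency: the overlap of the adult band
#' (0.15-0.40 Hz) and the child band starting at 0.24 Hz centres at 0.32 Hz,
#' and the band is shifted up by the positive excess of the respiration
#' frequency over that centre. A respiration frequency of 0.32 Hz or lower
#' gives 0.15-0.40 Hz; 0.40 Hz gives 0.23-0.48 Hz; 0.50 Hz gives
#' 0.33-0.58 Hz. For the 0.65 Hz-wide band the upper edge is clamped at
#' 0.93 Hz (the band narrows).
#'
#' @param median_resp_freq Median respiration frequency of the segment, Hz.
#' @param width Band width, Hz: 0.25 (HF5) or 0.65 (HF6).
#' @param center_ref Centre reference frequency (default 0.32 Hz).
#' @param clamp_upper Upper clamp for the wide band (default 0.93 Hz,
#'   applied when `width >= 0.65`); `Inf` disables it.
#' @return A one-row tibble with `lower` and `upper` (Hz).
#' @export
#' @examples
#' hf_dynamic_band(0.40, 0.25)  # 0.23-0.48 Hz
#' hf_dynamic_band(0.50, 0.25)  # 0.33-0.58 Hz
#' hf_dynamic_band(0.30, 0.25)  # 0.15-0.40 Hz
hf_dynamic_band <- function(median_resp_freq, width = 0.25,
                            center_ref = 0.32, clamp_upper = 0.93) {
  stopifnot(median_resp_freq > 0, width > 0)
  shift <- pmax(0, median_resp_freq - center_ref)
  lower <- 0.15 + shift
  upper <- lower + width
  if (width >= 0.65) upper <- pmin(upper, clamp_upper)
  tibble(lower = lower, upper = upper)
}

#' The six high-frequency band definitions
#'
#' HF1 (0.15-0.40 Hz) is the recommended adult band; HF2 (0.15-0.80 Hz) and
#' HF3 (0.24-1.04 Hz) were proposed for children; HF4 (0.15-1.04 Hz) is
#' their maximal-range combination; HF5 and HF6 are dynamically adjusted to
#' the segment's median respiration frequency with widths 0.25 and 0.65 Hz
#' (see [hf_dynamic_band()]).
#'
#' @param median_resp_freq Median respiration frequency, Hz; `NA` leaves the
#'   dynamic bands undefined.
#' @return A tibble with `band` (`hf1`..`hf6`), `lower`, `upper`, `dynamic`.
#' @export
hf_bands <- function(median_resp_freq = NA_real_) {
  fixed <- tibble(
    band = c("hf1", "hf2", "hf3", "hf4"),
    lower = c(0.15, 0.15, 0.24, 0.15),
    upper = c(0.40, 0.80, 1.04, 1.04),
    dynamic = FALSE
  )
  if (is.finite(median_resp_freq)) {
    b5 <- hf_dynamic_band(median_resp_freq, 0.25)
    b6 <- hf_dynamic_band(median_resp_freq, 0.65)
    dyn <- tibble(band = c("hf5", "hf6"),
                  lower = c(b5$lower, b6$lower),
                  upper = c(b5$upper, b6$upper),
                  dynamic = TRUE)
  } else {
    dyn <- tibble(band = c("hf5", "hf6"), lower = NA_real_, upper = NA_real_,
                  dynamic = TRUE)
  }
  dplyr::bind_rows(fixed, dyn)
}

#' Band power with natural-log transform
#'
#' @param psd A `psd_estimate`.
#' @param lower,upper Band edges, Hz.
#' @param ln_floor Power floor before taking the log (default 1e-6 ms^2),
#'   avoiding `-Inf` on degenerate segments.
#' @return A one-row tibble with `absolute` (ms^2), `ln_value` and
#'   `floored`.
#' @export
band_power <- function(psd, lower, upper, ln_floor = 1e-6) {
  if (!is.finite(lower) || !is.finite(upper) || upper <= lower) {
    return(tibble(absolute = NA_real_, ln_value = NA_real_, floored = NA))
  }
  p <- integrate_psd(psd, lower, upper)
  tibble(absolute = p, ln_value = log(max(p, ln_floor)),
         floored = p < ln_floor)
}

# the prevalent-frequency partition of 1/180-1.04 Hz
PREVALENT_BANDS <- tibble(
  name = c("frac_004_015", "frac_015_024", "frac_024_040",
           "frac_040_080", "frac_080_104"),
  lower = c(0.04, 0.15, 0.24, 0.40, 0.80),
  upper = c(0.15, 0.24, 0.40, 0.80, 1.04)
)

#' Prevalent frequency fractions of a spectrum
#'
#' Shares of total spectral power (over 1/180 to 1.04 Hz) falling into the
#' low-frequency band 0.04-0.15 Hz and the high-frequency sub-bands
#' 0.15-0.24, 0.24-0.40, 0.40-0.80 and 0.80-1.04 Hz. Together with the
#' remainder below 0.04 Hz the fractions sum to 1.
#'
#' @param psd A `psd_estimate`.
#' @return A one-row tibble with one column per band plus `frac_below_004`.
#' @export
prevalent_fractions <- function(psd) {
  total <- integrate_psd(psd, 1 / SEGMENT_LENGTH_S, 1.04)
  if (!is.finite(total) || total <= 0) {
    stop("total spectral power over 1/180-1.04 Hz is zero", call. = FALSE)
  }
  vals <- purrr::map_dbl(seq_len(nrow(PREVALENT_BANDS)), function(i) {
    integrate_psd(psd, PREVALENT_BANDS$lower[i], PREVALENT_BANDS$upper[i]) /
      total
  })
  out <- as_tibble(setNames(as.list(vals), PREVALENT_BANDS$name))
  out$frac_below_004 <- integrate_psd(psd, 1 / SEGMENT_LENGTH_S, 0.04) / total
  out
}

#' Resample the successive-difference series to the 4 Hz grid
#'
#' Builds the series of differences of successive valid R-R intervals
#' (indexed by the closing beat of the later interval) and resamples it with
#' the same piecewise cubic-spline machinery as the interval series itself.
#' Its Burg spectrum -- computed without trend correction -- shows where the
#' variability captured by RMSSD/SD1 lives: differencing acts as a high-pass
#' filter with gain `2 - 2 cos(2 pi f dt)`.
#'
#' @param rri An `rri_series` with `valid` flags.
#' @param max_gap_s,duration_s Passed to [resample_to_4hz()].
#' @return An `rri_grid` tibble of the differenced series (`rri_ms` column
#'   holds the differences).
#' @export
diff_series_grid <- function(rri, max_gap_s = max_run_budget_s(),
                             duration_s = NULL) {
  stopifnot(is.data.frame(rri),
            all(c("time_s", "rri_ms", "valid") %in% names(rri)))
  n <- nrow(rri)
  if (n < 3) stop("need at least 3 intervals", call. = FALSE)
  d <- tibble(
    time_s = rri$time_s[-1],
    rri_ms = diff(rri$rri_ms),
    valid = rri$valid[-1] & rri$valid[-n]
  )
  resample_to_4hz(d, max_gap_s = max_gap_s,
                  duration_s = duration_s %||% max(rri$time_s))
}
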