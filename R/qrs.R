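# QRS detection and beat classification.

# rolling mean, same length, edges extended
roll_mean <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  if (k >= length(x)) return(rep(mean(x), length(x)))
  zoo::rollmean(x, k, fill = "extend")
}

roll_median <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  if (k >= length(x)) return(rep(median(x), length(x)))
  zoo::rollmedian(x, k, fill = "extend")
}

roll_sd <- function(x, k) {
  k <- max(3L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  if (k >= length(x)) return(rep(sd(x), length(x)))
  m1 <- zoo::rollmean(x, k, fill = "extend")
  m2 <- zoo::rollmean(x^2, k, fill = "extend")
  v <- pmax(0, (m2 - m1^2) * k / (k - 1))
  sqrt(v)
}

#' Detect R peaks in a single-lead ECG
#'
#' A Pan-Tompkins-style detector: band-pass filter (5-15 Hz), squaring,
#' moving-window integration, block-adaptive thresholding, and refinement of
#' each R-peak position on the filtered signal. Flat (dropout) stretches
#' produce no beats rather than spurious ones.
#'
#' @param ecg An `ecg_record`, or a numeric vector of samples (then `fs`
#'   must be given).
#' @param fs Sampling rate in Hz when `ecg` is a bare vector.
#' @param min_rri_s Refractory period: minimum separation of two R peaks in
#'   seconds (default 0.25, i.e. 240 bpm).
#' @return Numeric vector of R-peak times in seconds.
#' @export
detect_qrs <- function(ecg, fs = NULL, min_rri_s = 0.25) {
  if (inherits(ecg, "ecg_record")) {
    fs <- ecg$fs
    x <- ecg$samples
  } else {
    if (is.null(fs)) stop("`fs` required for a bare sample vector", call. = FALSE)
    x <- as.numeric(ecg)
  }
  if (length(x) < 10 * fs) stop("ECG must be at least 10 s long", call. = FALSE)

  bp <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  y <- signal::filtfilt(bp, x)
  e <- y^2
  integ <- roll_mean(e, round(0.12 * fs))

  # block-adaptive threshold: 0.25 of the 99th percentile per 60 s block,
  # floored globally so noise-only/dropout blocks cannot fire
  nb <- ceiling(length(integ) / (60 * fs))
  block <- rep(seq_len(nb), each = 60 * fs)[seq_along(integ)]
  q_blk <- tapply(integ, block, quantile, probs = 0.99, names = FALSE)
  q_glob <- quantile(integ, 0.99, names = FALSE)
  thr_blk <- pmax(0.25 * q_blk, 0.02 * q_glob)
  thr <- as.numeric(thr_blk[block])

  above <- integ > thr
  if (!any(above)) return(numeric(0))
  # contiguous runs above threshold -> one candidate peak per run
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  cand <- vapply(runs, function(i) {
    s <- starts[i]; e2 <- ends[i]
    as.integer(s + which.max(integ[s:e2]) - 1L)
  }, integer(1))

  # refine on the band-passed signal around each candidate (+-60 ms)
  hw <- as.integer(round(0.06 * fs))
  n <- length(y)
  peak <- vapply(cand, function(i) {
    s <- max(1L, i - hw); e2 <- min(n, i + hw)
    as.integer(s + which.max(y[s:e2]) - 1L)
  }, integer(1))
  peak <- sort(unique(peak))

  # enforce refractory period, keeping the larger peak of close pairs
  if (length(peak) > 1) {
    min_gap <- min_rri_s * fs
    keep <- logical(length(peak))
    last <- 1L
    keep[1] <- TRUE
    for (i in 2:length(peak)) {
      if (peak[i] - peak[last] >= min_gap) {
        keep[i] <- TRUE
        last <- i
      } else if (y[peak[i]] > y[peak[last]]) {
        keep[last] <- FALSE
        keep[i] <- TRUE
        last <- i
      }
    }
    peak <- peak[keep]
  }
  (peak - 1) / fs
}

#' Classify beats by QRS morphology and timing
#'
#' Implements the first artifact criterion: the pattern of the QRS complex
#' and its time of occurrence. Each beat's band-pass-filtered QRS window is
#' correlated against a running-median template; beats with low template
#' correlation or premature timing (interval below a fraction of the local
#' median R-R interval) are labelled `ectopic`, grossly dissimilar complexes
#' `artifact`. Uses the whole ECG waveform, not the interval series alone.
#'
#' @param ecg An `ecg_record` or numeric vector (with `fs`).
#' @param beat_times R-peak times from [detect_qrs()], seconds.
#' @param fs Sampling rate when `ecg` is a bare vector.
#' @param cor_threshold Minimum template correlation for a normal beat
#'   (default 0.9); below `artifact_threshold` (default 0.5) the beat is an
#'   `artifact` rather than `ectopic`.
#' @param premature_fraction A beat closing an interval shorter than this
#'   fraction of the local median R-R interval is premature (default 0.75).
#' @param template_window Number of beats in the running-median template
#'   (default 101).
#' @param artifact_threshold See `cor_threshold`.
#' @return A tibble (`beat_annotation`) with `time_s`, `correlation`,
#'   `amplitude`, `label` (`normal`/`ectopic`/`artifact`).
#' @export
classify_beats <- function(ecg, beat_times, fs = NULL,
                           cor_threshold = 0.9,
                           premature_fraction = 0.75,
                           template_window = 101L,
                           artifact_threshold = 0.5) {
  if (inherits(ecg, "ecg_record")) {
    fs <- ecg$fs
    x <- ecg$samples
  } else {
    if (is.null(fs)) stop("`fs` required for a bare sample vector", call. = FALSE)
    x <- as.numeric(ecg)
  }
  nb <- length(beat_times)
  if (nb < 30) stop("at least 30 beats are needed to form a template",
                    call. = FALSE)

  bp <- signal::butter(2, c(5, 20) / (fs / 2), type = "pass")
  y <- signal::filtfilt(bp, x)

  hw <- round(0.06 * fs)
  idx <- round(beat_times * fs) + 1L
  offs <- -hw:hw
  mat <- matrix(0, nb, length(offs))
  n <- length(y)
  pos <- outer(idx, offs, `+`)
  pos[pos < 1L] <- 1L
  pos[pos > n] <- n
  mat[] <- y[pos]

  # running median template across beats, column-wise
  k <- min(template_window, nb)
  if (k %% 2L == 0L) k <- k - 1L
  tmpl <- apply(mat, 2, function(col) {
    if (k >= length(col)) rep(median(col), length(col))
    else zoo::rollmedian(col, k, fill = "extend")
  })

  # row-wise Pearson correlation beat vs its template
  rc <- function(a, b) {
    a <- a - rowMeans(a)
    b <- b - rowMeans(b)
    num <- rowSums(a * b)
    den <- sqrt(rowSums(a^2) * rowSums(b^2))
    out <- num / den
    out[!is.finite(out)] <- 0
    out
  }
  correlation <- rc(mat, tmpl)
  amplitude <- y[pmin(pmax(idx, 1L), n)]

  label <- rep("normal", nb)
  label[correlation < cor_threshold] <- "ectopic"
  label[correlation < artifact_threshold] <- "artifact"

  rri <- diff(beat_times)
  local_med <- roll_median(rri, 31L)
  premature <- c(FALSE, rri < premature_fraction * local_med)
  label[premature & label == "normal"] <- "ectopic"

  structure(
    tibble(time_s = beat_times, correlation = correlation,
           amplitude = amplitude, label = label),
    class = c("beat_annotation", "tbl_df", "tbl", "data.frame")
  )
}

#' Build the R-R interval series from annotated beats
#'
#' Each interval is indexed by the time of its closing beat. An interval is
#' provisionally valid only if both bounding beats are labelled `normal`
#' (artifact criterion 1); criteria 2 and 3 are applied by
#' [apply_artifact_rules()].
#'
#' @param annotation A `beat_annotation` tibble from [classify_beats()].
#' @return A tibble (`rri_series`) with `time_s` (closing beat), `rri_ms`,
#'   `valid` and `beats_normal`.
#' @export
beats_to_rri <- function(annotation) {
  stopifnot(is.data.frame(annotation),
            all(c("time_s", "label") %in% names(annotation)))
  bt <- annotation$time_s
  if (length(bt) < 2) stop("need at least 2 beats", call. = FALSE)
  ok <- annotation$label == "normal"
  beats_normal <- ok[-1] & ok[-length(ok)]
  structure(
    tibble(
      time_s = bt[-1],
      rri_ms = diff(bt) * 1000,
      beats_normal = beats_normal,
      valid = beats_normal
    ),
    class = c("rri_series", "tbl_df", "tbl", "data.frame")
  )
}
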