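# End-to-end processing: ECG -> beats -> validated RRI -> EDR -> segments ->
# per-segment metrics; cohort-level driver over synthetic participants.

#' Process one long-term ECG recording into per-segment HRV metrics
#'
#' Runs the full pipeline: QRS detection, beat classification, individual
#' physiological limits, the three artifact criteria, 4 Hz resampling,
#' ECG-derived respiration with cycle validity, 180 s segmentation with
#' schedule-based exclusions, activity classification from heart rate and
#' accelerometer dynamics, the four validity criteria, and all per-segment
#' HRV metrics.
#'
#' @param ecg An `ecg_record`.
#' @param log Activity log tibble with `begin_s`, `end_s`, `label`,
#'   `is_sleep` (e.g. from [generate_activity_log()]); `NULL` treats the
#'   whole recording as daytime.
#' @param group `"toddler"` or `"adult"`; defaults to the record's group.
#' @param include_diff Compute differenced-series spectra too (default
#'   TRUE; the costliest optional step).
#' @param exclude_nap_window Apply the 12:00-14:00 exclusion (default TRUE).
#' @return A list of class `hrv_recording` with `segments` (the metrics
#'   tibble, including `condition`, `activity` and `overall_valid`),
#'   `beats`, `rri`, `grid`, `edr`, `inclusion` (from [decide_inclusion()])
#'   and `activity_ok`.
#' @export
process_recording <- function(ecg, log = NULL, group = NULL,
                              include_diff = TRUE,
                              exclude_nap_window = TRUE) {
  stopifnot(inherits(ecg, "ecg_record"))
  group <- group %||% ecg$group

  beat_times <- detect_qrs(ecg)
  ann <- classify_beats(ecg, beat_times)
  rri <- beats_to_rri(ann)
  rri <- compute_individual_limits(rri, group)
  rri <- apply_artifact_rules(rri)
  grid <- resample_to_4hz(rri, duration_s = ecg$duration_s)

  edr <- compute_edr(ecg, ann, group)
  cycles <- list(awake = detect_cycles(edr, group, "awake"),
                 rest = detect_cycles(edr, group, "rest"))

  segments <- make_segments(grid)
  if (!is.null(log)) {
    segments <- apply_schedule_exclusions(
      segments, log, start_clock_s = ecg$start_clock_s,
      exclude_nap_window = exclude_nap_window)
  } else {
    segments$condition <- "daytime"
  }
  segments <- segments[segments$condition != "excluded", , drop = FALSE]

  metrics <- segment_metrics(grid, rri, segments, cycles,
                             accel = ecg$accel, accel_fs = ecg$accel_fs,
                             include_diff = include_diff)
  metrics <- classify_activity(metrics)
  activity_ok <- attr(metrics, "activity_ok")
  inclusion <- decide_inclusion(metrics)

  structure(list(
    segments = metrics,
    beats = ann,
    rri = rri,
    grid = grid,
    edr = edr,
    inclusion = inclusion,
    activity_ok = activity_ok,
    group = group,
    id = ecg$id
  ), class = "hrv_recording")
}

#' @export
print.hrv_recording <- function(x, ...) {
  v <- sum(x$segments$overall_valid)
  cat(sprintf(
    "<hrv_recording> %s participant %s: %d segments (%d valid, %.0f%%)\n",
    x$group, x$id, nrow(x$segments), v, 100 * v / max(1, nrow(x$segments))))
  invisible(x)
}

#' Simulate and process a synthetic cohort
#'
#' Generates `n_per_group` participants for each requested group
#' configuration, runs [process_recording()] on every recording, and binds
#' the per-segment metrics with participant and group identifiers --
#' the input expected by [participant_accordance()] and
#' [summarize_tables()].
#'
#' @param configs A named list of [cohort_config()] objects (names become
#'   group labels), e.g. `list(toddler = ..., adult = ...)`.
#' @param include_diff Passed to [process_recording()].
#' @return A list of class `hrv_cohort` with `segments` (bound tibble with
#'   `participant`, `group` columns) and `recordings` (list of
#'   `hrv_recording`).
#' @export
analyze_cohort <- function(configs, include_diff = FALSE) {
  stopifnot(is.list(configs), length(names(configs)) == length(configs))
  recs <- list()
  seg_list <- list()
  for (gname in names(configs)) {
    cfg <- configs[[gname]]
    for (i in seq_len(cfg$n_participants)) {
      p <- simulate_participant(cfg, i)
      rec <- process_recording(p$ecg, p$log, include_diff = include_diff)
      pid <- paste0(gname, "_", i)
      recs[[pid]] <- rec
      seg_list[[pid]] <- dplyr::mutate(rec$segments, participant = pid,
                                       group = gname, .before = 1)
    }
  }
  structure(list(segments = dplyr::bind_rows(seg_list), recordings = recs),
            class = "hrv_cohort")
}

#' Write the tables of a processed recording to CSV files
#'
#' Writes beat annotations (`beats.csv`: time_s, correlation, amplitude,
#' label), the validated R-R series (`rri.csv`: time_s, rri_ms, valid,
#' envelope columns) and the per-segment metrics (`segments.csv`) into a
#' directory.
#'
#' @param rec An `hrv_recording`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_recording_csv <- function(rec, dir) {
  stopifnot(inherits(rec, "hrv_recording"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(rec$beats, file.path(dir, "beats.csv"), row.names = FALSE)
  utils::write.csv(rec$rri, file.path(dir, "rri.csv"), row.names = FALSE)
  utils::write.csv(rec$segments, file.path(dir, "segments.csv"),
                   row.names = FALSE)
  invisible(dir)
}
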