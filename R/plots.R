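# ggplot2 helpers for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a Burg spectral estimate
#'
#' @param object A `psd_estimate` from [burg_psd()].
#' @param bands Optional band tibble from [hf_bands()] to shade.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.psd_estimate <- function(object, bands = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$freq_hz, .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (Hz)",
                  y = expression(PSD ~ (ms^2 / Hz))) +
    ggplot2::coord_cartesian(xlim = c(0, 1.04)) +
    ggplot2::theme_minimal()
  if (!is.null(bands)) {
    b <- bands[is.finite(bands$lower), , drop = FALSE]
    p <- p + ggplot2::geom_rect(
      data = b, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$lower, xmax = .data$upper,
                   ymin = -Inf, ymax = Inf, fill = .data$band),
      alpha = 0.12)
  }
  p
}

#' Stacked prevalent-frequency fractions per participant
#'
#' Reproduces the stacked-bar layout showing where each participant's
#' spectral power lives: one bar per participant, stacked by frequency
#' band, faceted by group.
#'
#' @param segments Per-segment metrics with `participant`, `group`,
#'   `overall_valid` and `frac_*` columns (use `diff = TRUE` for the
#'   differenced-series fractions).
#' @param diff Plot the differenced-series fractions instead.
#' @return A ggplot.
#' @export
plot_prevalent_fractions <- function(segments, diff = FALSE) {
  pre <- if (diff) "diff_frac_" else "frac_"
  cols <- paste0(pre, c("004_015", "015_024", "024_040", "040_080",
                        "080_104"))
  stopifnot(all(cols %in% names(segments)))
  lv <- c("0.04-0.15", "0.15-0.24", "0.24-0.40", "0.40-0.80", "0.80-1.04")
  d <- segments |>
    dplyr::filter(.data$overall_valid) |>
    dplyr::group_by(.data$participant, .data$group) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(cols),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop") |>
    tidyr::pivot_longer(dplyr::all_of(cols), names_to = "band",
                        values_to = "fraction") |>
    dplyr::mutate(band = factor(lv[match(.data$band, cols)], levels = rev(lv)))
  ggplot2::ggplot(d, ggplot2::aes(.data$participant, .data$fraction,
                                  fill = .data$band)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_wrap(~group, scales = "free_x") +
    ggplot2::scale_fill_viridis_d(name = "Band (Hz)") +
    ggplot2::labs(x = NULL, y = "Fraction of total PSD (1/180-1.04 Hz)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Accordance (Fisher Z') by band, group and condition
#'
#' @param accordance An `hrv_accordance` tibble from
#'   [participant_accordance()].
#' @return A ggplot: mean Z' with one-SD error bars per band, faceted by
#'   condition, coloured by group.
#' @export
plot_accordance <- function(accordance) {
  d <- summarize_tables(accordance)
  ggplot2::ggplot(d, ggplot2::aes(.data$band, .data$mean,
                                  colour = .data$group,
                                  group = .data$group)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.4)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      width = 0.2, position = ggplot2::position_dodge(0.4)) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "HF band", y = "Fisher Z' (ln SD1 vs ln HF power)") +
    ggplot2::theme_minimal()
}
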