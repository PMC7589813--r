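# Per-participant accordance between ln(SD1) and ln(HF band power),
# Fisher Z' transform, summary tables, three-way mixed ANOVA.

#' Fisher's Z' transform and its inverse
#'
#' `Z' = 0.5 * ln((1 + r) / (1 - r))`, the variance-stabilizing transform of
#' a Pearson correlation; the inverse is `tanh`. A mean Z' of 2.51
#' back-transforms to r = 0.987.
#'
#' @param r Pearson correlation(s), `|r| < 1`.
#' @return `fisher_z()`: the transformed value(s).
#' @export
#' @examples
#' fisher_z(0.5)            # 0.5 * log(3)
#' inverse_fisher_z(2.51)   # 0.987
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    stop("|r| must be < 1; clamp first (see participant_accordance)",
         call. = FALSE)
  }
  0.5 * log((1 + r) / (1 - r))
}

#' @rdname fisher_z
#' @param z Fisher-transformed value(s).
#' @return `inverse_fisher_z()`: the correlation(s), `tanh(z)`.
#' @export
inverse_fisher_z <- function(z) tanh(z)

#' Shared variance of two variables from their correlation
#'
#' @param r Pearson correlation, `|r| <= 1`.
#' @return Percentage of shared variance, `100 * r^2` (r = 0.987 gives
#'   97.42%).
#' @export
shared_variance <- function(r) {
  stopifnot(all(abs(r) <= 1, na.rm = TRUE))
  100 * r^2
}

# expand each valid segment row into the overlapping analysis conditions:
# sleep; daytime; low/high activity (subsets of daytime)
expand_conditions <- function(segments) {
  base <- dplyr::filter(segments, .data$condition %in% c("sleep", "daytime"))
  act <- dplyr::filter(base, .data$condition == "daytime",
                       !is.na(.data$activity))
  dplyr::bind_rows(
    base,
    dplyr::mutate(act, condition = paste0(.data$activity, "_activity"))
  )
}

#' Per-participant accordance between ln(SD1) and ln(HF band power)
#'
#' For every participant, frequency band (HF1-HF6) and recording condition
#' (sleep, total daytime, low-activity daytime, high-activity daytime), the
#' Pearson correlation between ln(SD1) and ln(HF band power) across all
#' valid 180 s segments is computed and Fisher-Z' transformed -- up to 24
#' correlation coefficients per participant. Correlations are clamped at
#' `1 - 1e-12` in magnitude before the transform; cells with fewer than
#' `min_segments` valid segments or zero variance are marked missing.
#'
#' @param segments Per-segment metrics with `participant`, `group`,
#'   `condition`, `activity`, `overall_valid`, `ln_sd1` and
#'   `ln_hf1`..`ln_hf6` columns (see [analyze_cohort()]).
#' @param min_segments Minimum valid segments per cell (default 10).
#' @return A tibble (`hrv_accordance`) with `participant`, `group`, `band`,
#'   `condition`, `n_segments`, `pearson_r`, `fisher_z`.
#' @export
participant_accordance <- function(segments, min_segments = 10) {
  stopifnot(all(c("participant", "group", "condition", "overall_valid",
                  "ln_sd1") %in% names(segments)))
  if (!"activity" %in% names(segments)) segments$activity <- NA_character_
  valid <- dplyr::filter(segments, .data$overall_valid)
  long <- tidyr::pivot_longer(
    expand_conditions(valid),
    cols = dplyr::all_of(paste0("ln_hf", 1:6)),
    names_to = "band", values_to = "ln_hf",
    names_prefix = "ln_")
  out <- long |>
    dplyr::group_by(.data$participant, .data$group, .data$band,
                    .data$condition) |>
    dplyr::summarise(
      n_segments = sum(is.finite(.data$ln_sd1) & is.finite(.data$ln_hf)),
      pearson_r = {
        ok <- is.finite(.data$ln_sd1) & is.finite(.data$ln_hf)
        x <- .data$ln_sd1[ok]; y <- .data$ln_hf[ok]
        if (length(x) < 2 || sd(x) == 0 || sd(y) == 0) NA_real_
        else cor(x, y)
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(
      pearson_r = dplyr::if_else(.data$n_segments >= min_segments,
                                 .data$pearson_r, NA_real_),
      fisher_z = fisher_z(pmin(pmax(.data$pearson_r, -(1 - 1e-12)),
                               1 - 1e-12))
    )
  structure(out, class = c("hrv_accordance", class(out)))
}

#' Mixed (split-plot) analysis of variance
#'
#' Classical univariate repeated-measures decomposition for designs with
#' one or two within-subject factors and one between-subject factor, fitted
#' with [stats::aov()] error strata (`Error(subject/(w1*w2))`). F values are
#' reported as `F(df_between, df_within)`; no sphericity correction is
#' applied by default, matching the uncorrected degrees-of-freedom
#' convention (e.g. a 6-level band factor over 95 subjects gives F(5, 465)
#' for the band-by-group interaction).
#'
#' @param data Long-format tibble: one row per subject x cell.
#' @param dv Name of the response column.
#' @param within Character vector of one or two within-subject factor
#'   columns.
#' @param between Name of the between-subject factor column.
#' @param subject Name of the subject identifier column.
#' @return An object of class `hrv_anova`; see [tidy.hrv_anova()].
#'   Subjects with incomplete within-factor cells are dropped listwise.
#' @export
mixed_anova <- function(data, dv, within, between, subject = "participant") {
  stopifnot(length(within) %in% c(1L, 2L),
            all(c(dv, within, between, subject) %in% names(data)))
  d <- data[, c(subject, between, within, dv)]
  names(d) <- c(".subj", ".grp", paste0(".w", seq_along(within)), ".y")
  d <- d[complete.cases(d), , drop = FALSE]
  # aggregate duplicates, then keep only subjects with complete cells
  wcols <- paste0(".w", seq_along(within))
  d <- dplyr::summarise(
    dplyr::group_by(dplyr::as_tibble(d),
                    dplyr::across(dplyr::all_of(c(".subj", ".grp", wcols)))),
    .y = mean(.data$.y), .groups = "drop")
  n_cells <- prod(vapply(wcols, function(w) length(unique(d[[w]])), 1L))
  cnt <- dplyr::count(d, .data$.subj)
  complete <- cnt$.subj[cnt$n == n_cells]
  n_dropped <- length(unique(d$.subj)) - length(complete)
  d <- d[d$.subj %in% complete, , drop = FALSE]
  if (length(unique(d$.grp)) < 2 ||
      min(table(unique(d[, c(".subj", ".grp")])$.grp)) < 2) {
    stop("need at least 2 subjects per group", call. = FALSE)
  }
  d$.subj <- factor(d$.subj)
  d$.grp <- factor(d$.grp)
  for (w in wcols) d[[w]] <- factor(d[[w]])

  rhs <- paste(c(wcols, ".grp"), collapse = " * ")
  err <- paste0("Error(.subj/(", paste(wcols, collapse = " * "), "))")
  form <- stats::as.formula(paste(".y ~", rhs, "+", err))
  fit <- stats::aov(form, data = d)

  smy <- summary(fit)
  rows <- list()
  for (stratum in names(smy)) {
    tab <- smy[[stratum]][[1]]
    terms <- trimws(rownames(tab))
    res_i <- which(terms == "Residuals")
    if (length(res_i) == 0) next
    df_w <- tab[res_i, "Df"]
    for (i in seq_len(nrow(tab))) {
      if (i == res_i) next
      rows[[length(rows) + 1L]] <- tibble(
        effect = terms[i], df1 = tab[i, "Df"], df2 = df_w,
        sumsq = tab[i, "Sum Sq"],
        statistic = tab[i, "F value"], p.value = tab[i, "Pr(>F)"],
        stratum = stratum
      )
    }
  }
  table <- dplyr::bind_rows(rows)
  # human-readable effect names
  ren <- c(stats::setNames(within, wcols), stats::setNames(between, ".grp"))
  relabel <- function(e) {
    parts <- strsplit(e, ":", fixed = TRUE)[[1]]
    paste(ifelse(parts %in% names(ren), ren[parts], parts), collapse = ":")
  }
  table$effect <- vapply(table$effect, relabel, character(1))

  structure(list(
    table = table,
    fit = fit,
    dv = dv, within = within, between = between,
    n_subjects = length(complete),
    n_dropped = n_dropped
  ), class = "hrv_anova")
}

#' @export
print.hrv_anova <- function(x, ...) {
  cat(sprintf("Mixed ANOVA of %s (%d subjects, %d dropped)\n",
              x$dv, x$n_subjects, x$n_dropped))
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-40s F(%d,%d) = %.2f, p = %.4g\n", tab$effect[i],
                tab$df1[i], tab$df2[i], tab$statistic[i], tab$p.value[i]))
  }
  invisible(x)
}

#' Tidy a mixed ANOVA
#'
#' @param x An `hrv_anova` from [mixed_anova()].
#' @param ... Unused.
#' @return A tibble with `effect`, `df1`, `df2`, `sumsq`, `statistic`,
#'   `p.value`, `stratum`.
#' @export
tidy.hrv_anova <- function(x, ...) x$table

#' @rdname tidy.hrv_anova
#' @return `glance()`: a one-row tibble with `n_subjects`, `n_dropped`,
#'   `n_effects`.
#' @export
glance.hrv_anova <- function(x, ...) {
  tibble(n_subjects = x$n_subjects, n_dropped = x$n_dropped,
         n_effects = nrow(x$table))
}

#' Group-by-condition summary tables
#'
#' Mean and standard deviation across participants, laid out like the
#' descriptive tables of a cohort report. For an accordance table
#' (`hrv_accordance` or any tibble with `fisher_z`), cells are mean +- SD
#' of Z' per band, group and condition. For per-segment metrics, each
#' participant is first reduced to a per-condition mean over valid
#' segments, then summarized across participants.
#'
#' @param x An `hrv_accordance` tibble, or per-segment metrics with
#'   `participant`, `group`, `condition`, `activity`, `overall_valid`.
#' @param vars For metrics input: variables to summarize (default heart
#'   rate, SDNN, ln SD1/SD2, respiration rate and the six ln HF powers).
#' @return A tibble with `variable` (or `band`), `group`, `condition`, `n`,
#'   `mean`, `sd`.
#' @export
summarize_tables <- function(x, vars = NULL) {
  if ("fisher_z" %in% names(x)) {
    out <- x |>
      dplyr::filter(is.finite(.data$fisher_z)) |>
      dplyr::group_by(.data$band, .data$group, .data$condition) |>
      dplyr::summarise(n = dplyr::n(), mean = mean(.data$fisher_z),
                       sd = if (dplyr::n() > 1) sd(.data$fisher_z) else 0,
                       .groups = "drop")
    return(out)
  }
  vars <- vars %||% c("mean_hr", "sdnn", "ln_sd1", "ln_sd2",
                      "median_resp_rate", paste0("ln_hf", 1:6))
  if (!"activity" %in% names(x)) x$activity <- NA_character_
  x |>
    dplyr::filter(.data$overall_valid) |>
    expand_conditions() |>
    tidyr::pivot_longer(dplyr::all_of(vars), names_to = "variable") |>
    dplyr::group_by(.data$participant, .data$group, .data$condition,
                    .data$variable) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::group_by(.data$variable, .data$group, .data$condition) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sd = if (dplyr::n() > 1) sd(.data$value) else 0,
                     .groups = "drop")
}
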