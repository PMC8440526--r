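#' Per-well FRET ratios normalized to the control mean
#'
#' Computes the raw ratiometric readout `raw_ratio = DxAm / DxDm` for every
#' well and normalizes it to the mean raw ratio of the no-treatment
#' (control) wells, so the control group has mean normalized ratio exactly
#' 1. Normalization can optionally be performed within groups (e.g. per
#' plate or per time point) via `group`.
#'
#' @param wells Data frame of well measurements with at least `DxDm`,
#'   `DxAm` and `treatment` columns.
#' @param control_label Treatment label identifying the reference wells.
#' @param group Optional character vector of grouping columns within which
#'   the control mean is computed (default: one reference for the whole
#'   table).
#'
#' @return The input tibble with `raw_ratio`, `reference_mean` and
#'   `normalized_ratio` columns appended.
#' @export
fret_ratio_normalize <- function(wells, control_label = "control",
                                 group = NULL) {
  wells <- as_tibble(wells)
  assert_columns(wells, c("DxDm", "DxAm", "treatment"), "`wells`")
  if (any(wells$DxDm <= 0)) {
    bad <- if ("well_id" %in% names(wells)) {
      paste(wells$well_id[wells$DxDm <= 0], collapse = ", ")
    } else {
      paste(which(wells$DxDm <= 0), collapse = ", ")
    }
    abort(sprintf("DxDm must be positive to form a ratio (offending well(s): %s).", bad),
          class = "osmofret_division_error")
  }
  if (!any(wells$treatment == control_label)) {
    abort(sprintf("no wells labelled '%s' to serve as the normalization reference.",
                  control_label),
          class = "osmofret_reference_error")
  }
  wells <- dplyr::mutate(wells, raw_ratio = .data$DxAm / .data$DxDm)
  if (is.null(group)) {
    ref <- mean(wells$raw_ratio[wells$treatment == control_label])
    wells$reference_mean <- ref
  } else {
    assert_columns(wells, group, "`wells`")
    refs <- wells |>
      dplyr::filter(.data$treatment == control_label) |>
      dplyr::group_by(dplyr::across(dplyr::all_of(group))) |>
      dplyr::summarise(reference_mean = mean(.data$raw_ratio), .groups = "drop")
    wells <- dplyr::left_join(wells, refs, by = group)
    if (anyNA(wells$reference_mean)) {
      abort("some groups contain no control wells.",
            class = "osmofret_reference_error")
    }
  }
  dplyr::mutate(wells, normalized_ratio = .data$raw_ratio / .data$reference_mean)
}

#' Dose-response sensitivity of the normalized FRET ratio
#'
#' Summarizes how strongly the normalized ratio responds to solute
#' concentration as the ordinary-least-squares slope of
#' `normalized_ratio ~ concentration`, with a sign dead-band: slopes within
#' `threshold` of zero are classed as `"none"`, positive slopes as
#' `"compaction"` (ratio rises as the sensor compacts) and negative slopes
#' as `"expansion"`.
#'
#' @param results Data frame with `normalized_ratio` and a concentration
#'   column.
#' @param concentration Name of the concentration column.
#' @param threshold Dead-band half-width on the slope (per unit
#'   concentration).
#'
#' @return A one-row tibble of class `fret_sensitivity` with `slope`,
#'   `direction`, `r_squared` and `n`.
#' @export
dose_response_sensitivity <- function(results, concentration = "concentration_M",
                                      threshold = 0.01) {
  results <- as_tibble(results)
  assert_columns(results, c("normalized_ratio", concentration), "`results`")
  conc <- results[[concentration]]
  if (length(unique(conc)) < 3L) {
    if (length(unique(conc)) == 1L) {
      abort("all concentrations are identical; the design is degenerate.",
            class = "osmofret_degenerate_design")
    }
    abort("at least 3 distinct concentrations are required.",
          class = "osmofret_invalid_parameter")
  }
  fit <- lm(results$normalized_ratio ~ conc)
  slope <- unname(coef(fit)[2])
  r2 <- summary(fit)$r.squared
  direction <- if (abs(slope) < threshold) "none"
    else if (slope > 0) "compaction" else "expansion"
  structure(
    tibble(slope = slope, direction = direction, r_squared = r2,
           n = nrow(results)),
    class = c("fret_sensitivity", class(tibble())))
}

#' Loess smoothing of a FRET time course
#'
#' Locally weighted linear regression (tricube weights over the
#' span-nearest neighbours) evaluated at the input times, with a 95%
#' pointwise confidence band from the local residual variance. Constant and
#' exactly linear series are reproduced to machine precision by the
#' degree-1 local fit.
#'
#' @param data Data frame holding the time course.
#' @param time,value Column names (tidy-eval) of the time (s) and response.
#' @param span Fraction of points in each local neighbourhood, in (0, 1].
#'
#' @return A tibble with `time`, `value`, `smoothed`, `ci_lower`,
#'   `ci_upper`.
#' @export
smooth_timecourse <- function(data, time = "time_s", value = "normalized_ratio",
                              span = 0.3) {
  data <- as_tibble(data)
  time <- rlang::as_name(rlang::ensym(time))
  value <- rlang::as_name(rlang::ensym(value))
  assert_columns(data, c(time, value), "`data`")
  t <- data[[time]]; v <- data[[value]]
  n <- length(t)
  if (n < 5L) {
    abort("at least 5 points are required for smoothing.",
          class = "osmofret_invalid_parameter")
  }
  assert_scalar_number(span, "span", lower = 0, upper = 1, strict_lower = TRUE)
  if (span * n < 3) {
    abort(sprintf("span %.3g covers fewer than 3 of the %d points.", span, n),
          class = "osmofret_span_error")
  }
  fit <- loess(v ~ t, span = span, degree = 1, family = "gaussian",
               surface = "direct")
  pred <- predict(fit, newdata = data.frame(t = t), se = TRUE)
  tibble(
    time = t, value = v,
    smoothed = as.numeric(pred$fit),
    ci_lower = as.numeric(pred$fit - 1.96 * pred$se.fit),
    ci_upper = as.numeric(pred$fit + 1.96 * pred$se.fit)
  )
}
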