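# ggplot2 visualizations for the main result types.

#' @export
autoplot.decay_histogram <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_center_ns,
                                            y = .data$counts)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (ns)", y = "photon counts")
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "lifetime_fit"))
    p <- p + ggplot2::geom_line(
      data = tibble(t = object$bin_center_ns, f = fit$fitted),
      ggplot2::aes(x = .data$t, y = .data$f), colour = "firebrick")
  }
  p
}

#' @export
autoplot.phasor_point <- function(object, ...) {
  semi <- tibble(
    g = 0.5 + 0.5 * cos(seq(0, pi, length.out = 200)),
    s = 0.5 * sin(seq(0, pi, length.out = 200))
  )
  ggplot2::ggplot(object, ggplot2::aes(x = .data$g, y = .data$s)) +
    ggplot2::geom_path(data = semi, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(colour = "steelblue", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "g", y = "s",
                  title = "Phasor plot (universal semicircle dashed)")
}

#' @export
autoplot.scan_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lambda, y = .data$normalized_rg)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = (.data$mean_rg - .data$sd_rg) / max(.data$mean_rg),
      ymax = (.data$mean_rg + .data$sd_rg) / max(.data$mean_rg)),
      alpha = 0.2, fill = "steelblue") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(x = "solution repulsion λ (kT per contact)",
                  y = "normalized Rg")
}

#' Dose-response plot of normalized FRET ratios
#'
#' Normalized ratio against concentration with the OLS sensitivity line.
#'
#' @param results Output of [fret_ratio_normalize()] with a concentration
#'   column.
#' @param concentration Concentration column name.
#' @return A ggplot object.
#' @export
plot_dose_response <- function(results, concentration = "concentration_M") {
  ggplot2::ggplot(results, ggplot2::aes(x = .data[[concentration]],
                                        y = .data$normalized_ratio)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "firebrick") +
    ggplot2::labs(x = "concentration (M)", y = "normalized DxAm/DxDm")
}

#' Render a ratiometric image
#'
#' @param x A `ratio_image` from [ratiometric_image()].
#' @return A ggplot raster of the masked ratio.
#' @export
plot_ratio_image <- function(x) {
  stopifnot(inherits(x, "ratio_image"))
  df <- tidyr::expand_grid(row = seq_len(nrow(x$ratio)),
                           col = seq_len(ncol(x$ratio)))
  df$ratio <- as.vector(x$ratio)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$ratio)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "DxAm/DxDm")
}
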