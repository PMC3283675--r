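#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot velocity-versus-voltage sweeps
#'
#' One line per cell of recorded terminal speed against applied voltage;
#' the slope of each line is proportional to that cell's zeta-potential
#' magnitude, so storage-related decay is visible as flattening.
#'
#' @param sweeps Sweep tibble (see [simulate_zeta_sweeps()]).
#' @param max_cells Plot at most this many cells per day (default 5).
#' @return A ggplot object.
#' @export
plot_zeta_sweeps <- function(sweeps, max_cells = 5L) {
  stopifnot(all(c("cell_id", "voltage_V", "velocity_m_s") %in% names(sweeps)))
  keep <- sweeps |>
    dplyr::distinct(.data$cell_id, .keep_all = TRUE) |>
    dplyr::group_by(dplyr::across(dplyr::any_of("day"))) |>
    dplyr::slice_head(n = max_cells) |>
    dplyr::pull(.data$cell_id)
  df <- dplyr::filter(sweeps, .data$cell_id %in% keep)
  df$speed_um_s <- convert_units(abs(df$velocity_m_s), "m/s", "um/s")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$voltage_V,
                                        y = .data$speed_um_s,
                                        group = .data$cell_id)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Applied voltage (V)",
                  y = "Terminal speed (µm/s)") +
    ggplot2::theme_minimal()
  if ("day" %in% names(df))
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$day),
                                 labeller = ggplot2::label_both)
  p
}

#' Autoplot a cohort day summary as a storage time course
#'
#' Mean with standard-error bars against storage day (pooled rows are
#' plotted at the mean of their member days), the layout of the published
#' elasticity time course.
#'
#' @param object An `"rbl_summary"` tibble from [summarize_by_day()].
#' @param units Axis label for the summarised quantity.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rbl_summary
#' @export
autoplot.rbl_summary <- function(object, units = "value", ...) {
  df <- tibble::tibble(
    day = vapply(object$days, function(d) mean(d), numeric(1L)),
    label = object$label, mean = object$mean, se = object$se,
    pooled = lengths(object$days) > 1L
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$mean)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.8) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$pooled), size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17),
                                guide = "none") +
    ggplot2::labs(x = "Storage time (days)", y = units) +
    ggplot2::theme_minimal()
}

#' Plot ROS percent-positive kinetics over storage
#'
#' @param ros_series Tibble with `day` and `percent_positive` columns.
#' @return A ggplot object.
#' @export
plot_ros_kinetics <- function(ros_series) {
  stopifnot(all(c("day", "percent_positive") %in% names(ros_series)))
  ggplot2::ggplot(ros_series, ggplot2::aes(x = .data$day,
                                           y = .data$percent_positive)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Storage time (days)",
                  y = "ROS-positive cells (%)") +
    ggplot2::theme_minimal()
}

#' Autoplot a simulated ROS event set
#'
#' Log-intensity histogram with the gating threshold marked, the standard
#' cytometry view of a two-population fluorescence distribution.
#'
#' @param object An `"rbl_ros"` event tibble from [simulate_ros()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rbl_ros
#' @export
autoplot.rbl_ros <- function(object, ...) {
  thr <- attr(object, "threshold")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$intensity)) +
    ggplot2::geom_histogram(bins = 80) +
    ggplot2::scale_x_log10() +
    ggplot2::geom_vline(xintercept = thr, linetype = 2) +
    ggplot2::labs(x = "Fluorescence intensity (a.u., log scale)",
                  y = "Events") +
    ggplot2::theme_minimal()
}
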