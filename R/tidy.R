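#' Tidy a tracked point trajectory
#'
#' @param x a [track_point()] trajectory.
#' @param ... unused.
#' @return A tibble with one row per cardiac phase: `label`, `phase`
#'   (fraction of R-R), `x`, `y`, `z` (mm).
#' @export
tidy.point_trajectory <- function(x, ...) {
  tibble::tibble(label = x$label, phase = seq(0, 0.9, by = 0.1),
                 x = x$positions[, 1], y = x$positions[, 2],
                 z = x$positions[, 3])
}

#' @rdname tidy.point_trajectory
#' @return `glance()`: a one-row tibble with the per-axis amplitudes and
#'   both pathlength closures.
#' @export
glance.point_trajectory <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(label = x$label),
    motion_amplitudes(x),
    tibble::tibble(pathlength_open = pathlength(x, "open"),
                   pathlength_cyclic = pathlength(x, "cyclic")))
}

#' Tidy a centerline
#'
#' @param x a [centerline()].
#' @param ... unused.
#' @return A tibble: `position` (arc mm), `x`, `y`, `z`, `mark`.
#' @export
tidy.centerline <- function(x, ...) {
  out <- tibble::tibble(position = arc_positions(x),
                        x = x$points[, 1], y = x$points[, 2],
                        z = x$points[, 3], mark = NA_character_)
  if (length(x$marks)) out$mark[x$marks] <- names(x$marks)
  out
}

#' Generic tidiers
#'
#' `tidy()` returns observation-level tibbles, `glance()` one-row
#' summaries, following the broom convention.
#'
#' @param x an object.
#' @param ... passed on to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Plot a curvature profile
#'
#' Curvature (m^-1) against arc-length position (mm); when the profile
#' carries a per-point cardiac-cycle range, it is drawn as a second panel.
#'
#' @param object a `curvature_profile` tibble from [curvature()] or
#'   [curvature_change_profile()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.curvature_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$kappa)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::labs(x = "centerline position (mm)",
                  y = expression(kappa ~ (m^-1)),
                  title = "Centerline curvature") +
    ggplot2::theme_minimal()
  if ("kappa_change" %in% names(df) && any(!is.na(df$kappa_change))) {
    long <- tidyr::pivot_longer(df, c("kappa", "kappa_change"),
                                names_to = "quantity", values_to = "value")
    p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$position, y = .data$value)) +
      ggplot2::geom_line(color = "#2c7fb8") +
      ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y",
                          labeller = ggplot2::as_labeller(c(
                            kappa = "curvature (m^-1)",
                            kappa_change = "cycle curvature change (m^-1)"))) +
      ggplot2::labs(x = "centerline position (mm)", y = NULL,
                    title = "Centerline curvature and cardiac-cycle change") +
      ggplot2::theme_minimal()
  }
  p
}

#' Plot diameter pairs along the centerline
#'
#' Mean diameter per 1 cm level with the min/max band of the two
#' perpendicular diameters; a second panel shows the pulsatile diameter
#' change when present.
#'
#' @param object a [diameter_pairs()] tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.diameter_pairs <- function(object, ...) {
  df <- tibble::as_tibble(object)[object$ok, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$spread_lo,
                                      ymax = .data$spread_hi),
                         fill = "#a6bddb", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), color = "#045a8d") +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean), color = "#045a8d") +
    ggplot2::labs(x = "centerline position (mm)", y = "diameter (mm)",
                  title = "Diameter pairs (mean and spread)") +
    ggplot2::theme_minimal()
  p
}

#' Plot per-point motion amplitudes
#'
#' Bar chart of per-axis amplitudes and pathlength for each labeled point —
#' the layout of a per-point pulsatility figure.
#'
#' @param motion the tibble returned by [track_points()].
#' @return A ggplot object.
#' @export
plot_motion_amplitudes <- function(motion) {
  long <- tidyr::pivot_longer(motion,
                              c("amplitude_x", "amplitude_y", "amplitude_z",
                                "pathlength"),
                              names_to = "metric", values_to = "mm")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$mm)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mm",
                  title = "Cardiac-pulsatility-induced motion per point") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
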