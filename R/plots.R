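# ggplot2 views of the main result types.

#' @describeIn contractile_trace autoplot(): contractile-strain trace with
#'   the peak marked.
#' @param object the result object.
#' @method autoplot contraction_trace
#' @export
autoplot.contraction_trace <- function(object, ...) {
  pk <- object$trace[object$trace$frame == object$peak_frame, ]
  ggplot2::ggplot(object$trace, ggplot2::aes(.data$t_s,
                                             100 * .data$mean_eps2)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = pk, colour = "red") +
    ggplot2::labs(x = "time (s)", y = "mean contractile strain (%)",
                  title = sprintf("max contractile strain %.2f%%",
                                  object$max_contractile_strain_pct)) +
    ggplot2::theme_minimal()
}

#' @describeIn build_activation_map autoplot(): isochronal activation map.
#' @param object an `activation_map`.
#' @param ... unused.
#' @method autoplot activation_map
#' @export
autoplot.activation_map <- function(object, ...) {
  ggplot2::ggplot(object[object$valid, ],
                  ggplot2::aes(.data$x_um, .data$y_um,
                               fill = .data$t_act_ms)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "activation (ms)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
}

#' @describeIn conduction_velocity autoplot(): local velocity vectors.
#' @param object a `velocity_field`.
#' @method autoplot velocity_field
#' @export
autoplot.velocity_field <- function(object, ...) {
  w <- object$windows[object$windows$valid, ]
  sc <- 0.4 * object$pixel_um_eff * object$k / max(w$speed_cm_s)
  ggplot2::ggplot(w, ggplot2::aes(.data$x_um, .data$y_um)) +
    ggplot2::geom_segment(ggplot2::aes(
      xend = .data$x_um + sc * .data$speed_cm_s *
        cos(.data$angle_deg * pi / 180),
      yend = .data$y_um + sc * .data$speed_cm_s *
        sin(.data$angle_deg * pi / 180),
      colour = .data$speed_cm_s),
      arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm"))) +
    ggplot2::scale_colour_viridis_c(name = "CV (cm/s)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
}

#' @describeIn orientation_field autoplot(): window orientations colored
#'   by angle, alpha by weight.
#' @param object an `orientation_field`.
#' @param ... unused.
#' @method autoplot orientation_field
#' @export
autoplot.orientation_field <- function(object, ...) {
  v <- object[object$valid, ]
  ggplot2::ggplot(v, ggplot2::aes(.data$col, -.data$row,
                                  fill = .data$angle_deg,
                                  alpha = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradientn(
      colours = c("#4575b4", "#ffffbf", "#d73027", "#4575b4"),
      limits = c(0, 180), name = "angle (deg)") +
    ggplot2::scale_alpha(range = c(0.2, 1), guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}

#' Rose histogram of step directions
#'
#' Polar histogram in the figure convention of migration analyses:
#' 90 degrees points up, 270 down.
#'
#' @param steps a [step_stats()] result.
#' @param bin_deg bin width (divides 360).
#' @return a ggplot.
#' @export
plot_rose <- function(steps, bin_deg = 20) {
  h <- angular_histogram(steps, bin_deg)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_start_deg + bin_deg / 2,
                                  y = .data$count)) +
    ggplot2::geom_col(width = bin_deg, fill = "steelblue",
                      colour = "grey30", linewidth = 0.2) +
    ggplot2::coord_polar(start = pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 315, by = 45)) +
    ggplot2::labs(x = NULL, y = "steps") +
    ggplot2::theme_minimal()
}
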