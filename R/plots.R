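# ggplot2 displays for the main result types.

#' Plot a long-channel march
#'
#' Step plot of the channel concentration and the feasible cross-section edge
#' along the channel axis.
#'
#' @param object A `march_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot march_result
#' @export
autoplot.march_result <- function(object, ...) {
  el <- object$elements
  df <- dplyr::bind_rows(
    tibble(z = el$z_in, value = el$c_wall,
           quantity = "channel concentration (mol/m^3)"),
    tibble(z = el$z_in, value = el$s, quantity = "edge length (mm)")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$value)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "axial position z (mm)", y = NULL,
                  title = sprintf("Long-channel march: v = %g mm/s, L = %g mm",
                                  object$v, object$L)) +
    ggplot2::theme_minimal()
}

#' Plot a design-space sweep
#'
#' Volume ratio versus channel concentration, one line per wall permeability,
#' faceted by outer radius and preset. Infeasible cells are dropped (missing
#' points).
#'
#' @param object A `design_sweep` tibble from [volume_ratio_sweep()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot design_sweep
#' @export
autoplot.design_sweep <- function(object, ...) {
  df <- dplyr::filter(object, .data$feasible)
  df$Pi_label <- ifelse(is.infinite(df$Pi_w), "no wall",
                        paste0("Π = ", df$Pi_w, " mm/s"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$c_channel, y = .data$ratio,
                                   colour = .data$Pi_label)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$preset),
                        cols = ggplot2::vars(.data$R_w),
                        labeller = ggplot2::label_both, scales = "free_y") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "channel concentration (mol/m^3)",
                  y = "tissue / network volume ratio", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a radial sphere profile
#'
#' @param object A `radial_profile`.
#' @param c_H Optional hypoxic threshold drawn as a horizontal line.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot radial_profile
#' @export
autoplot.radial_profile <- function(object, c_H = NULL, ...) {
  p <- ggplot2::ggplot(object$profile, ggplot2::aes(x = .data$r, y = .data$c)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "radius (mm)", y = "concentration (mol/m^3)",
                  title = sprintf("Sphere R = %g mm, surface %g mol/m^3",
                                  object$R, object$c_surface)) +
    ggplot2::theme_minimal()
  if (!is.null(c_H)) {
    p <- p + ggplot2::geom_hline(yintercept = c_H, linetype = "dashed")
  }
  p
}
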