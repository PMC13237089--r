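# broom-style tidiers for fitted/design objects.

#' Tidy a design result
#'
#' @param x A `design_result` from [max_unit_size()].
#' @param ... Unused.
#' @return One-row tibble with the design variables and outcome.
#' @method tidy design_result
#' @export
tidy.design_result <- function(x, ...) {
  tibble(kind = x$kind, R_w = x$R_w, c_channel = x$c_channel, Pi_w = x$Pi_w,
         feasible = x$feasible, s_max = x$s_max, ratio = x$ratio,
         min_c = x$min_c, bracket = x$bracket)
}

#' @rdname tidy.design_result
#' @method glance design_result
#' @export
glance.design_result <- function(x, ...) {
  tibble(feasible = x$feasible, s_max = x$s_max, ratio = x$ratio,
         omega_t = x$omega_t, omega_net = x$omega_net)
}

#' Tidy a long-channel march
#'
#' @param x A `march_result` from [long_channel_march()].
#' @param ... Unused.
#' @return The per-element tibble (`element`, `z_in`, `c_wall`, `s`, `phi`,
#'   `min_c`, `collapsed`).
#' @method tidy march_result
#' @export
tidy.march_result <- function(x, ...) x$elements

#' @rdname tidy.march_result
#' @method glance march_result
#' @export
glance.march_result <- function(x, ...) {
  tibble(v = x$v, c_in = x$c_in, L = x$L, n_elem = x$n_elem, Q = x$Q,
         outlet_c = x$outlet_c, s_final = utils::tail(x$elements$s, 1),
         n_collapsed = sum(x$elements$collapsed),
         balance_residual = x$balance_residual)
}

#' Tidy a radial sphere profile
#'
#' @param x A `radial_profile` from [solve_sphere()].
#' @param ... Unused.
#' @method tidy radial_profile
#' @export
tidy.radial_profile <- function(x, ...) x$profile

#' @rdname tidy.radial_profile
#' @method glance radial_profile
#' @export
glance.radial_profile <- function(x, ...) {
  tibble(R = x$R, c_surface = x$c_surface, c_center = x$c_center,
         c_min = x$c_min, iterations = x$iterations)
}
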