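# Porous channel wall model: the cylindrical wall shell is never meshed in the
# tissue solves; it is collapsed into a single permeability coefficient Pi_w
# applied as a Robin condition at the outer radius R_w.

#' Channel cross-section specification
#'
#' @param R_c Inner (lumen) radius (mm).
#' @param t_w Wall thickness (mm); 0 in `no_wall` mode.
#' @param f_p Wall porosity (fraction of the wall cross-section occupied by
#'   medium-filled pores), in \[0, 1\].
#' @param wall_mode `"walled"` or `"no_wall"` (sacrificial-template channels;
#'   infinite wall permeability, Dirichlet coupling at the channel surface).
#' @return An object of class `channel_spec` with derived field `R_w = R_c + t_w`.
#' @export
channel_spec <- function(R_c, t_w = 0, f_p = 1,
                         wall_mode = if (t_w == 0) "no_wall" else "walled") {
  check_positive(R_c, "R_c")
  check_positive(t_w, "t_w", strict = FALSE)
  wall_mode <- match.arg(wall_mode, c("walled", "no_wall"))
  if (!is.numeric(f_p) || f_p < 0 || f_p > 1) {
    abort("`f_p` must lie in [0, 1].", class = "perfunet_validation_error")
  }
  if (wall_mode == "no_wall" && t_w != 0) {
    abort("`no_wall` mode requires t_w = 0.", class = "perfunet_geometry_error")
  }
  if (wall_mode == "walled" && t_w <= 0) {
    abort("`walled` mode requires t_w > 0.", class = "perfunet_geometry_error")
  }
  structure(list(R_c = R_c, t_w = t_w, R_w = R_c + t_w, f_p = f_p,
                 wall_mode = wall_mode),
            class = "channel_spec")
}

#' Effective diffusivity of a porous wall
#'
#' Linear superposition of the pore-medium and solid-material diffusivities,
#' appropriate for parallel disconnected pores: `D_w = f_p D_c + (1 - f_p) D_ws`.
#'
#' @param f_p Porosity in \[0, 1\].
#' @param D_c Diffusivity in the pore-filling medium (mm^2 s^-1).
#' @param D_ws Diffusivity in the solid wall material (mm^2 s^-1).
#' @return Effective wall diffusivity (mm^2 s^-1).
#' @export
effective_wall_diffusivity <- function(f_p, D_c, D_ws) {
  if (!is.numeric(f_p) || length(f_p) != 1L || is.na(f_p) || f_p < 0 || f_p > 1) {
    abort("`f_p` must lie in [0, 1].", class = "perfunet_validation_error")
  }
  f_p * D_c + (1 - f_p) * D_ws
}

#' Wall permeability of a cylindrical channel wall
#'
#' Collapses the radial diffusion problem through the wall shell into a single
#' coefficient `Pi_w = D_w / (R_w log(R_w / R_c))`; the denominator is the
#' logarithmic wall thickness, the effective thickness of a cylindrical shell
#' for radial diffusion. In `no_wall` mode the permeability is infinite and
#' callers must switch to Dirichlet coupling.
#'
#' @param spec A [channel_spec()].
#' @param D_w Effective wall diffusivity (mm^2 s^-1), e.g. from
#'   [effective_wall_diffusivity()].
#' @return Permeability (mm s^-1); `Inf` in `no_wall` mode.
#' @export
wall_permeability <- function(spec, D_w) {
  stopifnot(inherits(spec, "channel_spec"))
  if (spec$wall_mode == "no_wall") return(Inf)
  if (spec$R_w <= spec$R_c) {
    abort("Walled mode requires R_w > R_c.", class = "perfunet_geometry_error")
  }
  D_w / (spec$R_w * log(spec$R_w / spec$R_c))
}

#' Solute flux through the channel wall
#'
#' `J_w = (c_inner - c_outer) * Pi_w`, converted to SI flux units
#' (mm s^-1 times mol m^-3 gives 1e-3 mol m^-2 s^-1).
#'
#' @param c_inner,c_outer Concentrations at the inner and outer wall surface
#'   (mol m^-3).
#' @param Pi_w Wall permeability (mm s^-1); `Inf` signals Dirichlet coupling
#'   and returns `NA` (there is no finite flux law in that limit).
#' @return Flux (mol m^-2 s^-1), positive from lumen to tissue.
#' @export
wall_flux <- function(c_inner, c_outer, Pi_w) {
  if (is.infinite(Pi_w)) return(NA_real_)
  (c_inner - c_outer) * Pi_w * 1e-3
}

#' Analytic radial concentration profile across the wall
#'
#' The steady purely radial diffusion problem in the wall shell has the exact
#' solution `c(r) = A + B log(r)`; this returns the profile matching the two
#' boundary values, used to verify that the collapsed permeability reproduces
#' the resolved wall exactly.
#'
#' @param c_inner,c_outer Boundary concentrations (mol m^-3) at `R_c`, `R_w`.
#' @param spec A [channel_spec()] in walled mode.
#' @param n Number of radial sample points.
#' @return A tibble with columns `r` (mm) and `c` (mol m^-3), plus attribute
#'   `flux_outer` — the diffusive flux at `R_w` in mol m^-2 s^-1.
#' @export
radial_wall_profile <- function(c_inner, c_outer, spec, n = 101) {
  stopifnot(inherits(spec, "channel_spec"))
  if (spec$wall_mode != "walled" || spec$R_w <= spec$R_c) {
    abort("radial_wall_profile() needs a walled spec with R_w > R_c.",
          class = "perfunet_geometry_error")
  }
  r <- seq(spec$R_c, spec$R_w, length.out = n)
  B <- (c_outer - c_inner) / log(spec$R_w / spec$R_c)
  A <- c_inner - B * log(spec$R_c)
  out <- tibble(r = r, c = A + B * log(r))
  # flux at R_w for unit D_w: -D_w dc/dr|R_w = -D_w B / R_w; report per unit
  # D_w so callers can scale; also provide the closed form with D_w supplied
  attr(out, "dcdr_outer") <- B / spec$R_w
  out
}

#' Verify the collapsed-wall permeability against the resolved radial profile
#'
#' Computes the diffusive flux at the outer wall surface from the exact
#' logarithmic profile and compares it with `(c_inner - c_outer) * Pi_w`.
#'
#' @inheritParams radial_wall_profile
#' @param D_w Effective wall diffusivity (mm^2 s^-1).
#' @return A list with `flux_profile` and `flux_permeability`
#'   (both mol m^-2 s^-1).
#' @export
wall_flux_check <- function(c_inner, c_outer, spec, D_w) {
  prof <- radial_wall_profile(c_inner, c_outer, spec)
  dcdr <- attr(prof, "dcdr_outer")           # (mol m^-3) / mm
  flux_profile <- -D_w * dcdr * 1e-3         # mol m^-2 s^-1
  list(flux_profile = flux_profile,
       flux_permeability = wall_flux(c_inner, c_outer,
                                     wall_permeability(spec, D_w)))
}
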