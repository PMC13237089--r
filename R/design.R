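# Hypoxia-constrained design: the objective is to maximize the tissue
# compartment supplied above the hypoxic threshold per unit network volume.
# Because the minimum tissue concentration decreases monotonically with
# compartment size (comparison principle), the feasible sizes form an interval
# and bisection is exact; monotonicity is spot-checked before each bisection
# and a violation aborts with a diagnostic (it would indicate a solver bug).

# generic bisection for a monotone feasibility problem.
# f(s) returns list(feasible = logical, min_c = numeric, payload = ...)
bisect_max_feasible <- function(f, lo, hi_cap, tol, check_monotone = TRUE,
                                c_scale = 1, lo_min = NULL) {
  flo <- f(lo)
  while (!flo$feasible && !is.null(lo_min) && lo / 2 >= lo_min) {
    lo <- lo / 2
    flo <- f(lo)
  }
  if (!flo$feasible) {
    return(list(feasible = FALSE, s_max = NA_real_, bracket = NA_real_,
                eval_lo = flo, eval_hi = NULL))
  }
  hi <- lo
  fhi <- flo
  while (fhi$feasible && hi < hi_cap) {
    hi <- min(2 * hi, hi_cap)
    fhi <- f(hi)
  }
  if (fhi$feasible) {                 # feasible up to the cap
    return(list(feasible = TRUE, s_max = hi_cap, bracket = 0,
                capped = TRUE, eval_lo = fhi, eval_hi = NULL))
  }
  lo2 <- hi / 2                        # last feasible probe
  flo <- f(lo2)
  if (check_monotone) {
    mid <- sqrt(lo2 * hi)
    fmid <- f(mid)
    slack <- 1e-3 * c_scale
    certified <- !isTRUE(flo$early_stop) && !isTRUE(fmid$early_stop) &&
      !isTRUE(fhi$early_stop)
    if (certified &&
        (flo$min_c < fmid$min_c - slack || fmid$min_c < fhi$min_c - slack)) {
      abort(sprintf("Feasibility is not monotone in size (min c at %.4g/%.4g/%.4g mm: %.5g/%.5g/%.5g): solver inconsistency.",
                    lo2, mid, hi, flo$min_c, fmid$min_c, fhi$min_c),
            class = "perfunet_solver_error")
    }
    if (fmid$feasible) { lo2 <- mid; flo <- fmid } else { hi <- mid; fhi <- fmid }
  }
  while ((hi - lo2) > tol * lo2) {
    mid <- (lo2 + hi) / 2
    fm <- f(mid)
    if (fm$feasible) { lo2 <- mid; flo <- fm } else { hi <- mid; fhi <- fm }
  }
  list(feasible = TRUE, s_max = lo2, bracket = hi - lo2, capped = FALSE,
       eval_lo = flo, eval_hi = fhi)
}

#' Largest viable sphere diameter
#'
#' Bisects on the radius for the largest spherical tissue compartment whose
#' center concentration stays at or above the hypoxic threshold, given a fixed
#' surface concentration (negligible external diffusion resistance).
#'
#' @param c_surface Surface concentration (mol m^-3); must exceed `c_H`.
#' @param transport A [species_transport()].
#' @param tissue A [tissue_params()].
#' @param tol Relative bisection tolerance on the radius (default 1e-3).
#' @param n Radial cells per solve.
#' @return A one-row tibble: `d_max` (mm), `c_center` at `d_max`, `bracket`
#'   (mm, on the diameter).
#' @export
#' @examples
#' p <- load_preset("panelA")
#' max_sphere_diameter(1.0, p$transport, p$tissue)
max_sphere_diameter <- function(c_surface, transport, tissue, tol = 1e-3,
                                n = 400L) {
  if (c_surface <= tissue$c_H) {
    abort("Surface concentration must exceed the hypoxic threshold c_H.",
          class = "perfunet_validation_error")
  }
  f <- function(R) {
    sol <- solve_sphere(R, c_surface, transport, tissue, n = n)
    list(feasible = sol$c_min >= tissue$c_H, min_c = sol$c_min)
  }
  res <- bisect_max_feasible(f, lo = 0.05, hi_cap = 100, tol = tol,
                             c_scale = c_surface, lo_min = 1e-4)
  if (!res$feasible) {
    # even tiny spheres infeasible cannot happen for c_surface > c_H, but
    # keep the contract explicit
    abort("No feasible sphere found.", class = "perfunet_solver_error")
  }
  tibble(d_max = 2 * res$s_max, c_center = res$eval_lo$min_c,
         bracket = 2 * res$bracket)
}

#' Largest feasible honeycomb base unit
#'
#' Bisects on the cell edge length for the largest cuboid or
#' rhombic-dodecahedral base unit whose minimum tissue concentration stays at
#' or above the hypoxic threshold, with channels of outer radius `R_w` along
#' all cell edges. Cuboid cells exploit octant symmetry. Infeasibility (no
#' size above `2 R_w` satisfies the constraint) is returned as data, not an
#' error.
#'
#' @param kind `"cuboid"` or `"rhombic_dodecahedron"`.
#' @param R_w Outer channel radius (mm).
#' @param c_channel Concentration at/behind the channel surface (mol m^-3).
#' @param tissue A [tissue_params()].
#' @param transport A [species_transport()].
#' @param Pi_w Wall permeability (mm s^-1); `Inf` (default) is the no-wall
#'   (Dirichlet) limit.
#' @param tol Relative bisection tolerance on the edge (default 1e-2).
#' @param h Voxel spacing (mm); default `min(R_w/5, s/64)` per candidate size.
#' @param s_cap Upper bound on the edge length searched (mm).
#' @return A `design_result` (see [tidy.design_result()]): `s_max`, volume
#'   `ratio`, `min_c` at `s_max`, bisection `bracket`, `feasible`, parameter
#'   echo.
#' @export
max_unit_size <- function(kind = c("cuboid", "rhombic_dodecahedron"),
                          R_w, c_channel, tissue, transport,
                          Pi_w = Inf, tol = 1e-2, h = NULL, s_cap = 16) {
  kind <- match.arg(kind)
  if (c_channel <= tissue$c_H) {
    return(new_design_result(kind, R_w, c_channel, Pi_w, feasible = FALSE))
  }
  bc <- if (is.infinite(Pi_w)) {
    boundary_spec("dirichlet", c_channel)
  } else {
    boundary_spec("robin", c_channel, Pi_w)
  }
  geom_kind <- if (kind == "cuboid") "cuboid_octant" else kind
  c_max <- max(c_channel)
  f <- function(s) {
    hs <- h %||% min(R_w / 5, s / 64)
    cell <- make_unit_cell(geom_kind, s, R_w)
    grid <- suppressWarnings(voxelize(cell, hs))
    # feasibility can often be certified before Picard convergence: iterates
    # descend from a supersolution, so crossing 0.98 c_H settles
    # infeasibility, and clearing c_H by ten decaying updates settles
    # feasibility. Large grids get a nested start: the coarser-grid solution,
    # inflated 5% so it stays a pointwise upper bound.
    init <- NULL
    hc <- min(2 * hs, R_w / 2)
    if (sum(grid$tissue) > 3e5 && hc >= 1.5 * hs) {
      coarse <- suppressWarnings(voxelize(cell, hc))
      cfld <- solve_steady_mm(coarse, NULL, transport, tissue, bc,
                              stop_below = 0.98 * tissue$c_H,
                              stop_above = tissue$c_H)
      if (cfld$early_stop != 1) {
        init <- pmin(upsample_field(cfld$values, coarse, grid) +
                       0.05 * c_max, c_max)
      }
    }
    fld <- solve_steady_mm(grid, NULL, transport, tissue, bc,
                           stop_below = 0.98 * tissue$c_H,
                           stop_above = tissue$c_H, init = init)
    st <- field_stats(fld, tissue$c_H)
    list(feasible = fld$early_stop == 2 ||
           (fld$early_stop == 0 && st$min >= tissue$c_H),
         min_c = st$min,
         early_stop = fld$early_stop != 0)
  }
  # rigorous upper bound on the feasible size from the comparison principle:
  # the cell center, at distance d(size) from the nearest channel axis, sees
  # less supply than the center of a sphere of radius d - R_w whose whole
  # surface is held at c_channel. Sizes whose center distance exceeds the
  # feasible sphere radius (plus R_w) are infeasible, which caps the
  # bracket-growth phase cheaply via the 1D sphere solve.
  R_sph <- max_sphere_diameter(c_channel, transport, tissue, tol = 1e-2)$d_max / 2
  center_dist_factor <- if (kind == "cuboid") 1 / sqrt(2) else 2 * sqrt(2) / 3
  s_bound <- (R_sph + R_w) / center_dist_factor
  lo <- 2 * R_w * 1.1
  res <- bisect_max_feasible(f, lo = lo, hi_cap = min(s_cap, 1.05 * s_bound),
                             tol = tol, c_scale = c_channel)
  if (!res$feasible) {
    return(new_design_result(kind, R_w, c_channel, Pi_w, feasible = FALSE))
  }
  s_max <- res$s_max
  # post-hoc verification: converged solve at the returned size (the
  # bisection itself may have certified feasibility from an early exit)
  hs <- h %||% min(R_w / 5, s_max / 64)
  vgrid <- suppressWarnings(voxelize(make_unit_cell(geom_kind, s_max, R_w), hs))
  vfld <- solve_steady_mm(vgrid, NULL, transport, tissue, bc)
  vmin <- field_stats(vfld, tissue$c_H)$min
  if (vmin < tissue$c_H) {
    warn(sprintf("Returned size %.4g mm re-verifies marginally infeasible (min c = %.4g); within bisection tolerance.",
                 s_max, vmin))
  }
  vol <- measure_volumes(suppressWarnings(
    voxelize(make_unit_cell(kind, s_max, R_w), hs)
  ))
  new_design_result(kind, R_w, c_channel, Pi_w, feasible = TRUE,
                    s_max = s_max, ratio = vol$ratio,
                    omega_t = vol$omega_t, omega_net = vol$omega_net,
                    min_c = vmin, bracket = res$bracket,
                    capped = isTRUE(res$capped))
}

new_design_result <- function(kind, R_w, c_channel, Pi_w, feasible,
                              s_max = NA_real_, ratio = NA_real_,
                              omega_t = NA_real_, omega_net = NA_real_,
                              min_c = NA_real_, bracket = NA_real_,
                              capped = FALSE) {
  structure(list(kind = kind, R_w = R_w, c_channel = c_channel, Pi_w = Pi_w,
                 feasible = feasible, s_max = s_max, ratio = ratio,
                 omega_t = omega_t, omega_net = omega_net, min_c = min_c,
                 bracket = bracket, capped = capped),
            class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  if (x$feasible) {
    cat(sprintf("%s unit, R_w = %g mm, c = %g: s_max = %.4g mm, ratio = %.3g, min c = %.4g\n",
                x$kind, x$R_w, x$c_channel, x$s_max, x$ratio, x$min_c))
  } else {
    cat(sprintf("%s unit, R_w = %g mm, c = %g: infeasible (no size above 2 R_w)\n",
                x$kind, x$R_w, x$c_channel))
  }
  invisible(x)
}

#' Sweep the design space of honeycomb base units
#'
#' Cartesian product of channel concentrations, outer radii, wall
#' permeabilities and parameter presets; each combination is maximized with
#' [max_unit_size()]. Infeasible combinations are recorded as rows with
#' `feasible = FALSE` (missing points), never raised as errors.
#'
#' @param c_list Channel concentrations (mol m^-3).
#' @param R_w_list Outer radii (mm).
#' @param Pi_list Wall permeabilities (mm s^-1); `Inf` = no wall.
#' @param preset_list Preset names (see [preset_names()]) or a named list of
#'   parameter sets as returned by [load_preset()].
#' @param kind Base-unit kind.
#' @param ... Passed to [max_unit_size()] (`tol`, `h`, `s_cap`).
#' @return A `design_sweep` tibble: one row per combination with columns
#'   `preset`, `c_channel`, `R_w`, `Pi_w`, `feasible`, `s_max`, `ratio`,
#'   `min_c`.
#' @export
volume_ratio_sweep <- function(c_list, R_w_list, Pi_list, preset_list,
                               kind = "cuboid", ...) {
  stopifnot(length(c_list) > 0, length(R_w_list) > 0,
            length(Pi_list) > 0, length(preset_list) > 0)
  presets <- if (is.character(preset_list)) {
    setNames(lapply(preset_list, load_preset), preset_list)
  } else {
    preset_list
  }
  cases <- tidyr::expand_grid(preset = names(presets), c_channel = c_list,
                              R_w = R_w_list, Pi_w = Pi_list)
  rows <- purrr::pmap(cases, function(preset, c_channel, R_w, Pi_w) {
    p <- presets[[preset]]
    r <- max_unit_size(kind, R_w, c_channel, p$tissue, p$transport,
                       Pi_w = Pi_w, ...)
    tibble(preset = preset, c_channel = c_channel, R_w = R_w, Pi_w = Pi_w,
           feasible = r$feasible, s_max = r$s_max, ratio = r$ratio,
           min_c = r$min_c)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("design_sweep", class(out))
  out
}

#' Axial marching procedure for a long supply channel
#'
#' A straight channel of length `L` through tissue is split into `n_elem`
#' axial elements. For each element, the cross-section edge is maximized under
#' the hypoxia constraint at the current channel concentration
#' ([solve_cross_section()]); the resulting wall flux depletes the channel via
#' the axial mean-concentration balance
#' `c[j+1] = c[j] - Phi[j] (L/n) / Q`, with `Q = pi R_c^2 v`. When no
#' cross-section above `2 R_w` is feasible the edge collapses to the
#' degenerate bound and the march continues (flux from the residual corner
#' tissue only).
#'
#' @param v Mean channel velocity (mm s^-1).
#' @param c_in Inlet concentration (mol m^-3); must exceed `c_H`.
#' @param L Channel length (mm).
#' @param n_elem Number of axial elements (>= 2).
#' @param spec A [channel_spec()].
#' @param transport,tissue Parameter objects.
#' @param tol Relative bisection tolerance on the edge (default 1e-3).
#' @param s_cap Maximum edge length considered (mm, default 3).
#' @param h Cross-section voxel spacing (mm); default `R_w / 5`.
#' @return A `march_result`: per-element tibble (`element`, `z_in` mm,
#'   `c_wall` entering concentration, `s` feasible edge, `phi` wall flux per
#'   length in mol m^-1 s^-1, `min_c`, `collapsed`), the inputs, the outlet
#'   concentration and the global solute balance residual.
#' @export
long_channel_march <- function(v, c_in, L, n_elem, spec, transport, tissue,
                               tol = 1e-3, s_cap = 3, h = NULL) {
  if (v <= 0) {
    abort("Mean velocity must be positive.",
          class = "perfunet_validation_error")
  }
  if (c_in <= tissue$c_H) {
    abort("Inlet concentration must exceed the hypoxic threshold.",
          class = "perfunet_validation_error")
  }
  stopifnot(n_elem >= 2, inherits(spec, "channel_spec"))
  R_w <- spec$R_w
  R_c <- spec$R_c
  Q <- pi * R_c^2 * v                     # mm^3 s^-1
  dz <- L / n_elem
  s_lo <- 2 * R_w * 1.02                  # degenerate bound

  solve_xs <- function(s, c_wall, probe = FALSE) {
    solve_cross_section(s, spec, c_wall, NULL, transport, tissue, h = h,
                        stop_below = if (probe) 0.98 * tissue$c_H else NULL)
  }
  elements <- vector("list", n_elem)
  c_j <- c_in
  s_prev <- s_cap     # feasible edges are non-increasing along the channel
  for (j in seq_len(n_elem)) {
    collapsed <- FALSE
    if (c_j <= tissue$c_H) {
      xs <- if (c_j > 0) solve_xs(s_lo, c_j) else NULL
      s_j <- s_lo
      collapsed <- TRUE
    } else {
      f <- function(s) {
        sol <- solve_xs(s, c_j, probe = TRUE)
        list(feasible = sol$early_stop == 0 && sol$min >= tissue$c_H,
             min_c = sol$min, early_stop = sol$early_stop != 0, sol = sol)
      }
      res <- bisect_max_feasible(f, lo = max(s_lo, 0.7 * s_prev),
                                 hi_cap = min(s_cap, s_prev), tol = tol,
                                 check_monotone = FALSE, c_scale = c_in,
                                 lo_min = s_lo)
      if (!res$feasible) {
        s_j <- s_lo
        collapsed <- TRUE
        xs <- solve_xs(s_lo, c_j)
      } else {
        s_j <- res$s_max
        xs <- res$eval_lo$sol
      }
    }
    s_prev <- s_j
    phi_internal <- if (is.null(xs)) 0 else xs$phi * 1e6  # (mol m^-3) mm^2 s^-1
    elements[[j]] <- tibble(
      element = j, z_in = (j - 1) * dz, c_wall = c_j, s = s_j,
      phi = if (is.null(xs)) 0 else xs$phi,
      min_c = if (is.null(xs)) NA_real_ else xs$min,
      collapsed = collapsed
    )
    c_j <- max(c_j - phi_internal * dz / Q, 0)
  }
  el <- dplyr::bind_rows(elements)
  outlet <- c_j
  total_flux <- sum(el$phi) * 1e6 * dz          # (mol m^-3) mm^3 s^-1
  balance_residual <- abs(Q * (c_in - outlet) - total_flux) /
    max(Q * c_in, 1e-300)
  structure(list(elements = el, v = v, c_in = c_in, L = L, n_elem = n_elem,
                 Q = Q, R_c = R_c, R_w = R_w, outlet_c = outlet,
                 balance_residual = balance_residual,
                 s_cap = s_cap),
            class = "march_result")
}

#' @export
print.march_result <- function(x, ...) {
  cat(sprintf("Long-channel march: L = %g mm, %d elements, v = %g mm/s\n",
              x$L, x$n_elem, x$v))
  cat(sprintf("  inlet c = %g, outlet c = %.4g mol/m^3; final edge %.4g mm\n",
              x$c_in, x$outlet_c, utils::tail(x$elements$s, 1)))
  invisible(x)
}


# nearest-neighbour interpolation of a coarse voxel field onto a finer grid
# sharing the same origin; NA (non-tissue) coarse values take the coarse
# field's maximum so the result stays a supersolution near channels
upsample_field <- function(values, coarse, fine) {
  vmax <- max(values, na.rm = TRUE)
  values[is.na(values)] <- vmax
  map1 <- function(nf, hf, nc, hc) {
    pmin(pmax(ceiling(((seq_len(nf) - 0.5) * hf) / hc), 1L), nc)
  }
  ix <- map1(fine$shape[1], fine$h, coarse$shape[1], coarse$h)
  iy <- map1(fine$shape[2], fine$h, coarse$shape[2], coarse$h)
  iz <- map1(fine$shape[3], fine$h, coarse$shape[3], coarse$h)
  values[ix, iy, iz, drop = FALSE]
}
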