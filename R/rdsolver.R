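# Steady Michaelis-Menten reaction-diffusion solves.
#
# The channel lumen (and wall) is never meshed: channel voxels enter the
# tissue solve only through face transmissibilities -- a Dirichlet ghost value
# in no-wall mode, or a Robin coefficient (wall permeability in series with
# the half-cell tissue resistance) in walled mode. Blocked channel surfaces
# are no-flux. All outer grid faces are symmetry planes (no-flux).

#' Boundary coupling for channel surfaces
#'
#' @param condition `"dirichlet"` (fixed concentration at the channel surface;
#'   the no-wall / sacrificial-template limit) or `"robin"` (flux =
#'   `Pi_w * (c_channel - c_tissue)` across the wall).
#' @param c_channel Channel concentration (mol m^-3); a scalar, or a vector
#'   indexed by channel segment id.
#' @param Pi_w Wall permeability (mm s^-1), required for `"robin"`.
#' @return A `boundary_spec`.
#' @export
boundary_spec <- function(condition = c("dirichlet", "robin"),
                          c_channel, Pi_w = Inf) {
  condition <- match.arg(condition)
  if (condition == "robin") {
    check_positive(Pi_w, "Pi_w")
    if (is.infinite(Pi_w)) condition <- "dirichlet"
  }
  if (any(c_channel < 0)) {
    abort("Channel concentrations must be non-negative.",
          class = "perfunet_validation_error")
  }
  structure(list(condition = condition, c_channel = c_channel, Pi_w = Pi_w),
            class = "boundary_spec")
}

# per-voxel uptake capacity (mol m^-3 s^-1) from a density field or uniform rho
uptake_array <- function(grid, density, tissue) {
  if (is.null(density)) {
    q <- array(uptake_capacity(tissue), dim = grid$shape)
  } else if (inherits(density, "density_field")) {
    stopifnot(all(dim(density$values) == grid$shape))
    q <- density$values * tissue$k_ocr * 1e9
  } else if (is.numeric(density) && length(density) == 1L) {
    q <- array(density * tissue$k_ocr * 1e9, dim = grid$shape)
  } else {
    stopifnot(all(dim(density) == grid$shape))
    q <- density * tissue$k_ocr * 1e9
  }
  q[!grid$tissue] <- 0
  q
}

# cell-type / bc-value arrays for the compiled kernel
bc_arrays <- function(grid, bc) {
  ct <- array(0L, dim = grid$shape)
  ct[grid$tissue] <- 1L
  chan_code <- if (bc$condition == "dirichlet") 2L else 3L
  ct[grid$channel] <- chan_code
  blocked_ids <- grid$cell$segments$id[grid$cell$segments$blocked]
  if (length(blocked_ids)) {
    ct[grid$channel & grid$seg_id %in% blocked_ids] <- 4L
  }
  bv <- array(0, dim = grid$shape)
  if (length(bc$c_channel) == 1L) {
    bv[grid$channel] <- bc$c_channel
  } else {
    bv[grid$channel] <- bc$c_channel[grid$seg_id[grid$channel]]
  }
  list(cell_type = ct, bc_value = bv)
}

#' Solve the steady reaction-diffusion problem on a voxel grid
#'
#' 7-point finite-volume discretization of the steady diffusion equation with
#' Michaelis-Menten sink `rho_T k_ocr c / (k_m + c)`. The concave sink is
#' Newton-linearized; starting from the boundary maximum the outer iterates
#' descend monotonically to the solution (so they stay bounded and
#' non-negative) and converge quadratically. Each step is a
#' multigrid-preconditioned conjugate-gradient solve of a symmetric
#' positive-definite system. The discrete maximum principle (no interior value
#' above the largest channel concentration, none below zero) is asserted on
#' every solve.
#'
#' @param grid A `voxel_grid` from [voxelize()].
#' @param density `NULL` (uniform `tissue$rho_T`), a scalar density, a
#'   [correlated_density_field()] or an array (cells mm^-3).
#' @param transport A [species_transport()].
#' @param tissue A [tissue_params()].
#' @param bc A [boundary_spec()].
#' @param picard_tol Relative-update convergence threshold for the outer
#'   (nonlinear) iteration (default 1e-6).
#' @param picard_max Maximum outer iterations (default 200).
#' @param cg_tol Relative residual for the inner linear solves (default 1e-10).
#' @param relax Outer-iteration under-relaxation factor in (0, 1\]; 1 = none.
#' @param stop_below,stop_above Optional early-exit thresholds (mol m^-3)
#'   used by the design bisections: because the outer iterates descend
#'   monotonically from a pointwise supersolution, an iterate falling below
#'   `stop_below` certifies the converged minimum does too
#'   (`early_stop = 1`), and once updates decay geometrically a minimum still
#'   clearing `stop_above` by ten updates certifies feasibility
#'   (`early_stop = 2`). The returned field is then a bounded iterate, not a
#'   converged solution. `NULL` disables either exit.
#' @param init Optional initial field (array of the grid's shape, e.g. an
#'   interpolated coarse solution). To preserve the early-exit certificates
#'   it must be a pointwise upper bound of the solution.
#' @return A `concentration_field`: `values` (mol m^-3, `NA` outside tissue),
#'   the grid, convergence record, and the integral boundary `influx` and
#'   metabolic `consumption` (both mol s^-1).
#' @export
solve_steady_mm <- function(grid, density, transport, tissue, bc,
                            picard_tol = 1e-6, picard_max = 200L,
                            cg_tol = 1e-10, relax = 1, stop_below = NULL,
                            stop_above = NULL, init = NULL) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(bc, "boundary_spec"),
            inherits(transport, "species_transport"),
            inherits(tissue, "tissue_params"))
  arrs <- bc_arrays(grid, bc)
  q <- uptake_array(grid, density, tissue)
  c_max_bc <- max(bc$c_channel)
  res <- fv_solve_mm(
    dims = as.integer(grid$shape),
    cell_type = as.integer(arrs$cell_type),
    bc_value = as.numeric(arrs$bc_value),
    robin_pi = if (bc$condition == "robin") bc$Pi_w else Inf,
    q = as.numeric(q),
    k_m = tissue$k_m, D_t = transport$D_t, h = grid$h,
    c_init = c_max_bc,
    picard_tol = picard_tol, picard_max = as.integer(picard_max),
    cg_tol = cg_tol, cg_max = 100000L, relax = relax,
    stop_below = stop_below %||% -1,
    stop_above = stop_above %||% -1,
    init_field = if (is.null(init)) numeric(0) else as.numeric(init)
  )
  if (!res$converged) {
    abort(paste0("Picard iteration did not converge in ", picard_max,
                 " iterations; final relative update ",
                 format(res$final_update), ". Update history: ",
                 paste(signif(utils::tail(res$update_history, 8), 3),
                       collapse = ", ")),
          class = "perfunet_solver_error")
  }
  vals <- array(res$c, dim = grid$shape)
  finite <- vals[!is.na(vals)]
  if (!res$early_stop && min(finite) < -1e-10 * max(c_max_bc, 1)) {
    abort("Solver produced negative concentrations beyond round-off.",
          class = "perfunet_solver_error")
  }
  if (max(finite) > c_max_bc * (1 + 1e-8)) {
    abort("Discrete maximum principle violated: interior concentration above the boundary maximum.",
          class = "perfunet_solver_error")
  }
  structure(list(values = vals, grid = grid,
                 iterations = res$picard_iterations,
                 final_update = res$final_update,
                 update_history = res$update_history,
                 early_stop = res$early_stop,
                 influx = res$influx * 1e-9,        # mol s^-1
                 consumption = res$consumption * 1e-9),
            class = "concentration_field")
}

#' Summary statistics of a concentration field over the tissue mask
#'
#' @param field A `concentration_field`, or a numeric array/vector.
#' @param c_H Hypoxic threshold (mol m^-3).
#' @param mask Optional logical mask (required when `field` is a bare array).
#' @return A tibble with `min`, `mean` and `hypoxic_fraction` (fraction of
#'   tissue voxels below `c_H`).
#' @export
field_stats <- function(field, c_H, mask = NULL) {
  if (inherits(field, "concentration_field")) {
    v <- field$values[field$grid$tissue]
  } else if (inherits(field, "cross_section_field")) {
    v <- field$values[field$tissue]
  } else {
    if (is.null(mask)) {
      v <- as.numeric(field)
    } else {
      v <- as.numeric(field)[as.logical(mask)]
    }
  }
  v <- v[!is.na(v)]
  if (!length(v)) {
    abort("Empty tissue mask.", class = "perfunet_validation_error")
  }
  tibble(min = min(v), mean = mean(v), hypoxic_fraction = mean(v < c_H))
}

#' Solve the spherical tissue-compartment problem
#'
#' Steady reaction-diffusion in a sphere of radius `R` with a fixed surface
#' concentration and symmetry at the center:
#' `D_t (1/r^2) d/dr(r^2 dc/dr) = rho_T k_ocr c / (k_m + c)`.
#' Radial finite volumes with exact spherical face areas; the Michaelis-Menten
#' sink is Picard-linearized and each step is a tridiagonal (Thomas) solve.
#'
#' @param R Sphere radius (mm).
#' @param c_surface Surface concentration (mol m^-3).
#' @param transport A [species_transport()].
#' @param tissue A [tissue_params()].
#' @param n Number of radial cells (default 400).
#' @param picard_tol,picard_max Picard convergence controls.
#' @return A `radial_profile`: tibble `profile` (`r` mm, `c` mol m^-3),
#'   `c_center`, `c_min`, convergence record.
#' @export
solve_sphere <- function(R, c_surface, transport, tissue, n = 400L,
                         picard_tol = 1e-8, picard_max = 200L) {
  check_positive(R, "R")
  check_positive(c_surface, "c_surface", strict = FALSE)
  h <- R / n
  rf <- (0:n) * h                    # faces
  rc <- (seq_len(n) - 0.5) * h       # centers
  A <- rf^2                          # face areas / 4pi
  V <- diff(rf^3) / 3                # cell volumes / 4pi
  D <- transport$D_t
  Tlo <- D * A[1:n] / h              # face below cell i (A[1] = 0: symmetry)
  Thi <- D * A[2:(n + 1)] / h
  Thi[n] <- D * A[n + 1] / (h / 2)   # Dirichlet ghost at the surface
  q <- uptake_capacity(tissue)
  km <- tissue$k_m

  c_old <- rep(c_surface, n)
  converged <- FALSE
  iter <- 0L
  for (it in seq_len(picard_max)) {
    iter <- it
    sink_diag <- V * q / (km + pmax(c_old, 0))
    a <- -Tlo[2:n]                       # sub-diagonal (face between i-1, i)
    b <- Tlo + Thi + sink_diag           # diagonal
    cc <- -Thi[1:(n - 1)]                # super-diagonal
    d <- c(rep(0, n - 1), Thi[n] * c_surface)
    # Thomas algorithm
    cp <- numeric(n - 1); dp <- numeric(n)
    cp[1] <- cc[1] / b[1]; dp[1] <- d[1] / b[1]
    for (i in 2:n) {
      m <- b[i] - a[i - 1] * cp[i - 1]
      if (i <= n - 1) cp[i] <- cc[i] / m
      dp[i] <- (d[i] - a[i - 1] * dp[i - 1]) / m
    }
    c_new <- numeric(n)
    c_new[n] <- dp[n]
    for (i in (n - 1):1) c_new[i] <- dp[i] - cp[i] * c_new[i + 1]
    upd <- max(abs(c_new - c_old)) / max(max(abs(c_new)), 1e-300)
    c_old <- c_new
    if (upd < picard_tol) { converged <- TRUE; break }
  }
  if (!converged) {
    abort("Sphere solve did not converge.", class = "perfunet_solver_error")
  }
  structure(list(profile = tibble(r = rc, c = c_old),
                 R = R, c_surface = c_surface,
                 c_center = c_old[1], c_min = min(c_old),
                 iterations = iter),
            class = "radial_profile")
}

#' Solve a channel cross-section element
#'
#' Square tissue cross-section of edge `s` with a centered circular channel of
#' outer radius `R_w`; by symmetry only one quarter is solved (channel quarter
#' in one corner, no-flux on all four sides). Coupling at the channel surface
#' is Dirichlet in `no_wall` mode, Robin with the collapsed wall permeability
#' otherwise. This is the axial element of the long-channel marching
#' procedure.
#'
#' @param s Full cross-section edge length (mm); must exceed `2 R_w`.
#' @param spec A [channel_spec()].
#' @param c_wall Channel concentration (mol m^-3) imposed at (Dirichlet) or
#'   behind (Robin) the channel surface.
#' @param density `NULL` for uniform `tissue$rho_T`, or a scalar.
#' @param transport A [species_transport()].
#' @param tissue A [tissue_params()].
#' @param h Voxel spacing (mm); default `R_w / 5`.
#' @param stop_below Optional certified infeasibility threshold; see
#'   [solve_steady_mm()].
#' @param ... Passed to the Picard iteration (`picard_tol`, `relax`, ...).
#' @return A `cross_section_field`: `values` matrix over the quarter domain,
#'   tissue mask, `min`/`mean` tissue concentration, and `phi` -- the wall
#'   flux per unit channel length of the full cross-section (mol m^-1 s^-1);
#'   `consumption_per_length` gives the integral metabolic sink in the same
#'   units for conservation checks.
#' @export
solve_cross_section <- function(s, spec, c_wall, density = NULL,
                                transport, tissue, h = NULL,
                                stop_below = NULL, stop_above = NULL, ...) {
  stopifnot(inherits(spec, "channel_spec"))
  R_w <- spec$R_w
  if (s <= 2 * R_w) {
    abort("Cross-section edge s must exceed 2*R_w.",
          class = "perfunet_geometry_error")
  }
  if (is.null(h)) h <- R_w / 5
  nq <- max(3L, as.integer(round((s / 2) / h)))
  hh <- (s / 2) / nq                  # exact half-edge discretization
  cx <- (seq_len(nq) - 0.5) * hh
  X <- matrix(cx, nq, nq)
  Y <- matrix(cx, nq, nq, byrow = TRUE)
  in_channel <- (X^2 + Y^2) < R_w^2
  ct <- matrix(1L, nq, nq)
  dirichlet <- spec$wall_mode == "no_wall"
  ct[in_channel] <- if (dirichlet) 2L else 3L
  if (!any(ct == 1L)) {
    abort("Degenerate cross-section: no tissue voxels.",
          class = "perfunet_geometry_error")
  }
  Pi_w <- if (dirichlet) Inf else
    wall_permeability(spec, effective_wall_diffusivity(spec$f_p, transport$D_c,
                                                       transport$D_ws))
  rho <- if (is.null(density)) tissue$rho_T else density
  q <- matrix(0, nq, nq)
  q[ct == 1L] <- rho * tissue$k_ocr * 1e9
  dots <- list(...)
  res <- fv_solve_mm(
    dims = c(nq, nq, 1L),
    cell_type = as.integer(ct),
    bc_value = as.numeric(matrix(c_wall, nq, nq)),
    robin_pi = Pi_w,
    q = as.numeric(q),
    k_m = tissue$k_m, D_t = transport$D_t, h = hh,
    c_init = c_wall,
    picard_tol = dots$picard_tol %||% 1e-8,
    picard_max = as.integer(dots$picard_max %||% 200L),
    cg_tol = dots$cg_tol %||% 1e-10, cg_max = 100000L,
    relax = dots$relax %||% 1,
    stop_below = stop_below %||% -1,
    stop_above = stop_above %||% -1,
    init_field = numeric(0)
  )
  if (!res$converged) {
    abort("Cross-section solve did not converge.",
          class = "perfunet_solver_error")
  }
  vals <- matrix(res$c, nq, nq)
  tis <- ct == 1L
  v <- vals[tis]
  # quarter-slab fluxes -> full cross-section, per unit channel length;
  # (mol m^-3) mm^3 s^-1 / mm = 1e-6 mol m^-1 s^-1
  phi <- 4 * res$influx / hh * 1e-6
  cons <- 4 * res$consumption / hh * 1e-6
  structure(list(values = vals, tissue = tis, h = hh, s = s, R_w = R_w,
                 min = min(v), mean = mean(v),
                 phi = phi, consumption_per_length = cons,
                 early_stop = res$early_stop,
                 iterations = res$picard_iterations),
            class = "cross_section_field")
}

#' @export
print.concentration_field <- function(x, ...) {
  st <- field_stats(x, c_H = NA)
  cat(sprintf("Concentration field: %d tissue voxels, min %.4g, mean %.4g mol/m^3 (%d Picard iterations)\n",
              sum(x$grid$tissue), st$min, st$mean, x$iterations))
  invisible(x)
}

#' Concentration field as a voxel tibble
#'
#' @param x A `concentration_field`.
#' @param ... Unused.
#' @return Tibble with voxel indices, center coordinates (mm) and
#'   concentration (tissue voxels only).
#' @method as_tibble concentration_field
#' @export
as_tibble.concentration_field <- function(x, ...) {
  g <- x$grid
  keep <- which(g$tissue)
  idx <- arrayInd(keep, .dim = g$shape)
  tibble(
    i = idx[, 1], j = idx[, 2], k = idx[, 3],
    x = g$origin[1] + (idx[, 1] - 0.5) * g$h,
    y = g$origin[2] + (idx[, 2] - 0.5) * g$h,
    z = g$origin[3] + (idx[, 3] - 0.5) * g$h,
    c = x$values[keep]
  )
}
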