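# Steady Michaelis-Menten reaction-diffusion solves: closed-form oracles,
# bracketing, boundary-condition limits and statistics.

test_that("a reaction-free solve returns the boundary concentration everywhere", {
  tiny_rho <- tissue_params(1e-6, 1e-16, 0.028, 0.05)  # effectively no sink
  fld <- octant_solve(0.4, 0.05, 0.2, list(transport = panelA$transport,
                                           tissue = tiny_rho))
  st <- field_stats(fld, 0.05)
  expect_equal(st$min, 0.2, tolerance = 1e-6)
  expect_equal(st$mean, 0.2, tolerance = 1e-6)
  expect_equal(st$hypoxic_fraction, 0)
})

test_that("the 1D slab solve matches the zeroth-order closed form", {
  # Dirichlet c0 at x = 0, no-flux at x = w: c(x) = c0 - q/(2D) (2wx - x^2)
  c0 <- 1.0; w <- 0.3; D <- 2e-3
  tz <- zeroth_tissue()
  q <- q_of(tz)
  nx <- 60L; h <- w / nx
  ct <- array(1L, dim = c(nx + 1L, 1L, 1L)); ct[1, 1, 1] <- 2L
  bv <- array(0, dim = dim(ct)); bv[1, 1, 1] <- c0
  qa <- array(q, dim = dim(ct)); qa[1, 1, 1] <- 0
  r <- perfunet:::fv_solve_mm(dim(ct), as.integer(ct), as.numeric(bv), Inf,
                              as.numeric(qa), tz$k_m, D, h, c0,
                              1e-8, 500L, 1e-12, 100000L, 1, -1, -1,
                              numeric(0))
  x <- (seq_len(nx) - 0.5) * h
  exact <- c0 - q / (2 * D) * (2 * w * x - x^2)
  expect_lt(max(abs(r$c[-1] - exact) / exact), 0.005)
})

test_that("the sphere solve matches the zeroth-order deficit and orderings", {
  p <- panelA
  # no reaction
  flat <- solve_sphere(0.5, 0.7, p$transport,
                       tissue_params(1e-6, 1e-16, 0.028, 0.05))
  expect_equal(flat$c_center, 0.7, tolerance = 1e-8)
  # zeroth-order limit: center deficit q R^2 / (6 D) = 1.667 R^2 for panelA
  tz <- zeroth_tissue()
  for (R in c(0.3, 0.5)) {
    sol <- solve_sphere(R, 1.0, p$transport, tz)
    expect_equal(1.0 - sol$c_center, q_of(tz) * R^2 / (6 * 2e-3),
                 tolerance = 0.005)
  }
  # comparison principle: center value decreases with radius
  centers <- vapply(c(0.3, 0.45, 0.6),
                    function(R) solve_sphere(R, 1.0, p$transport,
                                             p$tissue)$c_center, numeric(1))
  expect_true(all(diff(centers) < 0))
  # grid convergence of the radial scheme is second order
  ref <- solve_sphere(0.5, 1.0, p$transport, p$tissue, n = 3200)$c_center
  errs <- vapply(c(50, 100, 200),
                 function(n) abs(solve_sphere(0.5, 1.0, p$transport, p$tissue,
                                              n = n)$c_center - ref),
                 numeric(1))
  order_est <- log2(errs[1] / errs[3]) / 2
  expect_gt(order_est, 1.7)
})

test_that("cross-section wall flux balances the metabolic consumption", {
  spec <- channel_spec(0.05)
  xs <- solve_cross_section(0.5, spec, 1.0, NULL, panelA$transport,
                            panelA$tissue)
  expect_equal(xs$phi, xs$consumption_per_length, tolerance = 0.01)
  expect_gt(xs$phi, 0)
  # no cells: uniform field, no flux
  xs0 <- solve_cross_section(0.5, spec, 1.0, 1e-9, panelA$transport,
                             panelA$tissue)
  expect_equal(xs0$min, 1.0, tolerance = 1e-8)
  expect_lt(abs(xs0$phi), 1e-12)
})

test_that("the MM solution is bracketed by zeroth-order and no-reaction", {
  p <- panelA
  mm <- octant_solve(0.4, 0.05, 0.3, p, h = 0.0125)
  zo <- octant_solve(0.4, 0.05, 0.3,
                     list(transport = p$transport, tissue = zeroth_tissue()),
                     h = 0.0125)
  sel <- !is.na(mm$values)
  expect_true(all(mm$values[sel] >= zo$values[sel] - 1e-8))
  expect_true(all(mm$values[sel] <= 0.3 + 1e-10))  # no-reaction bound
})

test_that("Robin solutions approach the Dirichlet limit monotonically", {
  p <- panelA
  grid <- suppressWarnings(voxelize(make_unit_cell("cuboid_octant", 0.4, 0.05),
                                    0.0125))
  dirichlet <- solve_steady_mm(grid, NULL, p$transport, p$tissue,
                               boundary_spec("dirichlet", 0.3))
  sup_gap <- vapply(c(0.05, 5, 500), function(Pi) {
    rob <- solve_steady_mm(grid, NULL, p$transport, p$tissue,
                           boundary_spec("robin", 0.3, Pi))
    max(abs(rob$values - dirichlet$values), na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(sup_gap) < 0))
  expect_lt(sup_gap[3], 1e-3)
  # Robin solution sits below Dirichlet (extra wall resistance)
  rob <- solve_steady_mm(grid, NULL, p$transport, p$tissue,
                         boundary_spec("robin", 0.3, 0.1))
  sel <- !is.na(rob$values)
  expect_true(all(rob$values[sel] <= dirichlet$values[sel] + 1e-10))
})

test_that("discrete conservation and the maximum principle hold in 3D", {
  fld <- octant_solve(0.5, 0.05, 0.2, panelA, h = 0.01)
  expect_equal(fld$influx, fld$consumption, tolerance = 0.01)
  vals <- fld$values[!is.na(fld$values)]
  expect_lte(max(vals), 0.2)
  expect_gte(min(vals), 0)
})

test_that("a blocked channel produces a hypoxic region behind it", {
  p <- panelA
  cell <- make_unit_cell("cuboid", 0.5, 0.05)
  open_grid <- suppressWarnings(voxelize(cell, 0.0125))
  open_fld <- solve_steady_mm(open_grid, NULL, p$transport, p$tissue,
                              boundary_spec("dirichlet", 0.2))
  blocked_grid <- suppressWarnings(voxelize(block_segment(cell, 1L), 0.0125))
  blk <- solve_steady_mm(blocked_grid, NULL, p$transport, p$tissue,
                         boundary_spec("dirichlet", 0.2))
  st_open <- field_stats(open_fld, p$tissue$c_H)
  st_blk <- field_stats(blk, p$tissue$c_H)
  expect_gt(st_blk$hypoxic_fraction, st_open$hypoxic_fraction)
  expect_lt(st_blk$min, st_open$min)
})

test_that("heterogeneous density skews the field without breaking bounds", {
  p <- panelA
  grid <- suppressWarnings(voxelize(make_unit_cell("cuboid", 0.4, 0.05), 0.0125))
  dens <- correlated_density_field(grid, mean = p$tissue$rho_T, cv = 0.4,
                                   ell = 0.08, seed = 11)
  het <- solve_steady_mm(grid, dens, p$transport, p$tissue,
                         boundary_spec("dirichlet", 0.3))
  uni <- solve_steady_mm(grid, NULL, p$transport, p$tissue,
                         boundary_spec("dirichlet", 0.3))
  expect_false(isTRUE(all.equal(het$values, uni$values)))
  vals <- het$values[!is.na(het$values)]
  expect_lte(max(vals), 0.3)
  expect_gte(min(vals), 0)
})

test_that("field statistics count hypoxic voxels exactly", {
  st <- field_stats(rep(0.2, 100), c_H = 0.05)
  expect_equal(unlist(st), c(min = 0.2, mean = 0.2, hypoxic_fraction = 0))
  v <- c(rep(0.2, 99), 0.01)
  expect_equal(field_stats(v, 0.05)$hypoxic_fraction, 1 / 100)
  expect_error(field_stats(numeric(0), 0.05),
               class = "perfunet_validation_error")
})
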