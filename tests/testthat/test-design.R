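# Hypoxia-constrained design: sphere limits, unit maximization, sweeps, march.

test_that("the sphere limit reproduces the zeroth-order closed form", {
  tz <- zeroth_tissue()
  r <- max_sphere_diameter(1.0, panelA$transport, tz)
  d_exact <- 2 * sqrt((1.0 - 0.05) * 6 * 2e-3 / q_of(tz))
  expect_equal(r$d_max, d_exact, tolerance = 0.01)
  expect_error(max_sphere_diameter(0.04, panelA$transport, panelA$tissue),
               class = "perfunet_validation_error")
})

test_that("sphere bisection brackets are verified post hoc", {
  r <- max_sphere_diameter(0.2, panelA$transport, panelA$tissue, tol = 1e-3)
  at <- function(d) solve_sphere(d / 2, 0.2, panelA$transport,
                                 panelA$tissue)$c_min
  expect_gte(at(r$d_max), panelA$tissue$c_H)
  expect_lt(at(r$d_max * 1.003), panelA$tissue$c_H)
})

test_that("unit maximization is feasible-below and infeasible-above", {
  p <- panelA
  r <- max_unit_size("cuboid", 0.05, 0.6, p$tissue, p$transport,
                     tol = 2e-2, h = 0.02)
  expect_true(r$feasible)
  at <- function(s) {
    fld <- octant_solve(s, 0.05, 0.6, p, h = 0.02)
    field_stats(fld, p$tissue$c_H)$min
  }
  expect_gte(at(r$s_max), p$tissue$c_H)
  expect_lt(at(r$s_max + r$bracket * 1.5), p$tissue$c_H)
  # ratio echoes the voxel accounting at s_max
  vols <- measure_volumes(suppressWarnings(
    voxelize(make_unit_cell("cuboid", r$s_max, 0.05), 0.02)))
  expect_equal(r$ratio, vols$ratio, tolerance = 1e-10)
})

test_that("the feasible unit size grows with channel concentration", {
  p <- panelA
  s_max <- vapply(c(0.2, 0.6, 1.0), function(cc) {
    max_unit_size("cuboid", 0.05, cc, p$tissue, p$transport,
                  tol = 2e-2, h = 0.02)$s_max
  }, numeric(1))
  expect_true(all(diff(s_max) > 0))
})

test_that("oversized channels at low oxygen are infeasible data, not errors", {
  r <- max_unit_size("cuboid", 0.2, 0.06, panelA$tissue, panelA$transport,
                     tol = 2e-2, h = 0.08)
  expect_s3_class(tidy(r), "tbl_df")
  expect_false(r$feasible && r$ratio > 1)  # infeasible or tiny compartment
  # c below the hypoxic threshold is infeasible by construction
  r2 <- max_unit_size("cuboid", 0.05, 0.04, panelA$tissue, panelA$transport)
  expect_false(r2$feasible)
  expect_true(is.na(r2$s_max))
})

test_that("sweeps enumerate the design space with infeasible cells as data", {
  sw <- volume_ratio_sweep(c(0.06, 0.6), 0.05, c(Inf, 0.1), "panelA",
                           tol = 5e-2, h = 0.02)
  expect_s3_class(sw, "design_sweep")
  expect_equal(nrow(sw), 4)
  expect_true(all(c("preset", "c_channel", "R_w", "Pi_w", "feasible",
                    "s_max", "ratio") %in% names(sw)))
  # higher oxygen beats lower at both permeabilities
  high <- sw$ratio[sw$c_channel == 0.6]
  expect_true(all(sw$feasible[sw$c_channel == 0.6]))
  low <- sw$ratio[sw$c_channel == 0.06]
  expect_true(all(is.na(low) | high > low, na.rm = TRUE))
})

test_that("the march conserves solute and tapers monotonically", {
  p <- panelA
  m <- long_channel_march(8, 1.0, 2, 4, channel_spec(0.05), p$transport,
                          p$tissue, tol = 1e-2, s_cap = 1.5, h = 0.0125)
  el <- tidy(m)
  expect_true(all(diff(el$c_wall) < 0))
  expect_true(all(diff(el$s) <= 1e-9))
  expect_lt(m$balance_residual, 0.01)
  expect_equal(glance(m)$outlet_c, m$outlet_c)
  # every element is feasible at its own wall concentration
  expect_true(all(el$min_c >= p$tissue$c_H | el$collapsed))
})

test_that("a negligible cell density leaves the channel undepleted", {
  ghost <- tissue_params(1, 1e-16, 0.028, 0.05)
  m <- long_channel_march(8, 1.0, 2, 4, channel_spec(0.05), panelA$transport,
                          ghost, tol = 1e-2, s_cap = 0.8, h = 0.0125)
  el <- tidy(m)
  expect_equal(el$c_wall, rep(1.0, 4), tolerance = 1e-6)
  expect_equal(el$s, rep(0.8, 4), tolerance = 1e-9)  # capped everywhere
})

test_that("halving the velocity never helps any element", {
  p <- panelA
  fast <- long_channel_march(8, 1.0, 2, 4, channel_spec(0.05), p$transport,
                             p$tissue, tol = 1e-2, s_cap = 1.5, h = 0.0125)
  slow <- long_channel_march(4, 1.0, 2, 4, channel_spec(0.05), p$transport,
                             p$tissue, tol = 1e-2, s_cap = 1.5, h = 0.0125)
  expect_true(all(tidy(slow)$c_wall <= tidy(fast)$c_wall + 1e-12))
  expect_true(all(tidy(slow)$s <= tidy(fast)$s + 1e-9))
})

test_that("high demand at low velocity collapses the compartment", {
  p <- panelA
  m <- long_channel_march(0.5, 0.3, 4, 5, channel_spec(0.05), p$transport,
                          p$tissue, tol = 1e-2, s_cap = 1, h = 0.0125)
  el <- tidy(m)
  expect_true(any(el$collapsed))
  expect_equal(el$s[el$collapsed][1], 2 * 0.05 * 1.02, tolerance = 1e-9)
  expect_error(long_channel_march(-1, 1, 5, 10, channel_spec(0.05),
                                  p$transport, p$tissue),
               class = "perfunet_validation_error")
})

test_that("tidiers and plots expose the march and design results", {
  p <- panelA
  m <- long_channel_march(8, 0.4, 1, 2, channel_spec(0.05), p$transport,
                          p$tissue, tol = 5e-2, s_cap = 0.6, h = 0.0125)
  expect_named(glance(m), c("v", "c_in", "L", "n_elem", "Q", "outlet_c",
                            "s_final", "n_collapsed", "balance_residual"))
  expect_s3_class(autoplot(m), "ggplot")
  r <- max_unit_size("cuboid", 0.05, 0.4, p$tissue, p$transport,
                     tol = 5e-2, h = 0.02)
  expect_equal(tidy(r)$s_max, r$s_max)
  sw <- volume_ratio_sweep(0.4, 0.05, Inf, "panelA", tol = 5e-2, h = 0.02)
  expect_s3_class(autoplot(sw), "ggplot")
  sph <- solve_sphere(0.3, 0.2, p$transport, p$tissue)
  expect_s3_class(autoplot(sph, c_H = 0.05), "ggplot")
  expect_named(tidy(sph), c("r", "c"))
})
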