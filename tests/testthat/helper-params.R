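# Shared fixtures: parameter sets and small reference solves built in code.

panelA <- load_preset("panelA")
panelB <- load_preset("panelB")
panelD <- load_preset("panelD")
sphere_alt <- load_preset("sphere_alt")

# near-zeroth-order kinetics (k_m -> 0 limit) for closed-form oracles
zeroth_tissue <- function(rho_T = 2e5, k_ocr = 1e-16, c_H = 0.05) {
  tissue_params(rho_T = rho_T, k_ocr = k_ocr, k_m = 1e-8, c_H = c_H)
}

# volumetric uptake in mol m^-3 s^-1
q_of <- function(tissue) tissue$rho_T * tissue$k_ocr * 1e9

# coarse but valid voxel solve of a cuboid octant, for property tests
octant_solve <- function(s, R_w, c_channel, p, h = R_w / 4, ...) {
  grid <- suppressWarnings(voxelize(make_unit_cell("cuboid_octant", s, R_w), h))
  solve_steady_mm(grid, NULL, p$transport, p$tissue,
                  boundary_spec("dirichlet", c_channel), ...)
}
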