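Package: perfunet
Title: Design of Artificial Perfusion Networks for Engineered Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled channel-network hydraulics, porous-wall permeability and
    Michaelis-Menten oxygen reaction-diffusion modelling for the design of
    artificial supply networks that keep engineered human tissue above a
    hypoxic threshold. Provides Kirchhoff/Hagen-Poiseuille flow and solute
    routing on arbitrary channel graphs, voxelized unit-cell simulation of
    cuboid and rhombic-dodecahedral honeycomb base units, spherical
    compartment limits, hypoxia-constrained maximization of compartment size,
    design-parameter sweeps and an axial marching procedure for long channels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    tibble,
    tidyr,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
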