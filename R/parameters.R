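# Parameter objects and named presets.
#
# Unit convention used across the whole package: lengths in mm, time in s,
# concentrations in mol m^-3 (numerically equal to mM), pressure in Pa.
# Cell density rho_T is in cells mm^-3 and k_ocr in mol cell^-1 s^-1, so the
# volumetric uptake capacity rho_T * k_ocr (mol mm^-3 s^-1) is converted once,
# at use-site, to mol m^-3 s^-1 by the factor 1e9.

check_positive <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(paste0("`", name, "` must be a single finite number."),
          class = "perfunet_validation_error")
  }
  bad <- if (strict) x <= 0 else x < 0
  if (bad) {
    abort(paste0("`", name, "` must be ", if (strict) "strictly positive" else
                 "non-negative", " (got ", format(x), ")."),
          class = "perfunet_validation_error")
  }
  invisible(x)
}

#' Tissue and cell-metabolism parameters
#'
#' Bundles the cell number density, the Michaelis-Menten oxygen uptake
#' parameters and the hypoxic threshold that together define the metabolic
#' sink in the tissue compartment.
#'
#' @param rho_T Cell number density (cells mm^-3).
#' @param k_ocr Maximum oxygen consumption rate per cell (mol cell^-1 s^-1).
#' @param k_m Michaelis constant (mol m^-3): concentration at half-maximal
#'   uptake.
#' @param c_H Hypoxic threshold concentration (mol m^-3). Tissue is considered
#'   viable where the steady oxygen concentration stays above this value.
#' @return An object of class `tissue_params`.
#' @export
#' @examples
#' tissue_params(rho_T = 2e5, k_ocr = 1e-16, k_m = 0.028, c_H = 0.05)
tissue_params <- function(rho_T, k_ocr, k_m, c_H) {
  check_positive(rho_T, "rho_T")
  check_positive(k_ocr, "k_ocr")
  check_positive(k_m, "k_m")
  check_positive(c_H, "c_H")
  structure(list(rho_T = as.numeric(rho_T), k_ocr = as.numeric(k_ocr),
                 k_m = as.numeric(k_m), c_H = as.numeric(c_H)),
            class = "tissue_params")
}

#' Species transport coefficients
#'
#' Diffusivities of the solute (oxygen, unless the user supplies values for
#' another species) in the three model compartments plus the wall/tissue
#' partition coefficient.
#'
#' @param D_t Diffusivity in the tissue compartment (mm^2 s^-1).
#' @param D_c Diffusivity in the channel medium (mm^2 s^-1).
#' @param D_ws Diffusivity in the solid wall material (mm^2 s^-1); may be zero.
#' @param K Partition coefficient at the wall-tissue interface
#'   (dimensionless, default 1 for aqueous media on both sides).
#' @return An object of class `species_transport`.
#' @export
species_transport <- function(D_t, D_c, D_ws = 0, K = 1) {
  check_positive(D_t, "D_t")
  check_positive(D_c, "D_c")
  check_positive(D_ws, "D_ws", strict = FALSE)
  check_positive(K, "K")
  structure(list(D_t = as.numeric(D_t), D_c = as.numeric(D_c),
                 D_ws = as.numeric(D_ws), K = as.numeric(K)),
            class = "species_transport")
}

#' Culture-medium properties
#'
#' @param mu Dynamic viscosity (Pa s).
#' @param nu Kinematic viscosity (mm^2 s^-1).
#' @param c_in Inlet solute concentration (mol m^-3).
#' @return An object of class `medium_params`.
#' @export
medium_params <- function(mu = 6.9e-4, nu = 0.696, c_in = 0.2) {
  check_positive(mu, "mu")
  check_positive(nu, "nu")
  check_positive(c_in, "c_in", strict = FALSE)
  structure(list(mu = as.numeric(mu), nu = as.numeric(nu),
                 c_in = as.numeric(c_in)), class = "medium_params")
}

preset_file <- function() {
  system.file("extdata", "presets.json", package = "perfunet", mustWork = TRUE)
}

#' Available parameter presets
#'
#' @return Character vector of preset names understood by [load_preset()].
#' @export
preset_names <- function() {
  names(jsonlite::read_json(preset_file())$presets)
}

#' Load a named parameter preset
#'
#' Presets bundle literature values for high and low metabolic rate human
#' tissue (liver-like and fat/bone-like) with oxygen transport coefficients
#' and culture-medium properties. `panelA` is the high-demand reference
#' (rho_T = 2e5 cells mm^-3, k_m = 0.028 mol m^-3, k_ocr = 1e-16
#' mol cell^-1 s^-1), `panelB` has a tenth of that cell density, `panelC` a
#' lower Michaelis constant (0.015), `panelD` is low-demand tissue
#' (rho_T = 1.4e4, k_m = 0.007, k_ocr = 4.2e-17) and `sphere_alt` an
#' alternative high-density parameterization (k_m = 0.015, k_ocr = 7e-17).
#'
#' @param name One of `preset_names()`.
#' @return A list with elements `tissue` ([tissue_params()]),
#'   `transport` ([species_transport()]) and `medium` ([medium_params()]).
#' @export
#' @examples
#' p <- load_preset("panelA")
#' p$tissue$rho_T
load_preset <- function(name) {
  all <- jsonlite::read_json(preset_file(), simplifyVector = TRUE)$presets
  if (!is.character(name) || length(name) != 1L || !name %in% names(all)) {
    abort(paste0("Unknown preset `", paste(name, collapse = ","),
                 "`. Valid presets: ", paste(names(all), collapse = ", "), "."),
          class = "perfunet_validation_error")
  }
  p <- all[[name]]
  list(
    tissue = tissue_params(p$tissue$rho_T, p$tissue$k_ocr,
                           p$tissue$k_m, p$tissue$c_H),
    transport = species_transport(p$transport$D_t, p$transport$D_c,
                                  p$transport$D_ws, p$transport$K),
    medium = medium_params(p$medium$mu, p$medium$nu, p$medium$c_in)
  )
}

#' Serialize a parameter set to JSON
#'
#' Round-trips bit-for-bit with [read_params()]: numbers are written with
#' full precision (17 significant digits).
#'
#' @param params A list with `tissue`, `transport` and `medium` components,
#'   as returned by [load_preset()].
#' @param path File to write.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(all(c("tissue", "transport", "medium") %in% names(params)))
  x <- lapply(params, unclass)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a parameter set written by [write_params()]
#'
#' @param path JSON file to read.
#' @return A list with `tissue`, `transport` and `medium` components.
#' @export
read_params <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(
    tissue = tissue_params(p$tissue$rho_T, p$tissue$k_ocr,
                           p$tissue$k_m, p$tissue$c_H),
    transport = species_transport(p$transport$D_t, p$transport$D_c,
                                  p$transport$D_ws, p$transport$K),
    medium = medium_params(p$medium$mu, p$medium$nu, p$medium$c_in)
  )
}

# volumetric uptake capacity in mol m^-3 s^-1 (rho_T [cells mm^-3] *
# k_ocr [mol cell^-1 s^-1] = mol mm^-3 s^-1; 1 mol mm^-3 = 1e9 mol m^-3)
uptake_capacity <- function(tissue) {
  tissue$rho_T * tissue$k_ocr * 1e9
}

#' @export
print.tissue_params <- function(x, ...) {
  cat("Tissue parameters:\n",
      sprintf("  rho_T = %g cells/mm^3, k_ocr = %g mol/cell/s\n",
              x$rho_T, x$k_ocr),
      sprintf("  k_m = %g mol/m^3, c_H = %g mol/m^3\n", x$k_m, x$c_H))
  invisible(x)
}
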