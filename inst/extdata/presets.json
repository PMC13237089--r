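{
  "format_version": 1,
  "units": {
    "length": "mm",
    "time": "s",
    "concentration": "mol m^-3",
    "pressure": "Pa",
    "rho_T": "cells mm^-3",
    "k_ocr": "mol cell^-1 s^-1",
    "diffusivity": "mm^2 s^-1",
    "viscosity_dynamic": "Pa s",
    "viscosity_kinematic": "mm^2 s^-1"
  },
  "presets": {
    "defaults": {
      "tissue": { "rho_T": 2e5, "k_ocr": 1e-16, "k_m": 0.028, "c_H": 0.05 },
      "transport": { "D_t": 2e-3, "D_c": 3e-3, "D_ws": 1e-5, "K": 1 },
      "medium": { "mu": 6.9e-4, "nu": 0.696, "c_in": 0.2 }
    },
    "panelA": {
      "tissue": { "rho_T": 2e5, "k_ocr": 1e-16, "k_m": 0.028, "c_H": 0.05 },
      "transport": { "D_t": 2e-3, "D_c": 3e-3, "D_ws": 1e-5, "K": 1 },
      "medium": { "mu": 6.9e-4, "nu": 0.696, "c_in": 0.2 }
    },
    "panelB": {
      "tissue": { "rho_T": 2e4, "k_ocr": 1e-16, "k_m": 0.028, "c_H": 0.05 },
      "transport": { "D_t": 2e-3, "D_c": 3e-3, "D_ws": 1e-5, "K": 1 },
      "medium": { "mu": 6.9e-4, "nu": 0.696, "c_in": 0.2 }
    },
    "panelC": {
      "tissue": { "rho_T": 2e5, "k_ocr": 1e-16, "k_m": 0.015, "c_H": 0.05 },
      "transport": { "D_t": 2e-3, "D_c": 3e-3, "D_ws": 1e-5, "K": 1 },
      "medium": { "mu": 6.9e-4, "nu": 0.696, "c_in": 0.2 }
    },
    "panelD": {
      "tissue": { "rho_T": 1.4e4, "k_ocr": 4.2e-17, "k_m": 0.007, "c_H": 0.05 },
      "transport": { "D_t": 2e-3, "D_c": 3e-3, "D_ws": 1e-5, "K": 1 },
      "medium": { "mu": 6.9e-4, "nu": 0.696, "c_in": 0.2 }
    },
    "sphere_alt": {
      "tissue": { "rho_T": 2e5, "k_ocr": 7e-17, "k_m": 0.015, "c_H": 0.05 },
      "transport": { "D_t": 2e-3, "D_c": 3e-3, "D_ws": 1e-5, "K": 1 },
      "medium": { "mu": 6.9e-4, "nu": 0.696, "c_in": 0.2 }
    }
  }
}
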