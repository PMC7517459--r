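Package: kkpeusner
Title: Resistance-Matrix Form of the Kedem-Katchalsky-Peusner Membrane
    Transport Equations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the network-thermodynamic (Peusner) resistance-matrix
    form of the Kedem-Katchalsky equations describing passive transport of
    ternary non-electrolyte solutions across a polymer membrane, with and
    without concentration polarization. Computes volume and solute fluxes,
    the 3x3 resistance coefficients and their determinant for both gravity
    configurations of a horizontal membrane, concentration-boundary-layer
    thicknesses, solution densities and the concentration Rayleigh number,
    configuration-difference (convection) diagnostics, degrees of coupling,
    energy-conversion efficiencies and the Q_R coupling parameter, plus
    concentration sweeps, a YAML configuration format and a small command
    line interface. Ships the published parameter set for the Nephrophan
    membrane bathed by glucose in aqueous ethanol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
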