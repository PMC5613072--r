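Package: monofilm
Title: Thermodynamic Analysis of Langmuir Monolayer Pressure-Area Isotherms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the thermodynamic analysis of Langmuir monolayer
    surface pressure-area (pi-A) isotherms of membrane lipids. Provides a
    validated isotherm data model with a plain-text file dialect, local
    polynomial smoothing and shape-preserving regridding, extraction of the
    standard film descriptors (compression modulus, physical state, lift-off
    and limiting areas, collapse pressure, phase-transition pressures),
    excess-area and excess Gibbs energy of mixing for binary and
    pseudo-binary ternary films after Pagano and Gershfeld, a
    collapse-pressure miscibility criterion, critical packing parameter
    shape classification after Israelachvili, and an equation-of-state
    based synthetic isotherm generator with closed-form ground truth for
    validating every stage of the analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
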