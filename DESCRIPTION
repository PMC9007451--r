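Package: lipidtools
Title: Torsion Parameter Fitting and Bilayer Structural Analysis for
    AMBER-Family Lipid Force Fields
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for deriving and validating AMBER-family lipid force
    field parameters and for analysing lipid bilayer simulations. Fits
    cosine-series dihedral (torsion) parameters to quantum-mechanical
    reference energies with a real-coded genetic algorithm under
    discrete phase and periodicity constraints, fits harmonic angle
    parameters to 1D scans, and averages per-conformer RESP charge sets
    into neutral modular fragments. Implements the standard bilayer
    structural observables: area and volume per lipid, electron-density
    profiles and head-to-head thickness, carbon-hydrogen (deuterium
    NMR) order parameters, X-ray and neutron scattering form factors,
    cholesterol tilt distributions, midplane transit (flip-flop) event
    detection, and melting-point estimation from heating scans. Ships a
    synthetic-fixture generator with known ground truth so the whole
    pipeline is testable without quantum chemistry or molecular
    dynamics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
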