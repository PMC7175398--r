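Package: boreq
Title: Stem-Borehole Equilibration Modeling of Xylem Water Isotopes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the equilibration of water vapor with liquid xylem water in
    air flowing through a tree-stem borehole, for in-situ monitoring of the
    stable-isotope composition (d18O, d2H) of tree source water. Provides a
    segmented steady-state advection-diffusion model of vapor mole fraction and
    isotope ratios along the borehole with three closures for the isotopic
    composition of the evaporating wall water (fixed xylem equilibrium,
    Craig-Gordon steady state, and an f-weighted mixture), time-constant
    diagnostics, and parameter sweeps. Also implements the companion
    measurement pipeline for cavity ring-down vapor isotope time series:
    trailing-window cycle averaging, standard-deviation and relative-humidity
    quality control, calibration against headspace standards, vapor-to-liquid
    conversion via equilibrium fractionation, and tracer breakthrough-curve
    timing, together with a seeded synthetic campaign generator for testing
    the pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
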