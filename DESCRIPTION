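Package: voidpart
Title: Partition Crystal Unit-Cell Volume into Network and Void Components
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo partitioning of crystal unit-cell volume into the
    occupied "network" of atoms and intermolecular contacts and the unoccupied
    interstitial "void" space, based on van der Waals sphere unions sampled
    with random points. Reads crystallographic information files (CIF),
    expands symmetry to a full cell, normalizes X-H distances and propagates
    coordinate standard uncertainties into the volume estimates. A companion
    equation-of-state layer (Birch-Murnaghan and Vinet families) turns
    variable-pressure series of network and void volumes into component bulk
    moduli, composes the overall bulk modulus by reciprocal mixing with the
    packing coefficient, detects volume discontinuities across phase
    transitions by piecewise fits, and flags premonitory deviations from an
    extrapolated equation of state.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
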