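Package: filmphase
Title: Langmuir Monolayer Isotherm Analysis and Cubic Mesophase Indexing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Extracts physical descriptors from surface pressure-area
    isotherms of Langmuir monolayers (compressibility modulus profiles,
    Davies-Rideal phase classification, phase-transition minima, lift-off
    and limiting areas, areas at target pressures), quantifies drug
    penetration into preformed films through area-expansion (delta-A)
    metrics with replicate uncertainty and an excess-over-additivity
    synergy score, analyses constant-area injection kinetics, and
    identifies bicontinuous cubic lipid mesophases from one-dimensional
    small-angle X-ray scattering profiles by Bragg-peak detection,
    space-group ratio matching and lattice-parameter fitting. Includes a
    seeded synthetic-data generator that builds isotherms by integrating
    prescribed compressibility profiles so every ground-truth descriptor
    is known by construction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
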