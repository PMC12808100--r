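Package: nhuquant
Title: Quantitative Analysis of Native Holdup Affinity-Interactomics Data
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative analysis of native holdup (nHU)
    affinity-interactomics experiments. Converts mass-spectrometric prey
    depletion into degrees of binding and apparent dissociation constants
    through the single-site hyperbolic binding law, runs the proteome-scale
    statistical pipeline (median normalization, bottom-decile imputation,
    equal-variance t-tests, hyperbolic volcano significance threshold),
    fits titration holdup and direct/competitive fluorescence polarization
    binding curves, estimates affinities of tethered (indirectly captured)
    complexes, and performs disorder-aware short-linear-motif scanning with
    conservation-based re-ranking and proteome-background enrichment.
    Includes seeded synthetic-data generators with attached ground truth
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    optparse,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
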