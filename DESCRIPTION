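Package: gutfate
Title: Metabolic Fate Classification for In Vitro Fecal Fermentation
    Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for triaging untargeted LC-MS features from in vitro
    incubations of a plant extract with human fecal suspension. Classifies
    each feature's metabolic fate (increasing, decreasing, intermediate,
    unchanged, fast-metabolized, matrix) from time-course group ratios and
    pooled-variance t-tests, with matrix exclusion and an abiotic
    extract-control crosscheck. Includes molecular-formula parsing and
    monoisotopic-mass arithmetic for negative-mode electrospray data,
    annotation against a bundled willow-bark compound library by ppm mass
    tolerance with optional retention-time gating, directed
    degradation-pathway graphs with fate overlays, a seeded synthetic-data
    generator with known kinetic ground truth, and minimal OTU-table
    filtering and total-sum normalization utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
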