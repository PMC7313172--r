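Package: grscreen
Title: Growth-Rate Normalized Analysis of Ex Vivo Drug Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for plate-based ex vivo drug sensitivity
    screens of patient-derived tumor cells. Implements control-based
    normalized growth-rate inhibition (GR) metrics with a hydroxyurea
    stall reference, sigmoid GR-curve and four-parameter logistic
    dose-response fitting with absolute IC50 extraction, Chou-Talalay
    median-effect combination-index analysis for fixed-ratio dose
    designs, hit nomination and ranking, cross-assay concordance and
    hierarchical clustering of dose responses, and a seeded synthetic
    384-well screen generator with known ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
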