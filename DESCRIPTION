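Package: glycoforce
Title: Force-Curve Decomposition of Cell Elasticity and Glycocalyx Brush
    Mechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of atomic force microscopy (AFM) force-distance curves
    on living cells: baseline correction, contact-point estimation, and a
    two-regime decomposition into a Hertz (spherical) or Sneddon (pyramidal)
    elastic indentation response and an Alexander-de Gennes polymer-brush
    response, yielding the apparent Young's modulus E and the glycocalyx
    brush length L per curve. Force maps are aggregated into per-cell and
    per-region summaries with group statistics and before/after drug
    comparisons. Companion quantification tools cover corrected total cell
    fluorescence (CTCF), scratch-assay gap closure, differential
    expression/abundance threshold filtering and exact hypergeometric
    set-overlap tests. A synthetic-data module generates every input with
    planted ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    EBImage,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
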