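Package: plsperm
Title: PLS-Based QSPR Modelling of Membrane Permeability with Franz-Cell
    Data Reduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Chemometric toolkit for quantitative structure-property
    relationship (QSPR) modelling of in vitro membrane permeability.
    Reduces Franz diffusion-cell receptor time series to steady-state flux
    and apparent permeability coefficients, fits single-response partial
    least squares (NIPALS) models on autoscaled descriptor tables, and
    provides the full validation and diagnostic suite used in chemometric
    practice: cross-validated PRESS and Q-squared with component
    significance, response-permutation (Y-scrambling) validation with
    intercept criteria, external two-half swap validation with RMSEP,
    variable importance in the projection (VIP), weight-loading (w x c)
    coordinates, per-observation contribution profiles, and score/residual
    outlier flags. A seeded synthetic-data generator with known latent
    structure makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    withr,
    mixOmics,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
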