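Package: firfit
Title: Individual-Tree DBH Models for LiDAR-Derived Plantation Inventories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Height-diameter modeling workflow for plantation inventories in
    which tree height and crown width come from airborne laser scanning while
    diameter at breast height (DBH) must be predicted. Provides ten candidate
    DBH-height model forms with nonlinear least-squares fitting, variance
    inflation factor screening of LiDAR covariates, power-function covariate
    expansion, growth-stage dummy-variable models, and a two-level (region /
    plot) nonlinear mixed-effects model with stage-stratified residual
    variance, EBLUP calibration for new stands, and likelihood-ratio testing.
    A hierarchical synthetic-inventory generator calibrated to Chinese fir
    (Cunninghamia lanceolata) plantation summary statistics makes the whole
    pipeline testable by parameter recovery without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    nlme,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
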