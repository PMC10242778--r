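Package: stormreg
Title: Fiducial-Based Channel Registration for Single-Molecule
    Localization Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Registers sequentially acquired channels of multi-color STORM
    (stochastic optical reconstruction microscopy) recordings directly on
    localization tables.  Fiducial markers are detected from their
    non-blinking emission using per-frame neighborhood statistics (mean
    tolerance and variance limit); a rigid transformation per moving channel
    is estimated with the Iterative Closest Point algorithm and applied to
    all localizations.  A fiducial-free cluster mode detects dense
    localization clusters as landmarks instead.  Registration quality is
    quantified by Target Registration Error on landmark pairs and Normalized
    Cross-Correlation on rendered images.  Includes readers and writers for
    ThunderSTORM-style CSV localization tables, a synthetic-data generator
    with known ground truth, and a YAML-driven batch job runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
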