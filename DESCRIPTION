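Package: coralPCF
Title: Grid-Based Pair-Correlation Analysis of Algal Colonization on Coral
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying micro-scale spatial patterns of algae
    colonizing bleached coral surfaces from reflectance microscopy images.
    Implements HSV-saturation image segmentation to presence/absence raster
    maps, the grid-based (O-ring) pair-correlation function g(r) with
    buffer-zone edge correction and a minimum-focal-cell rule, resampling
    confidence intervals with order-statistic bounds, per-radius
    classification against complete spatial randomness, and critical-scale
    summaries.  A synthetic-scene generator (Poisson, Thomas cluster, and
    hexagonal polyp-lattice exclusion patterns, with a simple renderer)
    provides ground-truth inputs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Rcpp,
    jsonlite,
    png,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
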