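Package: tillercount
Title: Counting Grass Tillers from Images of Cut, Tip-Painted Bunches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-analysis pipeline for determining grass tillering (the
    number of above-ground shoots per bunch) from photographs of bunches that
    were cut and had their shoot tips painted white. Implements blue-band
    extraction, automatic maximum-contrast (Koehler) thresholding,
    morphological opening with small-object removal, eleven per-object
    morphometric shape descriptors (area, Crofton perimeter, compactness,
    equivalent-ellipse elongation, convex-hull area/perimeter/minimum angle,
    symmetry mean difference, Feret diameters, Pentland sphericity),
    collinearity pruning by variance inflation factor, two-class linear
    discriminant analysis with tolerance / F-to-remove / Wilks' lambda
    diagnostics, and method-agreement statistics (RMSE, MAE, MBE, identity-line
    regression tests) between image-based and manual counts. Includes a seeded
    synthetic-scene generator with ground truth so the whole pipeline is
    testable without field photographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jpeg,
    jsonlite,
    png,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
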