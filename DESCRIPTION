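Package: phenoshoot
Title: Image-Based Shoot Phenotyping and Growth-Curve Analysis for Grasses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A high-throughput shoot-phenotyping pipeline for grass-architecture
    plants such as sorghum. Generates synthetic top- and side-view plant images
    with exact ground truth, segments plants from a uniform background by
    nearest-neighbour colour classification with morphological cleanup,
    calibrates pixel counts to projected leaf area in physical units, computes
    canopy shape descriptors (convex hull, calliper length, minimum enclosing
    circle, compactness, surface coverage, eccentricity), extracts HSI hue and
    senescence fractions plus near-infrared grey values, fits a library of
    eight nonlinear growth models with AIC-based selection and population
    prediction intervals, and derives relative and absolute growth rates,
    leaf-rolling statistics and water-use efficiency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    minpack.lm,
    MASS,
    stats,
    grDevices,
    utils,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
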