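Package: morphfree
Title: Landmark-Free 2D Outline and 3D Surface Geometric Morphometrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Landmark-free geometric morphometrics for complex skeletal
    elements such as the teleost pelvic girdle. Implements the 2D outline
    pipeline (Freeman chain coding of binary silhouettes, elliptic Fourier
    descriptors with longest-radius normalization, covariance PCA with
    wireframe visualisation) and the 3D surface pipeline (mesh cleaning and
    resampling, area-weighted point sampling, modified iterative-closest-point
    superimposition to a prototype, Procrustes surface metric, generalized
    surface alignment with per-point deviation heat values), together with the
    two-criterion prototype and mesh-resolution selection procedure and
    downstream statistics: broken-stick component retention, PERMANOVA, range
    and convex-hull disparity with bootstrap t-tests, and phylogenetic
    generalized least squares with a Pagel's lambda policy. A synthetic
    bone-shape generator with known ground truth supports end-to-end recovery
    tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    vegan,
    MASS,
    EBImage,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    readr,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    nlme,
    optparse,
    png,
    withr
Config/testthat/edition: 3
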