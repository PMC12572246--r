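Package: mpodfit
Title: Modelling Macular Pigment Optical Density Spatial Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling the radial spatial profile of human macular
    pigment optical density (MPOD) as measured by dual-wavelength fundus
    autofluorescence. Implements a three-Gaussian-component profile model and
    the legacy exponential-plus-Gaussian model, constrained nonlinear
    least-squares fitting over configurable eccentricity windows with
    multi-start initialisation, analytic differentiation and second-derivative
    critical-point extraction (inflections and curvature turning points),
    derived parameters (central amplitude, eccentric-peak amplitude, areas
    under the curve, half-height radius), radial profile extraction from 2D
    MPOD maps by circular-path averaging, synthetic cohort generation with a
    morphometry linkage model, and a principal-components factor-analysis and
    stepwise-regression workflow for relating profile shape to foveal
    morphometry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    lhs,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    png,
    tiff,
    optparse
Config/testthat/edition: 3
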