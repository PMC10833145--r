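Package: morphsample
Title: Sample-Size and View Effects in Two-Dimensional Geometric
    Morphometrics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for two-dimensional landmark-based geometric
    morphometrics with an emphasis on study design: generalized
    Procrustes analysis with bending-energy sliding of semilandmarks,
    thin-plate-spline warps and deformation grids, shape principal
    component analysis, Procrustes ANOVA with residual-randomization
    permutation (RRPP), Procrustes-variance dispersion tests, two-block
    partial least squares, and a seeded rarefaction experiment that
    quantifies how sample size affects estimates of mean shape, shape
    variance, and centroid size. Includes a TPS (tpsDIG dialect) reader
    and writer and a synthetic landmark-data generator with known
    allometry and group effects for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
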