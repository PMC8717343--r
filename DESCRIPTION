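Package: bathysdm
Title: Demersal Fish Distribution Models from Sparse Singlebeam Bathymetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to build and evaluate demersal fish species distribution
    models from sparse singlebeam echo-sounder (SBES) soundings and to compare
    them against models built on full-coverage reference bathymetry. Provides
    sounding quality control (block averaging, tide correction, robust
    despiking), spatial interpolation by inverse distance weighting, radial
    basis functions (completely regularized spline and multiquadric) and
    ordinary/universal kriging with anisotropic Gaussian variograms,
    leave-one-out cross-validation model selection, multi-resolution seafloor
    terrain derivatives (slope, northness/eastness, standard deviation of
    depth, terrain ruggedness index, topographic position index, roughness,
    mean curvature), distance-banded surface agreement statistics, and
    random-forest presence/absence habitat models evaluated by cross-validated
    AUC. A synthetic-data module simulates anisotropic shelf bathymetry,
    transect surveys with tide and spike noise, and species with known
    depth/terrain responses so every stage is testable at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    pracma,
    e1071,
    randomForest,
    pROC,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
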