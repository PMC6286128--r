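Package: attnprf
Title: Population Receptive Field Mapping Under Attentional Gain Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of population receptive field (pRF)
    measurements under differential spatial and feature-based attention.
    Provides a traversing-bar stimulus design and hemodynamic forward model,
    a generative model of condition-specific BOLD time series in which a
    Gaussian stimulus-driven receptive field is multiplied by attentional
    gain fields, a three-step pRF estimation procedure (regularized
    back-projection, joint Gaussian fit, per-condition refit with a shared
    baseline), inversion of the gain-field model by grid search over the two
    gain-field sizes, descriptive shift/eccentricity/size analyses including
    the feature attention modulation index, an adaptive-staircase behavioural
    simulator, gaze-trace cleaning, and weighted-bootstrap voxel statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    minpack.lm,
    signal,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
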