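Package: needleuq
Title: Needle Deflection Prediction and Uncertainty Quantification for
    Transperineal Biopsy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates the deflection of a bevel-tipped biopsy needle
    inserted through layered soft tissue using a planar Euler-Bernoulli
    beam finite-element model supported on preloaded tissue springs,
    trains fast surrogate regressors (ordinary least squares, a
    multilayer perceptron, and a Fourier-feature neural network) on
    simulator output, and propagates truncated-normal priors on tissue
    elastic moduli through the surrogate by Monte Carlo sampling to
    produce needle-shape confidence bands for procedure planning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    graphics,
    grDevices,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
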