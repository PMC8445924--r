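Package: dftensor
Title: Linear Tensor Surrogate Models for Anisotropic Dark-Field Contrast
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation toolkit for grating-based X-ray and neutron
    dark-field tensor tomography. Synthesizes anisotropic dark-field
    extinction signals of isolated volume elements from a nonlinear
    physical model parametrized by a Gaussian mass-distribution tensor,
    reconstructs the two linear rank-2 surrogate tensor models (optical-axis
    and sensitivity-axis parametrizations) by damped iterative
    back-projection over circular acquisition trajectories, and compares
    reconstructed eigenvectors and eigenspectra against ground truth via
    normalized root-mean-square errors, angular-deviation distributions and
    mean-signal checks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
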