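Package: dwigp
Title: Gaussian Process Modelling and Prediction of Diffusion-Weighted MRI Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Non-parametric representation and prediction of single- and
    multi-shell diffusion-weighted MRI signals using Gaussian processes on
    the sphere. Provides axially symmetric spherical and exponential
    covariance models, cross-shell product kernels on log b-value distance,
    type-II maximum-likelihood and leave-one-out hyperparameter estimation,
    Laplace-approximated model evidence with Bayes factors, GP smoothing and
    interpolation of diffusion volumes, and a multi-tensor synthetic DWI
    simulator for validation. Reads and writes NIfTI volumes with FSL-style
    bvals/bvecs gradient tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
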