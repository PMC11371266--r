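Package: safir
Title: Spatially Adaptive Iteratively Reweighted L1 Image Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image reconstruction for denoising and undersampled single-coil
    magnetic-resonance imaging with spatially re-weighted L1-analysis
    regularization. Implements two iterative refinement schemes in which a
    per-channel, per-pixel mask generated from the previous reconstruction
    locally rescales the L1 penalty: a majorization-minimization scheme (MMR)
    whose masks are derivatives of learned concave potentials and whose
    objective provably decreases, and solution-adaptive fixed-point iterations
    (SAFI) whose masks come from a small learned convolutional network. Includes
    the nested accelerated forward-backward solvers with a dual evaluation of
    the weighted-L1 proximal operator, shape-constrained linear-spline
    nonlinearities, constrained convolutional parameterizations, a reduced-scale
    unrolled training loop with a built-in reverse-mode tape, synthetic phantoms
    and patch generators, PSNR/SSIM metrics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml,
    png,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
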