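Package: qpactoed
Title: Bayesian Cramer-Rao Bound Experimental Design for Quantitative
    Photoacoustic Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A virtual two-dimensional quantitative photoacoustic computed
    tomography (qPACT) system and an estimator-independent optimal
    experimental design pipeline built on the Bayesian Cramer-Rao bound.
    Provides a graded triangular disk mesher with first-order continuous
    Galerkin finite-element assembly, a diffusion-approximation optical
    forward model with Robin boundary conditions, cone-beam illumination
    design schemes, a sparse circular Radon transform acoustic operator with
    exact adjoint, log-Gaussian priors with diffusion-reaction (Matern-type)
    covariance operators, adjoint-based likelihood scores, Monte Carlo
    estimation of the Bayesian information and bound, nuisance-parameter
    post-marginalization with change-of-variable transport to the absorption
    coefficient, mass-weighted trace design metrics, and an inexact
    Newton-CG maximum a posteriori reconstructor used to validate the bound.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
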