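Package: polynode
Title: Bayesian Polynomial Neural Networks and Polynomial Neural ODEs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Symbolic recovery of polynomial dynamical systems from noisy
    time-series data using Bayesian polynomial neural networks (pi-nets) and
    polynomial neural ordinary differential equations.  A pi-net is built from
    linear layers combined by Hadamard products, so its output is an exact
    polynomial of its input and can be expanded symbolically into monomial
    coefficients.  The package trains such networks by penalised nonlinear
    least squares (MAP), quantifies parameter uncertainty with three
    interchangeable posterior engines (Laplace approximation with a
    Moore-Penrose pseudoinverse of the Fisher information, Hamiltonian Monte
    Carlo / No-U-Turn sampling, and mean-field Gaussian variational
    inference), and propagates parameter posteriors to polynomial-coefficient
    posteriors by Monte Carlo expansion.  Gaussian-process-regression
    pre-smoothing supplies initial conditions for training windows on noisy
    trajectories, and a benchmark module generates the classic test systems
    (univariate cubic, Lotka-Volterra, damped oscillator, Lorenz) with
    additive Gaussian noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    deSolve,
    minpack.lm,
    jsonlite,
    MASS,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
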