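---
title: "Bayesian polynomial neural ODEs: models, inference engines, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian polynomial neural ODEs: models, inference engines, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polynode)
```

This vignette documents the models implemented in `polynode`, the
assumptions behind them, the tunable parameters that matter, and the
numerical and design choices made where the problem leaves them open.

## 1. The π-net and its symbolic expansion

A polynomial neural network (π-net) composes linear layers
$L_i(x) = w_i x + b_i$ with Hadamard (elementwise) products and no
nonlinear activations, so the network output is an exact polynomial of
its input. `polynode` uses the wiring

$$z_1 = L_1(x), \qquad
  z_k = L_k(x) \circ z_{k-1} + z_{k-1} \quad (k = 2,\dots,D),$$

followed by a linear mixing layer $z_{mix} = M z_D + b$ and a bias-free
read-out $y = W z_{mix}$. Each product stage raises the attainable total
degree by one, so the output has degree at most $D$; the skip connection
keeps all lower-degree terms representable. For one input, one output,
degree 3 and hidden width 10 this gives the 1x10x10x10x10x1 layout with
exactly 180 scalar parameters. The wiring itself is a design choice: the
product-with-skip recursion is the simplest arrangement that makes that
layout well-defined, and the 180-parameter count is the anchor that pins
it. Hidden widths are configurable (`pinet_config()`); all product
stages must share one width so the Hadamard operands conform.

**Symbolic expansion.** Because the architecture is polynomial,
`expand_to_polynomial()` multiplies the factorized form out exactly:
every hidden unit's value is represented as a coefficient vector over
the monomial basis (all exponent vectors of total degree $\le D$,
ordered by degree then lexicographically), linear layers act as matrix
products on coefficient vectors, and Hadamard products become discrete
convolutions over the basis. Like terms are combined; nothing is pruned,
however small — pruning is a reporting choice, not a model choice.
Forward evaluation and expansion agree to floating-point roundoff, which
the test suite asserts at `1e-9` relative over random networks.

**Initialization.** Training starts from networks whose expanded
coefficients all have magnitude in $[10^{-10}, 10^{-5}]$ — numerically
the zero polynomial, so the optimizer grows terms rather than having to
cancel spurious ones. Weights are drawn uniformly; because the expanded
coefficients are *exactly linear* in the read-out layer, the band is hit
by rescaling the read-out alone (a global rescale of all layers would
act inhomogeneously through the skip connections and can push small
coefficients out the bottom of the band while large ones are still
inside). Draws whose coefficient dynamic range exceeds the band width
$10^5$ are rejected and redrawn, up to a bounded number of attempts.

## 2. Neural ODEs, integration, and training

For time-series data the π-net is the right-hand side of
$\dot y = f_\theta(y)$ (autonomous). Predictions integrate the field
from an initial condition with the explicit fourth-order
Runge–Kutta–Fehlberg scheme — stages $k_1..k_5$ with the fourth-order
weights; the fifth-order embedded estimate is not computed — taking
`substeps` equal fixed steps per observation interval. Fixed steps keep
the computation an explicit composition, so exact gradients are
available by forward sensitivity propagation: differentiating an
explicit Runge–Kutta map with respect to parameters is identical to
applying the same scheme to the variational equations
$\dot S = J_y S + J_\theta$, which is what the implementation does.
Gradients through the integrator therefore agree with finite differences
to the differencing error itself (asserted at `1e-4`). Adjoint methods
and stiff solvers are out of scope.

The default `substeps = 10` is validated by the fourth-order convergence
property (halving the step cuts the error ~16x); the Lorenz benchmark
uses `substeps = 3` because its observation interval is already small
(0.033 time units), where three substeps leave the discretization error
orders of magnitude below the observation noise.

**Batching.** Training data are sliced into all $n - L + 1$ overlapping
windows of $L$ consecutive points (`make_batches()`): 100 points with
$L = 12$ give 89 windows. Every epoch integrates all windows
simultaneously as a batched initial-value problem. Window length is a
per-system setting with no automatic selection (12 for Lotka–Volterra,
13 for the damped oscillator, 2 for the Lorenz attractor — short windows
suit fast oscillations). When replicate trajectories share the time
grid, each unique window is integrated once and its prediction is
compared against every replicate's observations — exactly equivalent to
duplicating the windows per replicate, at a tenth of the cost.

**The MAP objective.** With Gaussian observation noise of variance
$\beta^2$ and an isotropic zero-mean Gaussian prior of standard
deviation $\alpha$ (default $10^5$, deliberately noninformative), the
log-joint is
$-\tfrac{1}{2\beta^2}\sum (y_{pred}-y_{known})^2 -
 \tfrac{1}{2\alpha^2}\theta^\top\theta$.
Training maximizes it with the constant $1/(2\beta^2)$ scale dropped,
i.e. minimizes $\mathrm{SSE} + \theta^\top\theta/(2\alpha^2)$; at the
default prior the ridge term is numerically negligible and the MAP is a
least-squares fit. $\beta^2$ is *not* learned during training: it is
estimated afterwards as the $n$-denominator sample variance of the
pooled residuals (all states, windows, replicates) and reinstated in
every posterior computation. Whether the prior term participates in the
MAP is configurable (`map_control(include_prior=)`); it changes nothing
at the default $\alpha$.

**Optimizers.** Two are provided, with an automatic default:

- *Adam* (`lr = 1e-3`, 5000 epochs) for regression-mode fits. Beyond
  matching the class of optimizer these models are usually trained with,
  it has a property we rely on: started from the tiny-coefficient
  initialization it converges to the *small-parameter-norm* optimum
  among the continuum of equivalent MAP solutions (π-nets are
  overparameterized, so the likelihood fixes only the expanded
  coefficients, not the weights). The small-norm solution has far
  better-conditioned curvature than an arbitrary optimum — the Fisher
  spectrum spans many fewer decades — which the MCMC and VI engines
  need.
- *Levenberg–Marquardt* (`minpack.lm`, analytic residual Jacobian from
  the forward sensitivities) for neural-ODE fits, where each objective
  evaluation integrates every window and a second-order method's far
  smaller evaluation count matters. LM reaches the same SSE as Adam in
  tens of evaluations instead of thousands.

The regression objective and gradient run through a compiled
(RcppArmadillo) kernel. For regression models the kernel additionally
exploits an exact algebraic identity: the network output lies in the
span of the $M$ monomials, so the SSE against $n$ points is a quadratic
form in the $M$ expanded coefficients, recoverable from evaluations at
$M$ fixed collocation points (Chebyshev nodes for one input; a seeded
search for a well-conditioned design otherwise). The objective is then
independent of $n$, exact to machine precision, and cheap enough to
drive long MCMC chains.

## 3. Posterior engines

**Laplace approximation** (`fisher_information()`,
`laplace_posterior()`). The posterior is
$\theta \sim N(\theta^*, I_\theta^{-1})$ with the Fisher information in
gradient form. The expectation in the gradient form is taken under the
*model*: for Gaussian noise the per-observation expected outer product
is $J_i^\top J_i/\beta^2$ with $J_i$ the predicted-value Jacobian, so
$I_\theta = \sum_i J_i^\top J_i/\beta^2 + I/\alpha^2$ with the prior
precision added exactly. This choice makes the Laplace posterior
*coincide exactly* with closed-form Bayesian linear regression on
linear-in-parameters models — the validation axis the test suite
enforces at `1e-3` relative — where an empirical realized-gradient sum
would only agree within sampling noise. π-nets are overparameterized, so
$I_\theta$ is singular; the covariance is its Moore–Penrose
pseudoinverse with singular values below `rcond = 1e-10` (relative)
truncated, refused above 50 000 parameters where the dense SVD stops
being practical. A Hessian mode (numerical differentiation of the
analytic gradient) is retained as a cross-check for small models, and a
diagonal-only mode as a cheap fallback; neither is the default.

**HMC and NUTS** (`sample_hmc()`, `sample_nuts()`). Plain HMC uses
user-fixed step size and leapfrog count with a Metropolis correction and
no adaptation. NUTS implements slice-based tree doubling with a depth
cap of 10, dual-averaging step-size adaptation toward 0.8 acceptance,
and diagonal mass-matrix estimation over doubling warmup windows
(75-iteration initial buffer, windows of 25, 50, 100, ... iterations,
50-iteration terminal buffer), restarting the step-size adaptation after
each metric update. Chains start at the MAP. When run through
`polynode()`, the initial inverse mass is set to $1/\mathrm{diag}(I_\theta)$
capped at 1: the cap matters because the prior's nearly-flat directions
have curvature-implied scales of $\sim\alpha$, far beyond the
neighborhood where the log-joint is locally quadratic, and an uncapped
metric stalls the sampler. Warmup draws are discarded; a divergence rate
above 50% is surfaced as a warning on the result.

**Geweke diagnostic** (`geweke()`). For each monitored quantity,
$T = (\bar X_1 - \bar X_2)/\sqrt{s_1^2/n_1 + s_2^2/n_2}$ comparing the
first 10% against the last 50% of the post-burn-in chain, with plain
segment sample variances and a two-sided critical value of 1.964
(level 0.05). It is computed on the *expanded polynomial coefficient*
chains — each stored draw is expanded symbolically — because those are
the identified quantities; raw-parameter chains can be monitored too.
Burn-in defaults to 0 since sampler warmup is already discarded. Note
the statistic ignores autocorrelation by construction (no spectral
correction), so on slowly mixing chains it rejects more often than its
nominal level; this is a property of the diagnostic as defined, not of
the sampler. No effective-sample-size gate is enforced.

**Mean-field VI** (`fit_vi()`, `elbo_estimate()`). The variational
family is a diagonal Gaussian (independent per-parameter means and log
standard deviations); full-covariance Gaussian VI is deliberately not
implemented (keeping a learned covariance positive semidefinite is
fragile for these models, and the mean-field form is the tractable
alternative). The ELBO's expectation term is estimated by averaging the
log-likelihood over reparameterized draws $\theta = \mu + \sigma \circ z$
— chosen for gradient variance and differentiability — and the KL term
against the isotropic Gaussian prior is closed-form. Optimization is
Adam-moderated gradient ascent (`lr = 0.01`), 20 000 iterations by
default (no principled stopping rule exists; the trace is returned so
users can check the plateau). Means initialize from the MAP and scales
from $\sigma = 10^{-3}$: initializing from a point estimate is what
makes VI usable here at all. Known limitation, asserted in the tests:
mean-field variances *underestimate* the marginals of correlated
posteriors, so VI intervals are systematically narrow.

## 4. Coefficient posteriors and predictions

Weights and biases are dependent, so coefficient posteriors are not
analytic transforms of parameter posteriors; closed-form Gaussian
product/sum rules are explicitly not used. `sample_coefficients()`
propagates by Monte Carlo: Gaussian posteriors are sampled natively
(possibly singular covariances via eigendecomposition with negative
eigenvalues clamped at zero); MCMC posteriors reuse their stored draws,
capped at the chain length and thinned evenly. Each draw is expanded
symbolically. The default 2000 draws keeps quantile endpoints stable to
a few percent run-to-run.

Summaries use equal-tailed quantile intervals
($[(1-\gamma)/2,\ 1-(1-\gamma)/2]$ empirical quantiles); HPD intervals
are not implemented (appropriate mainly for skewed posteriors, which
these are not in practice). Default reporting levels are 0.95 and 0.997.
Kernel density summaries use a Gaussian kernel with Scott's-rule
bandwidth, flagging zero-variance samples as point masses.
`posterior_predictive()` evaluates each draw's implied model — the
regression polynomial, or the ODE integrated from a given initial state,
including any known-field augmentation — and reports the pointwise
sample mean with per-level quantile envelopes; draws whose integration
diverges are excluded with a count, and more than 10% exclusions is an
error rather than a silently truncated band.

## 5. GPR pre-smoothing

High-noise observations cannot serve as window initial conditions, so a
Gaussian-process smoother supplies them (`fit_gpr()`,
`initial_conditions()`). Kernels: exp-sine-squared (periodic) for
oscillatory systems, rational quadratic for the damped oscillator and
Lorenz, plus RBF and Matérn-5/2 — each scaled by a constant kernel with
an additive white-noise term that contributes only on the Gram diagonal.
Distance is Euclidean on scalar time. Hyperparameters are fitted by
marginal-likelihood maximization: L-BFGS-B in log space, bounded three
decades around data-driven initial guesses (variance-scaled amplitude,
span-scaled length scale), five random restarts, seeded and
deterministic. One independent GP is fitted per state dimension.

Replicates are pooled in one fit per dimension, and the pooling is
exact, not approximate: replicates share the time grid, so the joint
marginal likelihood factorizes into a GP on the replicate means with
white variance $\sigma^2/R$ plus a within-replicate scatter term in
$\sigma^2$ — the implementation works in that factorized form, which
also keeps the Gram matrix at the size of the unique grid. For long
grids the hyperparameters are optimized on an evenly thinned subset of
at most 400 points (the marginal likelihood is cubic in the grid length
and its optimum is insensitive to this thinning); the final predictive
equations always use the full grid. The smoother interpolates only —
requests outside the training span are errors — and the test suite
asserts the denoising property on the Lotka–Volterra noise setting: the
smoother's RMSE to the truth is below the raw observations'.

## 6. Benchmarks: what the generator emulates, and what it does not

`generate_dataset()` reproduces four synthetic studies: a univariate
cubic $1 + x + 2x^2 + 4x^3$ (200 uniform points on $[-1.25, 1.25]$,
noise variance 9, a single dataset); Lotka–Volterra
$\dot x = 1.5x - xy,\ \dot y = -3y + xy$ from $(1,1)$ (100 points on
$[0,10]$, 10 replicates, noise sd 2); the cubic damped oscillator
$\dot x = -0.1x^3 - 2y^3,\ \dot y = 2x^3 - 0.1y^3$ (500 points on
$[0,25]$, 10 replicates, sd 0.6); and the Lorenz attractor with
$\sigma = 10$, $r = 28$, $b = 8/3$ from $(1,1,1)$ (900 points on
$[0,30]$, 10 replicates, sd 2). Truths come from exact evaluation or
adaptive integration at tolerance $10^{-10}$ (deSolve); noise is
i.i.d. additive Gaussian, independent across replicates, deterministic
per seed. Net degrees follow the right-hand sides: 3 for the cubic and
damped oscillator, 2 for Lotka–Volterra and Lorenz. The missing-term
configuration (`lv_missing_terms`) generates *identical* data to the
full system and differs only in the known field passed to training; the
withheld terms default to the prey growth term $1.5x$ and the predator
interaction term $+xy$ (the choice is configurable; nothing in the
benchmark pins it uniquely).

What the generator does **not** emulate — and hence what passing tests
do not show about real data: noise is purely additive and homoscedastic
(no multiplicative or state-dependent noise), replicates share exact
time grids with no missingness or irregular sampling, the observation
operator is the identity (all states observed), and the true dynamics
are exactly polynomial. Conclusions about misspecified or partially
observed systems require separate evidence.

`blr_posterior()` provides the closed-form conjugate Bayesian linear
regression posterior
$\Sigma_B = (X^\top X/\beta^2 + I/\alpha^2)^{-1}$,
$\mu_B = \Sigma_B X^\top y/\beta^2$ used as the control: on the cubic
problem, posed as linear regression on monomials, every engine can be
compared against it. `coverage_experiment()` repeats the full pipeline
over independently seeded datasets (seeds $1..100$) and reports the
fraction in which the 90%/95% credible intervals contain the generating
coefficients, with exact binomial confidence intervals; BLR on its own
generating model is the calibration reference, and the Laplace engine is
required to track it.

## 7. Problem sizes used in the checks

The test suite and the acceptance script run the full pipelines at
sizes chosen to exercise every stage meaningfully on a single CPU: the
cubic study at its native size (200 points; Laplace and a 1000+1000 NUTS
chain), coverage over the full 100 seeded datasets, and the Lorenz study
at its native scale ($t \in [0, 30]$, 900 points, `substeps = 3`) in the
acceptance script, with the in-suite check on a reduced span
($t \in [0, 20]$, 600 points) and unit tests on correspondingly smaller
Lotka–Volterra problems. Estimates at the reduced sizes are wider than
at the full spans but the identification structure is unchanged.

## 8. Known limitations

- Additive, homoscedastic Gaussian noise only; a single pooled $\beta^2$
  across states and times.
- Fixed-step explicit integration: no stiff systems, no adaptive error
  control, no continuous-time adjoint.
- The Laplace approximation is a single Gaussian at one mode; data with
  genuinely multimodal parameter posteriors (e.g. mixtures of regimes)
  are outside its reach, though the *coefficient* posteriors it implies
  have been the reliable object in practice.
- Mean-field VI is systematically overconfident on correlated
  posteriors.
- The Geweke statistic without spectral correction over-rejects on
  autocorrelated chains.
- Single-chain MCMC workflow: no cross-chain diagnostics.
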