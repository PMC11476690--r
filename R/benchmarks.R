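#' Benchmark experiment specification
#'
#' Bundles a benchmark system with its data-generation and fitting
#' settings.  Defaults reproduce the study conditions of the four synthetic
#' experiments: a univariate cubic (200 points on \[-1.25, 1.25\], noise
#' variance 9), the Lotka-Volterra oscillator (100 points on \[0, 10\], 10
#' replicates, noise sd 2, window 12), the damped oscillator (500 points on
#' \[0, 25\], 10 replicates, noise sd 0.6, window 13), and the Lorenz
#' attractor (900 points on \[0, 30\], 10 replicates, noise sd 2,
#' window 2).
#'
#' @param system One of `"cubic"`, `"lotka_volterra"`, `"damped"`,
#'   `"lorenz"`, `"lv_missing_terms"`.
#' @param ... Overrides for any default field (e.g. `n_points`, `tspan`,
#'   `noise_sd`, `replicates`, `seed`, `window`, `degree`, `params`,
#'   `y0`, `xlim`, `kernel`, and for `lv_missing_terms` the `withheld`
#'   terms).
#' @return A list of class `experiment_spec`.
#' @export
experiment_spec <- function(system = c("cubic", "lotka_volterra", "damped",
                                       "lorenz", "lv_missing_terms"),
                            ...) {
  system <- match.arg(system)
  base <- switch(system,
    cubic = list(params = c(b0 = 1, b1 = 1, b2 = 2, b3 = 4),
                 xlim = c(-1.25, 1.25), n_points = 200L, noise_sd = 3,
                 replicates = 1L, degree = 3L, window = NA_integer_,
                 kernel = NA_character_),
    lotka_volterra = list(params = c(growth = 1.5, predation = 1,
                                     mortality = 3, conversion = 1),
                          y0 = c(x = 1, y = 1), tspan = c(0, 10),
                          n_points = 100L, noise_sd = 2, replicates = 10L,
                          degree = 2L, window = 12L, kernel = "periodic"),
    damped = list(params = c(a11 = -0.1, a12 = -2, a21 = 2, a22 = -0.1),
                  y0 = c(x = 1, y = 1), tspan = c(0, 25), n_points = 500L,
                  noise_sd = 0.6, replicates = 10L, degree = 3L,
                  window = 13L, kernel = "rq"),
    lorenz = list(params = c(sigma = 10, r = 28, b = 8 / 3),
                  y0 = c(x = 1, y = 1, z = 1), tspan = c(0, 30),
                  n_points = 900L, noise_sd = 2, replicates = 10L,
                  degree = 2L, window = 2L, kernel = "rq"),
    lv_missing_terms = {
      lv <- experiment_spec("lotka_volterra")
      out <- unclass(lv)
      out$system <- NULL
      ## withheld by default: the prey growth term 1.5x and the predator
      ## interaction term +xy
      out$withheld <- c("growth", "conversion")
      out
    })
  spec <- utils::modifyList(c(list(system = system, seed = 1L), base),
                            list(...))
  stopifnot(spec$n_points >= 2L, spec$noise_sd >= 0, spec$replicates >= 1L)
  structure(spec, class = "experiment_spec")
}

#' @export
print.experiment_spec <- function(x, ...) {
  cat(sprintf("experiment '%s': %d points, %d replicate(s), noise sd %g\n",
              x$system, x$n_points, x$replicates, x$noise_sd))
  invisible(x)
}

## analytic Jacobians for the true models keep the forward sensitivities of
## known-field augmentation exact
lv_field <- function(p) {
  known_field(
    function(t, y) c(p[["growth"]] * y[1] - p[["predation"]] * y[1] * y[2],
                     -p[["mortality"]] * y[2] +
                       p[["conversion"]] * y[1] * y[2]),
    state_dim = 2L,
    jx = function(t, y) matrix(c(
      p[["growth"]] - p[["predation"]] * y[2], -p[["predation"]] * y[1],
      p[["conversion"]] * y[2],
      -p[["mortality"]] + p[["conversion"]] * y[1]),
      2L, 2L, byrow = TRUE))
}

damped_field <- function(p) {
  known_field(
    function(t, y) c(p[["a11"]] * y[1]^3 + p[["a12"]] * y[2]^3,
                     p[["a21"]] * y[1]^3 + p[["a22"]] * y[2]^3),
    state_dim = 2L,
    jx = function(t, y) matrix(c(3 * p[["a11"]] * y[1]^2,
                                 3 * p[["a12"]] * y[2]^2,
                                 3 * p[["a21"]] * y[1]^2,
                                 3 * p[["a22"]] * y[2]^2),
                               2L, 2L, byrow = TRUE))
}

lorenz_field <- function(p) {
  known_field(
    function(t, y) c(p[["sigma"]] * (y[2] - y[1]),
                     y[1] * (p[["r"]] - y[3]) - y[2],
                     y[1] * y[2] - p[["b"]] * y[3]),
    state_dim = 3L,
    jx = function(t, y) matrix(c(
      -p[["sigma"]], p[["sigma"]], 0,
      p[["r"]] - y[3], -1, -y[1],
      y[2], y[1], -p[["b"]]), 3L, 3L, byrow = TRUE))
}

#' True model of a benchmark system
#'
#' For the ODE systems, returns an `ode_field` evaluating the generating
#' equations exactly (with analytic state Jacobians); for the cubic, a
#' plain regression function of `x`.
#'
#' @param system System id (see [experiment_spec()]).
#' @param params Named parameter vector; defaults to the benchmark values.
#' @return An `ode_field`, or for `"cubic"` a function.
#' @export
true_field <- function(system, params = NULL) {
  if (is.null(params)) params <- experiment_spec(system)$params
  switch(system,
    cubic = function(x) params[[1L]] + params[[2L]] * x +
      params[[3L]] * x^2 + params[[4L]] * x^3,
    lotka_volterra = lv_field(params),
    lv_missing_terms = lv_field(params),
    damped = damped_field(params),
    lorenz = lorenz_field(params),
    stop("unknown system '", system, "'"))
}

#' Known (partial) model for missing-term experiments
#'
#' Returns the benchmark model with the withheld terms removed, i.e. the
#' mechanistic part assumed known; the network is left to learn the rest.
#'
#' @param spec An [experiment_spec()] for `lv_missing_terms`.
#' @return An `ode_field` of the retained terms.
#' @export
known_part <- function(spec) {
  stopifnot(spec$system == "lv_missing_terms")
  p <- spec$params
  p[spec$withheld] <- 0
  lv_field(p)
}

#' Generate a benchmark dataset (noiseless truth + noisy replicates)
#'
#' The truth comes from exact evaluation (cubic) or high-accuracy adaptive
#' integration (tolerance 1e-10); each replicate adds independent
#' `N(0, noise_sd^2)` noise.  Deterministic for a fixed `spec$seed`.
#'
#' @param spec An [experiment_spec()].
#' @return A list of class `pn_dataset` with `truth` (data frame) and
#'   `replicates` (data frame with a `replicate` column).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "experiment_spec"))
  if (spec$system == "cubic") {
    x <- seq(spec$xlim[1L], spec$xlim[2L], length.out = spec$n_points)
    f <- true_field("cubic", spec$params)
    truth <- data.frame(x = x, y = f(x))
    reps <- with_local_seed(spec$seed, {
      do.call(rbind, lapply(seq_len(spec$replicates), function(r) {
        data.frame(x = x, y = truth$y + rnorm(length(x), 0, spec$noise_sd),
                   replicate = r)
      }))
    })
    return(structure(list(truth = truth, replicates = reps, spec = spec),
                     class = "pn_dataset"))
  }
  field <- true_field(spec$system, spec$params)
  times <- seq(spec$tspan[1L], spec$tspan[2L], length.out = spec$n_points)
  sol <- deSolve::ode(y = spec$y0, times = times,
                      func = function(t, y, parms)
                        list(field$fn(t, y)),
                      parms = NULL, method = "ode45",
                      rtol = 1e-10, atol = 1e-10)
  states <- unname(as.matrix(sol[, -1L, drop = FALSE]))
  nm <- names(spec$y0)
  truth <- data.frame(t = times)
  truth[nm] <- as.data.frame(states)
  reps <- with_local_seed(spec$seed, {
    do.call(rbind, lapply(seq_len(spec$replicates), function(r) {
      df <- data.frame(t = times)
      df[nm] <- as.data.frame(states +
        matrix(rnorm(length(states), 0, spec$noise_sd), nrow(states)))
      df$replicate <- r
      df
    }))
  })
  structure(list(truth = truth, replicates = reps, spec = spec),
            class = "pn_dataset")
}

#' @export
print.pn_dataset <- function(x, ...) {
  cat(sprintf("dataset '%s': %d points x %d replicate(s)\n",
              x$spec$system, x$spec$n_points, x$spec$replicates))
  invisible(x)
}

#' Instantaneous signal-to-noise profile of a trajectory
#'
#' Pointwise `|signal| / noise_sd` per time point and state dimension.
#'
#' @param truth Noiseless truth: a data frame (time/x column ignored) or
#'   matrix of signal values.
#' @param noise_sd Noise standard deviation (> 0).
#' @return A list with the `snr` matrix and its `range`.
#' @export
snr_profile <- function(truth, noise_sd) {
  if (noise_sd <= 0) stop("noise_sd must be positive")
  M <- if (is.data.frame(truth))
    as.matrix(truth[setdiff(names(truth), c("t", "x", "replicate"))])
  else as.matrix(truth)
  snr <- abs(M) / noise_sd
  list(snr = snr, range = range(snr))
}

#' Closed-form Bayesian linear regression posterior
#'
#' The conjugate Gaussian posterior for `y = X B + noise` with an isotropic
#' zero-mean Gaussian prior:
#' \deqn{\Sigma_B = (X^T X/\beta^2 + I/\alpha^2)^{-1}, \qquad
#'       \mu_B = \Sigma_B X^T y / \beta^2.}
#' When `beta2` is `NULL` it is approximated by the sample variance of the
#' residuals at the ridge mode (one fixed-point pass starting from
#' `beta2 = 1`).
#'
#' @param X Design matrix.
#' @param y Response vector.
#' @param alpha Prior standard deviation.
#' @param beta2 Observation noise variance, or `NULL` to estimate.
#' @return An object of classes `blr_posterior` and `gaussian_posterior`
#'   with `mean`, `covariance`, `beta2`.
#' @export
blr_posterior <- function(X, y, alpha = 1e5, beta2 = NULL) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) {
    p <- ncol(X)
    out <- gaussian_posterior(rep(0, p), diag(alpha^2, p))
    out$beta2 <- beta2
    class(out) <- c("blr_posterior", class(out))
    return(out)
  }
  stopifnot(nrow(X) == length(y))
  post_for <- function(b2) {
    S <- solve(crossprod(X) / b2 + diag(1 / alpha^2, ncol(X)))
    S <- (S + t(S)) / 2
    list(mean = drop(S %*% crossprod(X, y)) / b2, cov = S)
  }
  if (is.null(beta2)) {
    mode0 <- post_for(1)$mean
    beta2 <- estimate_noise_variance(drop(X %*% mode0) - y)
  }
  pp <- post_for(beta2)
  out <- gaussian_posterior(pp$mean, pp$cov)
  out$beta2 <- beta2
  class(out) <- c("blr_posterior", class(out))
  out
}

## equal-tailed interval of a Gaussian marginal
gaussian_interval <- function(mean, sd, level) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(mean - z * sd, mean + z * sd)
}

#' Credible-interval coverage study on the cubic benchmark
#'
#' Repeats the full inference pipeline over independently generated
#' datasets (seeds `1..n_datasets` by default), records for each expanded
#' polynomial coefficient whether the equal-tailed credible interval at
#' each level contains the generating value, and aggregates the coverage
#' fractions with exact binomial confidence intervals.
#'
#' @param method `"blr"`, `"laplace"`, `"nuts"`, `"hmc"`, or `"vi"`.
#' @param spec A cubic [experiment_spec()].
#' @param n_datasets Number of datasets (default 100).
#' @param seeds Dataset seeds (default `1..n_datasets`).
#' @param levels Credible levels (default 0.90 and 0.95).
#' @param n_samples Monte Carlo draws for coefficient propagation
#'   (network methods).
#' @param conf Confidence level of the binomial interval (default 0.99).
#' @param hidden Hidden width of the pi-net (network methods).
#' @return A data frame of class `coverage_result`: one row per
#'   (level, coefficient) with `coverage`, binomial `lo`/`hi`, and the
#'   number of successful datasets `n`.
#' @export
coverage_experiment <- function(method = c("blr", "laplace", "nuts", "hmc",
                                           "vi"),
                                spec = experiment_spec("cubic"),
                                n_datasets = 100L,
                                seeds = seq_len(n_datasets),
                                levels = c(0.90, 0.95),
                                n_samples = 1000L, conf = 0.99,
                                hidden = 10L) {
  method <- match.arg(method)
  stopifnot(spec$system == "cubic")
  truth <- unname(spec$params)
  labels <- c("1", "x", "x^2", "x^3")
  hits <- array(NA, c(length(seeds), length(levels), 4L))
  failures <- 0L
  for (i in seq_along(seeds)) {
    res <- tryCatch(
      coverage_one(method, spec, seeds[i], levels, n_samples, hidden),
      error = function(e) NULL)
    if (is.null(res)) { failures <- failures + 1L; next }
    for (l in seq_along(levels))
      hits[i, l, ] <- res[[l]][1L, ] <= truth & truth <= res[[l]][2L, ]
  }
  if (failures > 0.10 * length(seeds))
    stop(failures, " of ", length(seeds), " datasets failed")
  rows <- do.call(rbind, lapply(seq_along(levels), function(l) {
    do.call(rbind, lapply(1:4, function(k) {
      h <- hits[, l, k]; h <- h[!is.na(h)]
      bt <- stats::binom.test(sum(h), length(h), conf.level = conf)
      data.frame(method = method, level = levels[l],
                 coefficient = labels[k],
                 coverage = mean(h), lo = bt$conf.int[1L],
                 hi = bt$conf.int[2L], n = length(h))
    }))
  }))
  structure(rows, class = c("coverage_result", "data.frame"),
            failures = failures)
}

## one dataset -> per-level 2 x 4 matrices of interval endpoints for the
## coefficients of 1, x, x^2, x^3
coverage_one <- function(method, spec, seed, levels, n_samples, hidden) {
  spec$seed <- seed
  ds <- generate_dataset(spec)
  x <- ds$replicates$x; y <- ds$replicates$y
  if (method == "blr") {
    X <- cbind(1, x, x^2, x^3)
    post <- blr_posterior(X, y)
    sds <- sqrt(diag(post$covariance))
    return(lapply(levels, function(lv)
      vapply(1:4, function(k) gaussian_interval(post$mean[k], sds[k], lv),
             numeric(2))))
  }
  config <- pinet_config(1L, 1L, spec$degree, hidden)
  model <- pn_regression(config, matrix(x, ncol = 1L), y)
  map <- train_map(model, seed = seed)
  post <- switch(method,
    laplace = laplace_posterior(
      map$theta_star,
      fisher_information(map$theta_star, model, map$beta2)),
    nuts = sample_nuts(pn_logjoint(model, map$beta2), map$theta_star,
                       seed = seed),
    hmc = sample_hmc(pn_logjoint(model, map$beta2), map$theta_star,
                     seed = seed),
    vi = fit_vi(pn_loglik(model, map$beta2), map$theta_star, seed = seed))
  cs <- sample_coefficients(post, config, n_samples = n_samples,
                            seed = seed)
  S <- cs$samples[[1L]]
  lapply(levels, function(lv)
    vapply(1:4, function(k) quantile_interval(S[, k], lv), numeric(2)))
}
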