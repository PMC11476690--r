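#' Mean-field Gaussian variational family
#'
#' Independent Gaussians over all parameters, parameterized by a mean vector
#' and a log-standard-deviation vector.
#'
#' @param mean Per-parameter mean vector.
#' @param log_sd Per-parameter log standard deviation (scalar recycled).
#' @return An object of class `mean_field_gaussian`.
#' @export
mean_field_gaussian <- function(mean, log_sd = log(1e-3)) {
  if (length(log_sd) == 1L) log_sd <- rep(log_sd, length(mean))
  stopifnot(length(log_sd) == length(mean),
            all(is.finite(mean)), all(is.finite(log_sd)))
  structure(list(mean = mean, log_sd = log_sd),
            class = "mean_field_gaussian")
}

#' @export
print.mean_field_gaussian <- function(x, ...) {
  cat(sprintf("mean-field Gaussian over %d parameters\n", length(x$mean)))
  invisible(x)
}

#' Convert a mean-field Gaussian to a (diagonal) Gaussian posterior
#'
#' @param x A [mean_field_gaussian()].
#' @param ... Unused.
#' @return A diagonal [gaussian_posterior()].
#' @export
as_gaussian_posterior <- function(x, ...) {
  stopifnot(inherits(x, "mean_field_gaussian"))
  gaussian_posterior(x$mean, exp(2 * x$log_sd))
}

## closed-form KL( N(mu, diag(sd^2)) || N(0, alpha^2 I) )
kl_mean_field <- function(mean, log_sd, alpha) {
  sd2 <- exp(2 * log_sd)
  sum(log(alpha) - log_sd + (sd2 + mean^2) / (2 * alpha^2) - 0.5)
}

#' Variational-inference settings
#'
#' @param lr Learning rate for the (Adam-moderated) gradient ascent of the
#'   ELBO (default 0.01).
#' @param iterations Optimization iterations (default 20000).
#' @param n_mc Monte Carlo draws per ELBO / gradient estimate
#'   (default 1000).
#' @param init_log_sd Initial log standard deviation (default `log(1e-3)`:
#'   the variational means start at a point estimate and the scales start
#'   small).
#' @return A list of class `vi_settings`.
#' @export
vi_settings <- function(lr = 0.01, iterations = 20000L, n_mc = 1000L,
                        init_log_sd = log(1e-3)) {
  stopifnot(lr > 0, iterations >= 1, n_mc >= 1)
  structure(list(lr = lr, iterations = as.integer(iterations),
                 n_mc = as.integer(n_mc), init_log_sd = init_log_sd),
            class = "vi_settings")
}

## evaluate a log-likelihood callable on a matrix of draws.
## vectorized targets accept the whole matrix; otherwise loop rows.
loglik_batch <- function(loglik, Theta, vectorized) {
  if (vectorized) {
    out <- loglik(Theta)
    stopifnot(length(out$value) == nrow(Theta))
    return(out)
  }
  vals <- numeric(nrow(Theta))
  grads <- matrix(0, nrow(Theta), ncol(Theta))
  for (s in seq_len(nrow(Theta))) {
    o <- loglik(Theta[s, ])
    vals[s] <- o$value
    grads[s, ] <- o$grad
  }
  list(value = vals, grad = grads)
}

#' Monte Carlo ELBO estimate
#'
#' \eqn{ELBO = E_q[\log p(D|\theta)] - KL(q \| p_r)}: the expectation term
#' is estimated by averaging the log-likelihood over `n_mc` reparameterized
#' draws \eqn{\theta = \mu + \sigma \circ z}; the KL between the diagonal
#' Gaussian `q` and the isotropic Gaussian prior is computed in closed form.
#'
#' @param q A [mean_field_gaussian()].
#' @param loglik Function `theta -> list(value, grad)` returning the
#'   log-likelihood and its gradient (see [pn_loglik()]); with
#'   `vectorized = TRUE` it receives an `n_mc x p` matrix and returns
#'   vectorized values/gradients.
#' @param prior A [prior_spec()].
#' @param n_mc Number of Monte Carlo draws.
#' @param seed Seed for the draws.
#' @param vectorized Whether `loglik` accepts a matrix of draws.
#' @return Scalar ELBO estimate.
#' @export
elbo_estimate <- function(q, loglik, prior = prior_spec(), n_mc = 1000L,
                          seed = 1L, vectorized = FALSE) {
  stopifnot(inherits(q, "mean_field_gaussian"), n_mc >= 1)
  p <- length(q$mean)
  with_local_seed(seed, {
    Z <- matrix(rnorm(n_mc * p), n_mc, p)
    Theta <- sweep(Z, 2L, exp(q$log_sd), `*`) +
      matrix(q$mean, n_mc, p, byrow = TRUE)
    lb <- loglik_batch(loglik, Theta, vectorized)
    if (any(!is.finite(lb$value)))
      stop("non-finite log-likelihood at a variational draw")
    mean(lb$value) - kl_mean_field(q$mean, q$log_sd, prior$alpha)
  })
}

#' Log-likelihood callable (with gradient) for a pi-net model
#'
#' Like [pn_logjoint()] but without the prior term, for use with the
#' variational engine whose KL term absorbs the prior in closed form.
#'
#' @inheritParams pn_logjoint
#' @return A function `theta -> list(value, grad)`.
#' @export
pn_loglik <- function(model, beta2) {
  stopifnot(beta2 > 0)
  function(theta) {
    sg <- model_sse_grad(model, theta)
    list(value = -sg$sse / (2 * beta2), grad = -sg$grad / (2 * beta2))
  }
}

#' Mean-field Gaussian variational inference
#'
#' Maximizes the Monte Carlo ELBO over the per-parameter means and log
#' standard deviations using reparameterization gradients and Adam.  The
#' variational means are initialized from a point estimate (`init_mean`,
#' typically the MAP) and the scales start small -- initializing from a
#' point fit is what makes VI practical for these models.
#'
#' @param loglik Log-likelihood callable as in [elbo_estimate()].
#' @param init_mean Initial mean vector (typically `theta_star`).
#' @param prior A [prior_spec()].
#' @param settings A [vi_settings()].
#' @param seed Seed; the fit is deterministic given it.
#' @param vectorized Whether `loglik` accepts a matrix of draws.
#' @return A diagonal [gaussian_posterior()] with attributes
#'   `elbo_trace` (per-iteration ELBO estimates) and `q` (the fitted
#'   [mean_field_gaussian()]).
#' @export
fit_vi <- function(loglik, init_mean, prior = prior_spec(),
                   settings = vi_settings(), seed = 1L,
                   vectorized = FALSE) {
  p <- length(init_mean)
  mu <- init_mean
  ls <- rep(settings$init_log_sd, p)
  a2 <- prior$alpha^2
  m1m <- v1m <- numeric(p); m1s <- v1s <- numeric(p)
  b1 <- 0.9; b2 <- 0.999; epsa <- 1e-8
  trace <- numeric(settings$iterations)
  with_local_seed(seed, {
    for (it in seq_len(settings$iterations)) {
      sd <- exp(ls)
      Z <- matrix(rnorm(settings$n_mc * p), settings$n_mc, p)
      Theta <- sweep(Z, 2L, sd, `*`) + matrix(mu, settings$n_mc, p,
                                              byrow = TRUE)
      lb <- loglik_batch(loglik, Theta, vectorized)
      if (any(!is.finite(lb$value)))
        stop("ELBO became non-finite at iteration ", it)
      elbo <- mean(lb$value) - kl_mean_field(mu, ls, prior$alpha)
      trace[it] <- elbo
      gmu <- colMeans(lb$grad) - mu / a2
      gls <- colMeans(lb$grad * sweep(Z, 2L, sd, `*`)) + 1 - sd^2 / a2
      ## Adam ascent
      m1m <- b1 * m1m + (1 - b1) * gmu
      v1m <- b2 * v1m + (1 - b2) * gmu^2
      mu <- mu + settings$lr * (m1m / (1 - b1^it)) /
        (sqrt(v1m / (1 - b2^it)) + epsa)
      m1s <- b1 * m1s + (1 - b1) * gls
      v1s <- b2 * v1s + (1 - b2) * gls^2
      ls <- ls + settings$lr * (m1s / (1 - b1^it)) /
        (sqrt(v1s / (1 - b2^it)) + epsa)
    }
    q <- mean_field_gaussian(mu, ls)
    post <- as_gaussian_posterior(q)
    attr(post, "elbo_trace") <- trace
    attr(post, "q") <- q
    post
  })
}
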