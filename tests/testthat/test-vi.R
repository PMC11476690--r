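test_that("the KL term vanishes when q equals the prior and matches the closed form", {
  q0 <- mean_field_gaussian(c(0, 0), log(c(2, 2)))
  zero_ll <- function(th) list(value = 0, grad = c(0, 0))
  expect_equal(elbo_estimate(q0, zero_ll, prior_spec(2), n_mc = 3,
                             seed = 1), 0)
  # KL( N(1, 2^2) || N(0, 1) ) in closed form, via a zero likelihood
  q1 <- mean_field_gaussian(1, log(2))
  kl <- -elbo_estimate(q1, function(th) list(value = 0, grad = 0),
                       prior_spec(1), n_mc = 3, seed = 1)
  expect_equal(kl, log(1 / 2) + (4 + 1) / 2 - 0.5, tolerance = 1e-12)
})

test_that("the ELBO at the exact conjugate posterior approaches the evidence", {
  set.seed(2)
  n <- 30; s2 <- 2; a2 <- 9
  y <- rnorm(n, 1, sqrt(s2))
  post_var <- 1 / (n / s2 + 1 / a2)
  post_mean <- post_var * sum(y) / s2
  ll <- function(th) list(value = -sum((y - th)^2) / (2 * s2),
                          grad = sum(y - th) / s2)
  q <- mean_field_gaussian(post_mean, 0.5 * log(post_var))
  elbo <- elbo_estimate(q, ll, prior_spec(3), n_mc = 4000, seed = 3)
  # log evidence up to the same likelihood constant
  evidence <- -0.5 * sum(y^2) / s2 + 0.5 * post_mean^2 / post_var +
    0.5 * log(post_var / a2)
  expect_lte(elbo, evidence + 0.05)
  expect_gt(elbo, evidence - 0.05)
})

test_that("VI recovers a 1-parameter conjugate posterior", {
  set.seed(4)
  n <- 50; s2 <- 4; a2 <- 100
  y <- rnorm(n, 2.5, sqrt(s2))
  post_var <- 1 / (n / s2 + 1 / a2)
  post_mean <- post_var * sum(y) / s2
  ll <- function(th) list(value = -sum((y - th)^2) / (2 * s2),
                          grad = sum(y - th) / s2)
  fit <- fit_vi(ll, init_mean = mean(y), prior = prior_spec(sqrt(a2)),
                settings = vi_settings(iterations = 3000, n_mc = 100),
                seed = 9)
  expect_lt(abs(fit$mean - post_mean) / abs(post_mean), 0.02)
  expect_lt(abs(fit$covariance - post_var) / post_var, 0.10)
})

test_that("mean-field variances underestimate correlated-posterior marginals", {
  set.seed(5)
  X <- cbind(1, rnorm(40, 1, 0.1))        # strongly collinear design
  y <- drop(X %*% c(1, 2)) + rnorm(40)
  bp <- blr_posterior(X, y, alpha = 10, beta2 = 1)
  llv <- function(Th) {
    r <- matrix(y, nrow(Th), 40, byrow = TRUE) - Th %*% t(X)
    list(value = -rowSums(r^2) / 2, grad = r %*% X)
  }
  fit <- fit_vi(llv, bp$mean, prior = prior_spec(10),
                settings = vi_settings(iterations = 3000, n_mc = 100),
                seed = 9, vectorized = TRUE)
  expect_true(all(fit$covariance <= diag(bp$covariance)))
})

test_that("with negligible data the posterior collapses to the prior", {
  ll <- function(th) list(value = -(th - 2)^2 / (2 * 1e6),
                          grad = (2 - th) / 1e6)
  fit <- fit_vi(ll, 0, prior = prior_spec(2),
                settings = vi_settings(iterations = 2000, n_mc = 50,
                                       init_log_sd = 0),
                seed = 6)
  expect_lt(abs(fit$mean), 0.2)
  expect_lt(abs(sqrt(fit$covariance) - 2) / 2, 0.1)
})

test_that("the ELBO trace is non-decreasing near convergence", {
  set.seed(7)
  y <- rnorm(20, 1)
  ll <- function(th) list(value = -sum((y - th)^2) / 2,
                          grad = sum(y - th))
  fit <- fit_vi(ll, 0, prior = prior_spec(5),
                settings = vi_settings(iterations = 2000, n_mc = 200),
                seed = 7)
  tr <- attr(fit, "elbo_trace")
  late <- tr[seq(0.9 * length(tr), length(tr))]
  expect_lt(diff(range(late)), 0.5)       # plateau within MC noise
})

test_that("more Monte Carlo draws shrink the ELBO estimator noise as sqrt(n)", {
  set.seed(8)
  y <- rnorm(20, 1)
  ll <- function(th) list(value = -sum((y - th)^2) / 2,
                          grad = sum(y - th))
  q <- mean_field_gaussian(1, log(0.3))
  est <- function(n_mc) vapply(1:30, function(s)
    elbo_estimate(q, ll, prior_spec(5), n_mc = n_mc, seed = 1000 + s),
    numeric(1))
  ratio <- sd(est(10)) / sd(est(1000))
  expect_gt(ratio, 5)
  expect_lt(ratio, 20)
})

test_that("mean-field fits convert to diagonal Gaussian posteriors", {
  q <- mean_field_gaussian(c(1, -1), log(c(0.5, 2)))
  post <- as_gaussian_posterior(q)
  expect_true(post$diagonal)
  expect_equal(post$covariance, c(0.25, 4))
  expect_error(mean_field_gaussian(c(1, NA)), "finite")
})
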