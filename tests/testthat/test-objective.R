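test_that("log-likelihood is the scaled sum of squared residuals", {
  expect_equal(log_likelihood(1:5, 1:5, 2), 0)
  expect_equal(log_likelihood(3, 1, 1), -2)
  set.seed(1)
  r <- rnorm(50); beta2 <- 2.5
  oracle <- sum(dnorm(r, 0, sqrt(beta2), log = TRUE)) +
    50 * 0.5 * log(2 * pi * beta2)
  expect_equal(log_likelihood(r, numeric(50), beta2), oracle,
               tolerance = 1e-10)
  expect_error(log_likelihood(1, 1, 0), "positive")
})

test_that("log-prior is the isotropic Gaussian quadratic form", {
  expect_equal(log_prior(numeric(5)), 0)
  expect_equal(log_prior(3, prior_spec(1)), -4.5)
  set.seed(2)
  th <- rnorm(20); a <- 7
  expect_equal(log_prior(th, prior_spec(a)), -sum(th^2 / (2 * a^2)))
})

test_that("log-joint is additive and decreases with residual size", {
  set.seed(3)
  th <- rnorm(10); r <- rnorm(30)
  expect_equal(log_joint(r, numeric(30), th, 1.3, prior_spec(2)),
               log_likelihood(r, numeric(30), 1.3) +
                 log_prior(th, prior_spec(2)))
  expect_equal(log_joint(numeric(3), numeric(3), numeric(2), 1,
                         prior_spec(1)), 0)
  expect_lt(log_joint(2 * r, numeric(30), th, 1.3, prior_spec(2)),
            log_joint(r, numeric(30), th, 1.3, prior_spec(2)))
})

test_that("noise-variance estimation is the n-denominator sample variance", {
  expect_equal(estimate_noise_variance(rep(3, 10)), 0)
  expect_equal(estimate_noise_variance(c(-1, 1)), 1)
  set.seed(4)
  r <- rnorm(1e5, 0, 3)
  expect_lt(abs(estimate_noise_variance(r) - 9) / 9, 0.05)
  expect_error(estimate_noise_variance(1), "at least 2")
})

test_that("MAP training recovers a noiseless cubic via the OLS oracle", {
  ds <- generate_dataset(experiment_spec("cubic", n_points = 80,
                                         noise_sd = 0, seed = 2))
  cfg <- pinet_config(1, 1, 3, 10)
  model <- pn_regression(cfg, matrix(ds$replicates$x), ds$replicates$y)
  map <- train_map(model, seed = 2)
  co <- drop(expand_to_polynomial(map$theta_star, cfg)$coefficients)
  expect_lt(max(abs(co - c(1, 1, 2, 4))), 1e-2)
})

test_that("trained expanded coefficients match the ridge/OLS mode", {
  fix <- tiny_cubic(n = 100, noise_sd = 2, seed = 5)
  cfg <- pinet_config(1, 1, 3, 10)
  model <- pn_regression(cfg, fix$x, fix$y)
  ols <- qr.solve(cbind(1, fix$x, fix$x^2, fix$x^3), fix$y)
  for (opt in c("lm", "adam")) {
    map <- train_map(model, control = map_control(opt), seed = 5)
    co <- drop(expand_to_polynomial(map$theta_star, cfg)$coefficients)
    expect_lt(max(abs(co - ols) / abs(ols)), 1e-4)
  }
})

test_that("linear models reproduce the closed-form ridge mode exactly", {
  set.seed(6)
  X <- cbind(1, rnorm(50), rnorm(50))
  y <- drop(X %*% c(1, 2, -1)) + rnorm(50)
  map <- train_map(pn_linear(X, y), prior = prior_spec(3))
  ridge <- solve(crossprod(X) + diag(1 / (2 * 9), 3), crossprod(X, y))
  expect_lt(max(abs(map$theta_star - ridge) / abs(ridge)), 1e-4)
})

test_that("a much tighter prior strictly shrinks the MAP norm", {
  fix <- tiny_cubic(n = 60, noise_sd = 1, seed = 7)
  cfg <- pinet_config(1, 1, 3, 6)
  model <- pn_regression(cfg, fix$x, fix$y)
  wide <- train_map(model, prior = prior_spec(1e5), seed = 7)
  tight <- train_map(model, prior = prior_spec(1e5 / 1e6), seed = 7)
  expect_lt(sum(tight$theta_star^2), sum(wide$theta_star^2))
})

test_that("the objective trace is non-worsening at the end of training", {
  fix <- tiny_cubic(n = 60, noise_sd = 1, seed = 8)
  cfg <- pinet_config(1, 1, 3, 6)
  model <- pn_regression(cfg, fix$x, fix$y)
  map <- train_map(model, control = map_control("adam", epochs = 2000),
                   seed = 8)
  tail10 <- tail(map$trace, 200)
  expect_lt(max(tail10) - min(tail10), 1e-3 * abs(map$value) + 1e-8)
  expect_true(all(is.finite(map$trace)))
})

test_that("objective value is invariant to window ordering", {
  spec <- experiment_spec("lotka_volterra", n_points = 20, noise_sd = 0.1,
                          replicates = 1, seed = 9)
  ds <- generate_dataset(spec)
  b <- make_batches(ds$replicates, 5)
  cfg <- pinet_config(2, 2, 2, 3)
  model <- pn_ode_model(pinet_field(cfg), b, substeps = 3)
  theta <- pinet_pack(random_params(cfg, 9, 0.1), cfg)
  r1 <- polynode:::model_residuals(model, theta)$r
  perm <- rev(seq_len(b$n_windows))
  b2 <- b
  b2$y0 <- b$y0[perm, , drop = FALSE]
  b2$times <- b$times[perm, , drop = FALSE]
  b2$targets <- b$targets[perm, , , , drop = FALSE]
  model2 <- pn_ode_model(pinet_field(cfg), b2, substeps = 3)
  r2 <- polynode:::model_residuals(model2, theta)$r
  expect_equal(sum(r1^2), sum(r2^2), tolerance = 1e-12)
})

test_that("noiseless Lotka-Volterra ODE training recovers the equations", {
  spec <- experiment_spec("lotka_volterra", n_points = 40, noise_sd = 0,
                          replicates = 1, seed = 1)
  ds <- generate_dataset(spec)
  b <- make_batches(ds$replicates, 8)
  cfg <- pinet_config(2, 2, 2, 6)
  model <- pn_ode_model(pinet_field(cfg), b, substeps = 4)
  map <- suppressWarnings(
    train_map(model, control = map_control(maxit = 120), seed = 1))
  co <- expand_to_polynomial(map$theta_star, cfg)$coefficients
  truth <- rbind(c(0, 1.5, 0, 0, -1, 0), c(0, 0, -3, 0, 1, 0))
  nz <- truth != 0
  expect_lt(max(abs(co[nz] - truth[nz]) / abs(truth[nz])), 0.05)
  expect_lt(max(abs(co[!nz])), 0.05)
})
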