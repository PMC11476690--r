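test_that("a zero-covariance posterior propagates to a point mass at the mean expansion", {
  cfg <- pinet_config(1, 1, 2, 3)
  theta <- pinet_pack(random_params(cfg, 1), cfg)
  post <- gaussian_posterior(theta, diag(0, length(theta)))
  cs <- sample_coefficients(post, cfg, n_samples = 50, seed = 1)
  expected <- drop(expand_to_polynomial(theta, cfg)$coefficients)
  for (s in 1:50)
    expect_equal(unname(cs$samples$f1[s, ]), unname(expected))
})

test_that("coefficient-sample moments match direct Monte Carlo propagation", {
  cfg <- pinet_config(1, 1, 1, 2)           # 9 parameters, nonlinear map
  theta <- pinet_pack(random_params(cfg, 2, 0.5), cfg)
  p <- length(theta)
  set.seed(3)
  Sig <- crossprod(matrix(rnorm(p * p, 0, 0.05), p))
  post <- gaussian_posterior(theta, Sig)
  cs <- sample_coefficients(post, cfg, n_samples = 4000, seed = 4)
  # independent oracle: fresh draws + per-draw expansion
  set.seed(99)
  Th <- MASS::mvrnorm(4000, theta, Sig)
  oracle <- t(apply(Th, 1, function(tt)
    drop(expand_to_polynomial(tt, cfg)$coefficients)))
  for (k in seq_len(ncol(oracle))) {
    se <- sd(oracle[, k]) / sqrt(4000)
    expect_lt(abs(mean(cs$samples$f1[, k]) - mean(oracle[, k])), 5 * se)
    expect_lt(abs(sd(cs$samples$f1[, k]) / sd(oracle[, k]) - 1), 0.1)
  }
})

test_that("chain posteriors reuse stored draws, capped at chain length", {
  cfg <- pinet_config(1, 1, 1, 1)           # 5 parameters
  p <- count_parameters(cfg)
  draws <- matrix(rnorm(40 * p), 40, p)
  ch <- structure(list(draws = draws, warmup = 0, algorithm = "nuts"),
                  class = "chain_samples")
  cs <- sample_coefficients(ch, cfg, n_samples = 1000, seed = 1)
  expect_identical(nrow(cs$samples$f1), 40L)
  expect_equal(unname(cs$samples$f1[7, ]),
               unname(drop(expand_to_polynomial(draws[7, ],
                                                cfg)$coefficients)))
  expect_error(sample_coefficients(ch, pinet_config(2, 2, 2, 4)),
               "parameters")
})

test_that("quantile intervals are equal-tailed and calibrated", {
  set.seed(5)
  z <- rnorm(1e6)
  qi <- quantile_interval(z, 0.95)
  expect_lt(abs(qi[1] + 1.96), 0.02)
  expect_lt(abs(qi[2] - 1.96), 0.02)
  expect_equal(quantile_interval(rep(2, 10), 0.9), c(2, 2))
  wide <- quantile_interval(z, 1 - 1e-9)
  expect_equal(wide, range(z), tolerance = 1e-4)
  expect_error(quantile_interval(z, 1.2), "level")
  # empirical coverage matches nominal within binomial error at n = 10000
  set.seed(6)
  x <- rnorm(10000)
  qi90 <- quantile_interval(x, 0.90)
  cover <- mean(x >= qi90[1] & x <= qi90[2])
  expect_lt(abs(cover - 0.90), 3 * sqrt(0.9 * 0.1 / 10000) + 2e-4)
})

test_that("posterior predictive bands are degenerate at a point posterior and nest", {
  cfg <- pinet_config(1, 1, 3, 4)
  theta <- pinet_pack(random_params(cfg, 7), cfg)
  post <- gaussian_posterior(theta, diag(0, length(theta)))
  grid <- seq(-1, 1, length.out = 11)
  band <- posterior_predictive(post, cfg, newdata = grid,
                               n_samples = 30, seed = 1)
  truth <- pinet_forward(theta, cfg, matrix(grid))
  expect_equal(band$mean[, 1], drop(truth))
  expect_equal(band$lower[[1]], band$upper[[1]], tolerance = 1e-12)

  post2 <- gaussian_posterior(theta, diag(1e-4, length(theta)))
  band2 <- posterior_predictive(post2, cfg, newdata = grid,
                                levels = c(0.95, 0.997),
                                n_samples = 400, seed = 2)
  expect_true(all(band2$lower[["0.997"]] <= band2$lower[["0.95"]]))
  expect_true(all(band2$upper[["0.997"]] >= band2$upper[["0.95"]]))
  expect_true(all(band2$lower[["0.95"]] <= band2$mean))
  expect_true(all(band2$upper[["0.95"]] >= band2$mean))
})

test_that("95% bands from a fitted cubic cover the true function pointwise", {
  fix <- tiny_cubic(n = 120, noise_sd = 2, seed = 8)
  cfg <- pinet_config(1, 1, 3, 10)
  model <- pn_regression(cfg, fix$x, fix$y)
  map <- train_map(model, seed = 8)
  post <- laplace_posterior(
    map$theta_star, fisher_information(map$theta_star, model, map$beta2))
  fresh <- seq(-1.2, 1.2, length.out = 50)
  band <- posterior_predictive(post, cfg, newdata = fresh,
                               levels = 0.95, n_samples = 1000, seed = 8)
  truth <- 1 + fresh + 2 * fresh^2 + 4 * fresh^3
  covered <- mean(band$lower[[1]][, 1] <= truth &
                    truth <= band$upper[[1]][, 1])
  expect_gte(covered, 0.85)
})

test_that("ODE predictive bands integrate each posterior draw", {
  cfg <- pinet_config(2, 2, 2, 4)
  spec <- experiment_spec("lotka_volterra", n_points = 25, noise_sd = 0,
                          replicates = 1, seed = 2)
  ds <- generate_dataset(spec)
  b <- make_batches(ds$replicates, 6)
  map <- suppressWarnings(
    train_map(pn_ode_model(pinet_field(cfg), b, substeps = 3), seed = 2))
  post <- gaussian_posterior(map$theta_star,
                             diag(0, length(map$theta_star)))
  grid <- seq(0, 5, length.out = 21)
  band <- posterior_predictive(post, cfg, y0 = c(1, 1), grid = grid,
                               n_samples = 10, seed = 3, substeps = 3)
  direct <- integrate_rkf45(pinet_field(cfg), map$theta_star, c(1, 1),
                            grid, substeps = 3)
  expect_equal(band$mean, direct$states, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("density summaries integrate to one and find the mode", {
  set.seed(9)
  z <- rnorm(5000)
  ds <- density_summary(z)
  expect_false(ds$point_mass)
  expect_lt(abs(sum(ds$density) * diff(ds$grid[1:2]) - 1), 0.01)
  expect_lt(abs(ds$grid[which.max(ds$density)]), 0.15)
  shifted <- density_summary(z + 3)
  expect_lt(abs(shifted$grid[which.max(shifted$density)] - 3), 0.15)
  pm <- density_summary(rep(1.5, 10))
  expect_true(pm$point_mass)
  expect_equal(pm$value, 1.5)
})
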