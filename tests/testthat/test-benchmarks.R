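test_that("true fields evaluate the benchmark equations exactly", {
  lv <- true_field("lotka_volterra")
  expect_equal(lv$fn(0, c(3, 1.5)), c(0, 0))       # coexistence equilibrium
  expect_equal(lv$fn(0, c(1, 1)), c(0.5, -2))
  lorenz <- true_field("lorenz")
  expect_equal(lorenz$fn(0, c(0, 0, 0)), c(0, 0, 0))
  expect_equal(lorenz$fn(0, c(1, 2, 3)), c(10, 25 - 2, 2 - 8))
  damped <- true_field("damped")
  expect_equal(damped$fn(0, c(1, 1)), c(-2.1, 1.9))
  expect_error(true_field("unknown"))
  cubic <- true_field("cubic")
  expect_equal(cubic(0), 1)
  expect_equal(cubic(2), 1 + 2 + 8 + 32)
})

test_that("analytic field Jacobians agree with numerical differentiation", {
  for (sys in c("lotka_volterra", "damped", "lorenz")) {
    f <- true_field(sys)
    y <- if (f$state_dim == 2) c(1.3, 0.7) else c(1.3, 0.7, 2.1)
    J <- f$jx(0, y)
    eps <- 1e-6
    for (b in seq_along(y)) {
      yp <- y; yp[b] <- yp[b] + eps
      ym <- y; ym[b] <- ym[b] - eps
      expect_equal(J[, b], (f$fn(0, yp) - f$fn(0, ym)) / (2 * eps),
                   tolerance = 1e-6)
    }
  }
})

test_that("the cubic dataset honours the documented grid and truth", {
  ds <- generate_dataset(experiment_spec("cubic", seed = 1))
  expect_identical(nrow(ds$truth), 200L)
  expect_equal(range(ds$truth$x), c(-1.25, 1.25))
  expect_equal(ds$truth$y[which.min(abs(ds$truth$x))][1],
               true_field("cubic")(ds$truth$x[which.min(abs(ds$truth$x))]))
  expect_equal(ds$truth$y[1], 1 - 1.25 + 2 * 1.25^2 - 4 * 1.25^3)
})

test_that("ODE datasets have the configured sizes and replicate structure", {
  ds <- generate_dataset(experiment_spec("lotka_volterra", n_points = 30,
                                         replicates = 4, seed = 2))
  expect_identical(nrow(ds$truth), 30L)
  expect_identical(nrow(ds$replicates), 120L)
  expect_equal(range(ds$truth$t), c(0, 10))
  # default study conditions
  for (sys in c("lotka_volterra", "damped", "lorenz")) {
    spec <- experiment_spec(sys)
    expect_identical(spec$n_points,
                     c(lotka_volterra = 100L, damped = 500L,
                       lorenz = 900L)[[sys]])
    expect_identical(spec$replicates, 10L)
  }
  expect_identical(experiment_spec("cubic")$n_points, 200L)
})

test_that("zero noise reproduces the truth; noise has the nominal scale", {
  ds0 <- generate_dataset(experiment_spec("lotka_volterra", n_points = 20,
                                          noise_sd = 0, replicates = 2,
                                          seed = 3))
  r1 <- ds0$replicates[ds0$replicates$replicate == 1, c("x", "y")]
  expect_equal(as.matrix(r1), as.matrix(ds0$truth[c("x", "y")]),
               ignore_attr = TRUE)
  dsn <- generate_dataset(experiment_spec("cubic", n_points = 10000,
                                          noise_sd = 3, seed = 4))
  resid <- dsn$replicates$y - dsn$truth$y
  expect_lt(abs(sd(resid) - 3) / 3, 0.03)
})

test_that("datasets are deterministic per seed", {
  a <- generate_dataset(experiment_spec("lorenz", n_points = 15, seed = 5))
  b <- generate_dataset(experiment_spec("lorenz", n_points = 15, seed = 5))
  expect_identical(a$replicates, b$replicates)
})

test_that("the missing-term configuration shares data with the full system", {
  full <- generate_dataset(experiment_spec("lotka_volterra",
                                           n_points = 25, seed = 6))
  miss <- generate_dataset(experiment_spec("lv_missing_terms",
                                           n_points = 25, seed = 6))
  expect_identical(full$replicates, miss$replicates)
  known <- known_part(experiment_spec("lv_missing_terms"))
  # retained terms only: -xy in dx/dt, -3y in dy/dt
  expect_equal(known$fn(0, c(2, 1.5)), c(-3, -4.5))
})

test_that("SNR profiles scale as |signal| / sd", {
  prof <- snr_profile(matrix(c(2, -4, 0), 3), 2)
  expect_equal(prof$snr[, 1], c(1, 2, 0))
  expect_equal(prof$range, c(0, 2))
  half <- snr_profile(matrix(c(2, -4, 0), 3), 4)
  expect_equal(half$snr, prof$snr / 2)
  expect_error(snr_profile(matrix(1), 0), "positive")
})

test_that("the BLR posterior follows the conjugate formulas", {
  # no data: the posterior is the prior
  p0 <- blr_posterior(matrix(numeric(0), 0, 3), numeric(0), alpha = 2)
  expect_equal(p0$mean, rep(0, 3))
  expect_equal(p0$covariance, diag(4, 3))
  # one scalar observation with a diffuse prior
  p1 <- blr_posterior(matrix(1), 2, alpha = 1e6, beta2 = 1)
  expect_equal(drop(p1$mean), 2, tolerance = 1e-9)
  expect_equal(drop(p1$covariance), 1, tolerance = 1e-9)
  # direct formula check
  set.seed(7)
  X <- cbind(1, rnorm(30)); y <- rnorm(30)
  bp <- blr_posterior(X, y, alpha = 3, beta2 = 2)
  S <- solve(crossprod(X) / 2 + diag(1 / 9, 2))
  expect_equal(bp$covariance, S, tolerance = 1e-12)
  expect_equal(bp$mean, drop(S %*% crossprod(X, y) / 2),
               tolerance = 1e-12)
})

test_that("BLR concentrates on the generating cubic coefficients", {
  ds <- generate_dataset(experiment_spec("cubic", n_points = 10000,
                                         seed = 8))
  X <- cbind(1, ds$replicates$x, ds$replicates$x^2, ds$replicates$x^3)
  bp <- blr_posterior(X, ds$replicates$y)
  sds <- sqrt(diag(bp$covariance))
  expect_true(all(abs(bp$mean - c(1, 1, 2, 4)) < 3 * sds))
})

test_that("coverage runs are reproducible for identical seed lists", {
  a <- coverage_experiment("blr", n_datasets = 15)
  b <- coverage_experiment("blr", n_datasets = 15)
  expect_identical(a$coverage, b$coverage)
  expect_true(all(a$coverage >= 0 & a$coverage <= 1))
  expect_identical(unique(a$n), 15L)
})
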