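test_that("kernel evaluations match their closed forms", {
  ks <- kernel_spec("periodic", c2 = 2, l = 0.7, p = 3, sigma2 = 0.4)
  expect_equal(kernel_eval(ks, 1.3, 1.3, same_index = TRUE), 2 + 0.4)
  expect_equal(kernel_eval(ks, 1.3, 1.3), 2)
  # distance equal to the period: the sine term vanishes
  expect_equal(kernel_eval(ks, 0, 3), 2)
  krq <- kernel_spec("rq", c2 = 1.5, l = 0.9, alpha_rq = 2)
  d <- 0.6
  expect_equal(kernel_eval(krq, 0, d),
               1.5 * (1 + d^2 / (2 * 2 * 0.9^2))^(-2))
  expect_error(kernel_spec("rbf", l = -1), "positive")
})

test_that("the rational quadratic approaches the squared exponential at large alpha", {
  krq <- kernel_spec("rq", c2 = 1, l = 0.8, alpha_rq = 1e6)
  krbf <- kernel_spec("rbf", c2 = 1, l = 0.8)
  for (d in c(0.1, 0.5, 1.5)) {
    a <- kernel_eval(krq, 0, d)
    b <- kernel_eval(krbf, 0, d)
    expect_lt(abs(a - b) / b, 1e-4)
  }
})

test_that("kernels are symmetric in their arguments", {
  for (v in c("periodic", "rq", "rbf", "matern")) {
    ks <- kernel_spec(v, c2 = 1.3, l = 0.6, p = 2, alpha_rq = 1.5)
    for (pair in list(c(0.2, 1.9), c(-1, 2.5))) {
      expect_equal(kernel_eval(ks, pair[1], pair[2]),
                   kernel_eval(ks, pair[2], pair[1]))
    }
  }
})

test_that("a periodic GP recovers a noiseless sine on the training span", {
  tt <- seq(0, 4 * pi, length.out = 60)
  df <- data.frame(t = tt, x = sin(tt))
  fit <- fit_gpr(df, kernel = "periodic", restarts = 3, seed = 1)
  pred <- initial_conditions(fit, tt)
  expect_lt(max(abs(pred[, 1] - sin(tt))), 1e-2)
})

test_that("pure white noise is explained by the white kernel", {
  set.seed(2)
  tt <- seq(0, 10, length.out = 120)
  x <- rnorm(120, 5, 1.5)
  fit <- fit_gpr(data.frame(t = tt, x = x), kernel = "rbf", restarts = 3,
                 seed = 2)
  s2 <- fit$dims[[1]]$spec$sigma2
  expect_lt(abs(s2 - var(x)) / var(x), 0.20)
  pred <- initial_conditions(fit, tt)
  se <- sd(x) / sqrt(120)
  expect_lt(max(abs(pred[, 1] - mean(x))), 4 * se)
})

test_that("fits are deterministic for fixed seed and restarts", {
  set.seed(3)
  df <- data.frame(t = seq(0, 5, length.out = 40),
                   x = sin(seq(0, 5, length.out = 40)) + rnorm(40, 0, 0.2))
  f1 <- fit_gpr(df, kernel = "rq", restarts = 3, seed = 7)
  f2 <- fit_gpr(df, kernel = "rq", restarts = 3, seed = 7)
  expect_identical(f1$dims[[1]]$spec, f2$dims[[1]]$spec)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("smoothing denoises replicated noisy Lotka-Volterra trajectories", {
  spec <- experiment_spec("lotka_volterra", n_points = 50)
  for (seed in c(11, 12, 13)) {
    ds <- generate_dataset(experiment_spec("lotka_volterra",
                                           n_points = 50, seed = seed))
    fit <- fit_gpr(ds$replicates, kernel = "periodic", restarts = 3,
                   seed = seed)
    truth <- as.matrix(ds$truth[c("x", "y")])
    pred <- initial_conditions(fit, ds$truth$t)
    rep1 <- as.matrix(ds$replicates[ds$replicates$replicate == 1,
                                    c("x", "y")])
    rmse_smooth <- sqrt(mean((pred - truth)^2))
    rmse_raw <- sqrt(mean((rep1 - truth)^2))
    expect_lt(rmse_smooth, rmse_raw)
  }
})

test_that("the smoother refuses to extrapolate beyond its span", {
  df <- data.frame(t = seq(0, 2, length.out = 20), x = rnorm(20))
  fit <- fit_gpr(df, kernel = "rbf", restarts = 2, seed = 1)
  expect_error(initial_conditions(fit, 2.5), "span")
  expect_error(initial_conditions(fit, -0.1), "span")
  expect_silent(initial_conditions(fit, c(0, 1, 2)))
  expect_error(fit_gpr(data.frame(t = 1:4, x = rnorm(4))), "at least 5")
})

test_that("smoothed trajectories export as standard trajectory CSV", {
  tt <- seq(0, 3, length.out = 25)
  df <- data.frame(t = tt, x = cos(tt))
  fit <- fit_gpr(df, kernel = "rbf", restarts = 2, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  smoother_write(fit, path)
  back <- load_timeseries(path)
  expect_named(back, c("t", "x", "replicate"))
  expect_equal(nrow(back), 25L)
})
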