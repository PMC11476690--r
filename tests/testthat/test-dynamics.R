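test_that("a zero field yields a constant trajectory", {
  f <- known_field(function(t, y) c(0, 0), 2)
  tr <- integrate_rkf45(f, NULL, c(1.5, -2), seq(0, 3, 0.5))
  expect_equal(tr$states, matrix(rep(c(1.5, -2), each = 7), ncol = 2))
})

test_that("exponential decay matches the closed form", {
  f <- known_field(function(t, y) -y, 1)
  tr <- integrate_rkf45(f, NULL, 1, seq(0, 1, 0.1), substeps = 1)
  expect_lt(abs(tr$states[11, 1] - exp(-1)), 1e-6)
})

test_that("Lotka-Volterra integration matches an adaptive reference solver", {
  lv <- true_field("lotka_volterra")
  grid <- seq(0, 10, length.out = 101)
  tr <- integrate_rkf45(lv, NULL, c(1, 1), grid, substeps = 10)
  ref <- deSolve::ode(c(1, 1), grid, function(t, y, p) list(lv$fn(t, y)),
                      NULL, method = "ode45", rtol = 1e-10, atol = 1e-10)
  expect_lt(max(abs(tr$states - as.matrix(ref[, 2:3]))), 1e-4)
})

test_that("halving the step reduces error ~16x (4th-order convergence)", {
  f <- known_field(function(t, y) -y, 1)
  err <- function(s) abs(integrate_rkf45(f, NULL, 1, c(0, 1),
                                         substeps = s)$states[2, 1] -
                           exp(-1))
  ratio <- err(4) / err(8)
  expect_gt(ratio, 8)
  expect_lt(ratio, 32)
})

test_that("integration divergence raises an error naming the failing time", {
  f <- known_field(function(t, y) y^2, 1)
  expect_error(integrate_rkf45(f, NULL, 1, seq(0, 5, 0.5), substeps = 2),
               "diverged near t")
})

test_that("window counts equal n - L + 1 for overlapping windows", {
  mk <- function(n) data.frame(t = seq(0, 1, length.out = n),
                               x = sin(seq_len(n)), y = cos(seq_len(n)))
  expect_identical(make_batches(mk(100), 12)$n_windows, 89L)
  expect_identical(make_batches(mk(900), 2)$n_windows, 899L)
  b <- make_batches(mk(30), 30)
  expect_identical(b$n_windows, 1L)
  expect_identical(ncol(b$times), 30L)
  expect_error(make_batches(mk(10), 11), "\\[2, 10\\]")
})

test_that("batching covers every source observation at least once", {
  n <- 25
  df <- data.frame(t = seq(0, 1, length.out = n), x = rnorm(n))
  b <- make_batches(df, 7)
  seen <- unique(as.vector(b$times))
  expect_setequal(round(seen, 12), round(df$t, 12))
  # and window times are consecutive subsequences of the source grid
  for (i in seq_len(b$n_windows))
    expect_equal(b$times[i, ], df$t[i:(i + 6)])
})

test_that("window initial states come from observations or the smoother", {
  set.seed(1)
  n <- 40
  tt <- seq(0, 6, length.out = n)
  df <- do.call(rbind, lapply(1:4, function(r)
    data.frame(t = tt, x = sin(tt) + rnorm(n, 0, 0.3), replicate = r)))
  b_obs <- make_batches(df, 5, y0_source = "observed")
  xbar <- rowMeans(sapply(split(df, df$replicate), function(d) d$x))
  expect_equal(drop(b_obs$y0), xbar[1:b_obs$n_windows])
  sm <- fit_gpr(df, kernel = "rbf", restarts = 2, seed = 1)
  b_sm <- make_batches(df, 5, y0_source = "smoother", smoother = sm)
  expect_equal(b_sm$y0, initial_conditions(sm, tt[1:b_sm$n_windows]))
})

test_that("augmenting with a known field adds pointwise", {
  cfg <- pinet_config(2, 2, 2, 4)
  params <- random_params(cfg, 3)
  theta <- pinet_pack(params, cfg)
  learned <- pinet_field(cfg)
  known <- true_field("lotka_volterra")
  both <- augment_with_known(known, learned)
  set.seed(3)
  for (i in 1:20) {
    y <- runif(2, 0.5, 3)
    expect_equal(
      drop(polynode:::field_eval(both, 0, matrix(y, 1), theta)$f),
      known$fn(0, y) + pinet_forward(params, cfg, y),
      tolerance = 1e-12)
  }
  zero <- known_field(function(t, y) c(0, 0), 2)
  y <- c(1.2, 0.4)
  expect_equal(
    drop(polynode:::field_eval(augment_with_known(zero, learned), 0,
                               matrix(y, 1), theta)$f),
    pinet_forward(params, cfg, y))
  expect_error(augment_with_known(known_field(function(t, y) y, 3),
                                  learned), "dimensions differ")
})

test_that("forward sensitivities match central finite differences", {
  cfg <- pinet_config(2, 2, 2, 3)
  field <- pinet_field(cfg)
  theta <- pinet_pack(random_params(cfg, 6, scale = 0.3), cfg)
  Y0 <- matrix(c(1, 1.1, 0.9, 0.7), 2, 2)
  Tm <- rbind(seq(0, 0.6, 0.2), seq(0, 0.6, 0.2))
  res <- polynode:::rkf45_batch(field, theta, Y0, Tm, substeps = 4,
                                sens = TRUE)
  eps <- 1e-6
  set.seed(6)
  for (j in sample(length(theta), 8)) {
    tp <- theta; tp[j] <- tp[j] + eps
    tm <- theta; tm[j] <- tm[j] - eps
    num <- (polynode:::rkf45_batch(field, tp, Y0, Tm, 4)$states -
              polynode:::rkf45_batch(field, tm, Y0, Tm, 4)$states) /
      (2 * eps)
    for (l in 2:4) for (a in 1:2) {
      an <- res$sens[[l]][[a]][, j]
      expect_lt(max(abs(an - num[, l, a])),
                1e-4 * max(abs(num[, l, a]), 1e-6))
    }
  }
})

test_that("trajectory data frames convert and print", {
  f <- known_field(function(t, y) -y, 1)
  tr <- integrate_rkf45(f, NULL, 2, seq(0, 1, 0.25))
  df <- as.data.frame(tr)
  expect_named(df, c("t", "y1"))
  expect_identical(nrow(df), 5L)
  expect_output(print(tr), "5 time points")
})
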