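std_normal <- function(th) list(value = -0.5 * sum(th^2), grad = -th)

test_that("NUTS recovers 1-D and correlated 2-D Gaussian targets", {
  ch <- sample_nuts(std_normal, 0.5,
                    hmc_settings(warmup = 500, samples = 1000), seed = 2)
  expect_lte(abs(mean(ch$draws)), 0.1)
  expect_gte(var(drop(ch$draws)), 0.85)
  expect_lte(var(drop(ch$draws)), 1.15)

  P <- solve(matrix(c(1, 0.8, 0.8, 1), 2))
  corr_target <- function(th) list(value = -0.5 * sum(th * (P %*% th)),
                                   grad = -drop(P %*% th))
  ch2 <- sample_nuts(corr_target, c(0, 0),
                     hmc_settings(warmup = 500, samples = 1000), seed = 3)
  expect_lt(abs(cor(ch2$draws)[1, 2] - 0.8), 0.1)
})

test_that("HMC recovers the same known targets with fixed step settings", {
  ch <- sample_hmc(std_normal, 0.5,
                   hmc_settings(step_size = 0.4, leapfrog = 10,
                                warmup = 500, samples = 1000), seed = 4)
  expect_lte(abs(mean(ch$draws)), 0.1)
  expect_gte(var(drop(ch$draws)), 0.85)
  expect_lte(var(drop(ch$draws)), 1.15)
  P <- solve(matrix(c(1, 0.8, 0.8, 1), 2))
  corr_target <- function(th) list(value = -0.5 * sum(th * (P %*% th)),
                                   grad = -drop(P %*% th))
  ch2 <- sample_hmc(corr_target, c(0, 0),
                    hmc_settings(step_size = 0.25, leapfrog = 15,
                                 warmup = 500, samples = 1000), seed = 5)
  expect_lt(abs(cor(ch2$draws)[1, 2] - 0.8), 0.1)
})

test_that("both samplers recover a 5-parameter conjugate BLR posterior", {
  set.seed(6)
  X <- cbind(1, rnorm(80), rnorm(80), runif(80), runif(80))
  beta <- c(1, 2, -1, 0.5, 1.5)
  y <- drop(X %*% beta) + rnorm(80)
  alpha <- 10; beta2 <- 1
  bp <- blr_posterior(X, y, alpha = alpha, beta2 = beta2)
  m <- pn_linear(X, y)
  lj <- pn_logjoint(m, beta2, prior_spec(alpha))
  for (sampler in c("nuts", "hmc")) {
    ch <- if (sampler == "nuts")
      sample_nuts(lj, bp$mean, hmc_settings(warmup = 500, samples = 1000),
                  seed = 7)
    else
      sample_hmc(lj, bp$mean,
                 hmc_settings(step_size = 0.05, leapfrog = 12,
                              warmup = 500, samples = 1000), seed = 7)
    mns <- colMeans(ch$draws)
    mcse <- sqrt(diag(bp$covariance) / 100)   # generous effective n
    expect_true(all(abs(mns - bp$mean) < 3 * sqrt(diag(bp$covariance))),
                info = sampler)
    expect_lt(max(abs(mns - bp$mean) / sqrt(diag(bp$covariance))), 1,
              label = paste(sampler, "posterior mean error (in sds)"))
  }
})

test_that("samplers are deterministic for a fixed seed", {
  ch1 <- sample_nuts(std_normal, 0, hmc_settings(warmup = 100,
                                                 samples = 100), seed = 9)
  ch2 <- sample_nuts(std_normal, 0, hmc_settings(warmup = 100,
                                                 samples = 100), seed = 9)
  expect_identical(ch1$draws, ch2$draws)
})

test_that("a non-finite log-joint at the start is rejected", {
  bad <- function(th) list(value = NaN, grad = th)
  expect_error(sample_nuts(bad, 0), "finite")
  expect_error(sample_hmc(bad, 0), "finite")
})

test_that("Geweke matches direct evaluation of the segment formula", {
  # alternating chain: both segment means are zero
  alt <- rep(c(1, -1), 500)
  g <- geweke(alt)
  expect_equal(g$T, 0)
  expect_true(g$pass)

  set.seed(10)
  ch <- c(rnorm(100), rnorm(900, 5))      # drifted chain
  g2 <- geweke(ch)
  s1 <- ch[1:100]; s2 <- ch[501:1000]
  oracle <- (mean(s1) - mean(s2)) /
    sqrt(var(s1) / 100 + var(s2) / 500)
  expect_equal(g2$T, oracle, tolerance = 1e-12)
  expect_false(g2$pass)

  expect_error(geweke(rep(1, 1000)), "degenerate")
  expect_error(geweke(rnorm(10)), "too short")
})

test_that("Geweke accepts a well-mixed i.i.d. chain at the nominal rate", {
  set.seed(11)
  passes <- vapply(1:100, function(i) geweke(rnorm(1000))$pass, logical(1))
  expect_gte(mean(passes), 0.90)
})

test_that("chains export to CSV with one column per parameter", {
  ch <- sample_nuts(std_normal, 0, hmc_settings(warmup = 50, samples = 20),
                    seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  chain_write(ch, path, col_names = "theta")
  back <- utils::read.csv(path)
  expect_identical(dim(back), c(20L, 1L))
  expect_equal(back$theta, drop(ch$draws))
})
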