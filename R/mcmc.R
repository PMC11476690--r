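#' HMC / NUTS sampler settings
#'
#' @param step_size Leapfrog discretization step (HMC only; NUTS adapts its
#'   own during warmup).
#' @param leapfrog Number of leapfrog steps per HMC iteration.
#' @param warmup Warmup iterations, discarded (default 1000).
#' @param samples Post-warmup draws to keep (default 1000).
#' @param max_treedepth NUTS doubling depth cap (default 10).
#' @param target_accept Dual-averaging target acceptance for NUTS
#'   (default 0.8).
#' @param init_inv_mass Optional initial inverse mass: a vector of
#'   per-parameter posterior-scale variances (diagonal metric), or a full
#'   symmetric positive-definite covariance matrix (e.g.
#'   [fisher_metric()]), in which case NUTS runs in the whitened
#'   coordinates it defines.  Warmup adaptation refines the (whitened)
#'   diagonal metric.  Default `NULL` (unit metric).
#' @return A list of class `hmc_settings`.
#' @export
hmc_settings <- function(step_size = 0.01, leapfrog = 20L, warmup = 1000L,
                         samples = 1000L, max_treedepth = 10L,
                         target_accept = 0.8, init_inv_mass = NULL) {
  stopifnot(step_size > 0, leapfrog >= 1, warmup >= 0, samples >= 1)
  if (!is.null(init_inv_mass)) {
    stopifnot(all(is.finite(init_inv_mass)))
    if (!is.matrix(init_inv_mass)) stopifnot(all(init_inv_mass > 0))
  }
  structure(list(step_size = step_size, leapfrog = as.integer(leapfrog),
                 warmup = as.integer(warmup), samples = as.integer(samples),
                 max_treedepth = as.integer(max_treedepth),
                 target_accept = target_accept,
                 init_inv_mass = init_inv_mass),
            class = "hmc_settings")
}

## normalize a log-joint callable to function(theta) -> list(value, grad)
as_value_grad <- function(logjoint) {
  function(theta) {
    out <- logjoint(theta)
    if (is.list(out)) {
      list(value = as.numeric(out$value), grad = as.numeric(out$grad))
    } else {
      g <- attr(out, "gradient")
      if (is.null(g)) stop("logjoint must supply a gradient")
      list(value = as.numeric(out), grad = as.numeric(g))
    }
  }
}

#' Log-joint callable (with gradient) for a pi-net model
#'
#' Builds the differentiable target
#' \eqn{\log f(D,\theta) = -\sum r^2/(2\beta^2) - \theta^T\theta/(2\alpha^2)}
#' used by the MCMC and VI engines.
#'
#' @param model A [pn_regression()] / [pn_ode_model()].
#' @param beta2 Observation noise variance.
#' @param prior A [prior_spec()].
#' @return A function `theta -> list(value, grad)`.
#' @export
pn_logjoint <- function(model, beta2, prior = prior_spec()) {
  stopifnot(beta2 > 0)
  function(theta) {
    sg <- model_sse_grad(model, theta)
    list(value = -sg$sse / (2 * beta2) -
           sum(theta^2) / (2 * prior$alpha^2),
         grad = -sg$grad / (2 * beta2) - theta / prior$alpha^2)
  }
}

## one leapfrog step under a diagonal metric (vinv = posterior-scale
## variances, i.e. the inverse mass)
leapfrog_step <- function(vg, theta, r, grad, eps, vinv) {
  r <- r + 0.5 * eps * grad
  theta <- theta + eps * (vinv * r)
  ev <- vg(theta)
  r <- r + 0.5 * eps * ev$grad
  list(theta = theta, r = r, value = ev$value, grad = ev$grad)
}

joint_logp <- function(value, r, vinv) value - 0.5 * sum(vinv * r^2)

find_reasonable_eps <- function(vg, theta, vinv) {
  eps <- 1
  ev <- vg(theta)
  r <- rnorm(length(theta)) / sqrt(vinv)
  lp0 <- joint_logp(ev$value, r, vinv)
  st <- leapfrog_step(vg, theta, r, ev$grad, eps, vinv)
  lp1 <- joint_logp(st$value, st$r, vinv)
  if (!is.finite(lp1)) lp1 <- -Inf
  a <- if (lp1 - lp0 > log(0.5)) 1 else -1
  for (i in 1:50) {
    eps <- eps * 2^a
    st <- leapfrog_step(vg, theta, r, ev$grad, eps, vinv)
    lp1 <- joint_logp(st$value, st$r, vinv)
    if (!is.finite(lp1)) lp1 <- -Inf
    if (a * (lp1 - lp0) <= a * log(0.5)) break
  }
  eps
}

#' No-U-Turn sampling of a differentiable log-joint
#'
#' A single-chain implementation of the No-U-Turn Sampler: slice-based tree
#' doubling with a configurable depth cap, dual-averaging step-size
#' adaptation toward `target_accept`, and diagonal mass-matrix estimation
#' from the middle of the warmup phase.  Warmup draws are discarded.
#'
#' @param logjoint Function of the parameter vector returning
#'   `list(value, grad)` (see [pn_logjoint()]).
#' @param init Finite initial parameter vector (typically the MAP).
#' @param settings An [hmc_settings()].
#' @param seed Integer seed; draws are deterministic given it.
#' @return An object of class `chain_samples`: `draws`
#'   (`samples x n_params`), acceptance statistics, warmup length,
#'   divergence count (a warning is attached when more than half of the
#'   post-warmup iterations diverge).
#' @export
sample_nuts <- function(logjoint, init, settings = hmc_settings(),
                        seed = 1L) {
  vg <- as_value_grad(logjoint)
  p <- length(init)
  stopifnot(all(is.finite(init)))
  ## dense metric: run the sampler in whitened coordinates theta = V s phi
  white <- NULL
  if (is.matrix(settings$init_inv_mass)) {
    S <- settings$init_inv_mass
    stopifnot(nrow(S) == p, ncol(S) == p)
    e <- eigen((S + t(S)) / 2, symmetric = TRUE)
    white <- list(V = e$vectors, s = sqrt(pmax(e$values, 1e-12)))
    vg_raw <- vg
    vg <- function(phi) {
      ev <- vg_raw(drop(white$V %*% (white$s * phi)))
      list(value = ev$value,
           grad = white$s * drop(crossprod(white$V, ev$grad)))
    }
    init <- drop(crossprod(white$V, init)) / white$s
    settings$init_inv_mass <- NULL
  }
  ev0 <- vg(init)
  if (!is.finite(ev0$value)) stop("log-joint is not finite at init")
  with_local_seed(seed, {
    w <- settings$warmup; ns <- settings$samples
    vinv <- if (is.null(settings$init_inv_mass)) rep(1, p)
            else rep_len(settings$init_inv_mass, p)
    eps <- find_reasonable_eps(vg, init, vinv)
    mu <- log(10 * eps)
    log_eps_bar <- 0; Hbar <- 0
    gamma <- 0.05; t0 <- 10; kappa <- 0.75
    adapt_i <- 0L
    theta <- init; ev <- ev0
    draws <- matrix(NA_real_, ns, p)
    accept_stats <- numeric(ns)
    treedepths <- integer(ns)
    divergences <- 0L
    ## Stan-style warmup: an initial step-size-only buffer, doubling
    ## metric-estimation windows, and a terminal step-size-only buffer
    win_ends <- integer(0)
    if (w >= 150L) {
      lo <- 76L; hi <- w - 50L; size <- 25L
      while (lo <= hi) {
        end <- min(lo + size - 1L, hi)
        if (hi - end < size * 2L) end <- hi   # absorb the remainder
        win_ends <- c(win_ends, end)
        lo <- end + 1L; size <- size * 2L
      }
    }
    win_start <- 76L
    mass_buf <- NULL
    total <- w + ns
    for (it in seq_len(total)) {
      r0 <- rnorm(p) / sqrt(vinv)
      lp0 <- joint_logp(ev$value, r0, vinv)
      logu <- lp0 + log(runif(1))
      thm <- thp <- theta; rm_ <- rp_ <- r0
      gm <- gp <- ev$grad; vm <- vp <- ev$value
      j <- 0L; n_keep <- 1L; s <- TRUE
      prop_theta <- theta; prop_ev <- ev
      alpha_sum <- 0; n_alpha <- 0L; diverged <- FALSE
      while (s && j < settings$max_treedepth) {
        dir <- if (runif(1) < 0.5) -1 else 1
        if (dir == -1) {
          bt <- nuts_build_tree(vg, thm, rm_, gm, vm, logu, dir, j, eps,
                                vinv, lp0)
          thm <- bt$theta_minus; rm_ <- bt$r_minus; gm <- bt$grad_minus
          vm <- bt$value_minus
        } else {
          bt <- nuts_build_tree(vg, thp, rp_, gp, vp, logu, dir, j, eps,
                                vinv, lp0)
          thp <- bt$theta_plus; rp_ <- bt$r_plus; gp <- bt$grad_plus
          vp <- bt$value_plus
        }
        alpha_sum <- alpha_sum + bt$alpha; n_alpha <- n_alpha + bt$n_alpha
        if (bt$diverged) diverged <- TRUE
        if (bt$s && runif(1) < bt$n_keep / max(n_keep, 1L)) {
          prop_theta <- bt$proposal
          prop_ev <- list(value = bt$proposal_value,
                          grad = bt$proposal_grad)
        }
        n_keep <- n_keep + bt$n_keep
        dtheta <- thp - thm
        s <- bt$s && sum(dtheta * (vinv * rm_)) >= 0 &&
          sum(dtheta * (vinv * rp_)) >= 0
        j <- j + 1L
      }
      theta <- prop_theta; ev <- prop_ev
      accept <- if (n_alpha > 0) alpha_sum / n_alpha else 0
      if (it <= w) {
        adapt_i <- adapt_i + 1L
        Hbar <- (1 - 1 / (adapt_i + t0)) * Hbar +
          (settings$target_accept - accept) / (adapt_i + t0)
        log_eps <- mu - sqrt(adapt_i) / gamma * Hbar
        wts <- adapt_i^(-kappa)
        log_eps_bar <- wts * log_eps + (1 - wts) * log_eps_bar
        eps <- exp(log_eps)
        if (length(win_ends) && it >= win_start) {
          mass_buf <- rbind(mass_buf, theta)
          if (it == win_ends[1L]) {
            v_est <- apply(mass_buf, 2L, stats::var)
            nw <- nrow(mass_buf)
            ## shrink toward the current metric over short windows
            v_new <- (nw / (nw + 5)) * v_est + (5 / (nw + 5)) * vinv
            bad <- v_new <= 0 | !is.finite(v_new)
            v_new[bad] <- vinv[bad]
            vinv <- v_new
            eps <- find_reasonable_eps(vg, theta, vinv)
            mu <- log(10 * eps)
            log_eps_bar <- 0; Hbar <- 0; adapt_i <- 0L
            win_start <- it + 1L
            win_ends <- win_ends[-1L]
            mass_buf <- NULL
          }
        }
        if (it == w) eps <- exp(log_eps_bar)
      } else {
        k <- it - w
        draws[k, ] <- theta
        accept_stats[k] <- accept
        treedepths[k] <- j
        if (diverged) divergences <- divergences + 1L
      }
    }
    if (!is.null(white))
      draws <- sweep(draws, 2L, white$s, `*`) %*% t(white$V)
    res <- structure(list(draws = draws, accept_stat = accept_stats,
                          treedepth = treedepths, warmup = w,
                          divergences = divergences, step_size = eps,
                          algorithm = "nuts"),
                     class = "chain_samples")
    if (divergences > ns / 2)
      res$warning <- sprintf("%d of %d iterations diverged", divergences, ns)
    res
  })
}

## recursive NUTS tree doubling (Hoffman & Gelman, slice variant)
nuts_build_tree <- function(vg, theta, r, grad, value, logu, dir, j, eps,
                            vinv, lp0, delta_max = 1000) {
  if (j == 0L) {
    st <- leapfrog_step(vg, theta, r, grad, dir * eps, vinv)
    lp <- joint_logp(st$value, st$r, vinv)
    if (!is.finite(lp)) lp <- -Inf
    n_keep <- as.integer(logu <= lp)
    diverged <- (lp - logu) < -delta_max
    alpha <- min(1, exp(lp - lp0))
    if (!is.finite(alpha)) alpha <- 0
    return(list(theta_minus = st$theta, r_minus = st$r, grad_minus = st$grad,
                value_minus = st$value,
                theta_plus = st$theta, r_plus = st$r, grad_plus = st$grad,
                value_plus = st$value,
                proposal = st$theta, proposal_value = st$value,
                proposal_grad = st$grad,
                n_keep = n_keep, s = !diverged, alpha = alpha,
                n_alpha = 1L, diverged = diverged))
  }
  t1 <- nuts_build_tree(vg, theta, r, grad, value, logu, dir, j - 1L, eps,
                        vinv, lp0, delta_max)
  if (!t1$s) return(t1)
  if (dir == -1) {
    t2 <- nuts_build_tree(vg, t1$theta_minus, t1$r_minus, t1$grad_minus,
                          t1$value_minus, logu, dir, j - 1L, eps, vinv, lp0,
                          delta_max)
    t1$theta_minus <- t2$theta_minus; t1$r_minus <- t2$r_minus
    t1$grad_minus <- t2$grad_minus; t1$value_minus <- t2$value_minus
  } else {
    t2 <- nuts_build_tree(vg, t1$theta_plus, t1$r_plus, t1$grad_plus,
                          t1$value_plus, logu, dir, j - 1L, eps, vinv, lp0,
                          delta_max)
    t1$theta_plus <- t2$theta_plus; t1$r_plus <- t2$r_plus
    t1$grad_plus <- t2$grad_plus; t1$value_plus <- t2$value_plus
  }
  ntot <- t1$n_keep + t2$n_keep
  if (t2$n_keep > 0L && runif(1) < t2$n_keep / ntot) {
    t1$proposal <- t2$proposal
    t1$proposal_value <- t2$proposal_value
    t1$proposal_grad <- t2$proposal_grad
  }
  dtheta <- t1$theta_plus - t1$theta_minus
  t1$s <- t2$s && sum(dtheta * (vinv * t1$r_minus)) >= 0 &&
    sum(dtheta * (vinv * t1$r_plus)) >= 0
  t1$n_keep <- ntot
  t1$alpha <- t1$alpha + t2$alpha
  t1$n_alpha <- t1$n_alpha + t2$n_alpha
  t1$diverged <- t1$diverged || t2$diverged
  t1
}

#' Hamiltonian Monte Carlo sampling with fixed step size and path length
#'
#' Plain HMC: leapfrog integration of the momentum-augmented dynamics for a
#' user-fixed step size and step count, with a Metropolis-Hastings
#' correction for the discretization error.  Warmup draws are discarded
#' without adaptation (the settings are user-fixed by construction).
#'
#' @inheritParams sample_nuts
#' @return A `chain_samples` object (see [sample_nuts()]).
#' @export
sample_hmc <- function(logjoint, init, settings = hmc_settings(),
                       seed = 1L) {
  vg <- as_value_grad(logjoint)
  p <- length(init)
  stopifnot(all(is.finite(init)))
  ev <- vg(init)
  if (!is.finite(ev$value)) stop("log-joint is not finite at init")
  with_local_seed(seed, {
    w <- settings$warmup; ns <- settings$samples
    vinv <- rep(1, p)
    eps <- settings$step_size; Lf <- settings$leapfrog
    theta <- init
    draws <- matrix(NA_real_, ns, p)
    accepts <- logical(ns)
    for (it in seq_len(w + ns)) {
      r <- rnorm(p)
      lp0 <- joint_logp(ev$value, r, vinv)
      st <- list(theta = theta, r = r, value = ev$value, grad = ev$grad)
      for (l in seq_len(Lf))
        st <- leapfrog_step(vg, st$theta, st$r, st$grad, eps, vinv)
      lp1 <- joint_logp(st$value, st$r, vinv)
      acc <- is.finite(lp1) && log(runif(1)) < (lp1 - lp0)
      if (acc) {
        theta <- st$theta
        ev <- list(value = st$value, grad = st$grad)
      }
      if (it > w) {
        draws[it - w, ] <- theta
        accepts[it - w] <- acc
      }
    }
    structure(list(draws = draws, accept_stat = mean(accepts),
                   warmup = w, divergences = sum(!accepts),
                   step_size = eps, algorithm = "hmc"),
              class = "chain_samples")
  })
}

#' @export
print.chain_samples <- function(x, ...) {
  cat(sprintf("%s chain: %d draws x %d parameters (warmup %d discarded)\n",
              toupper(x$algorithm), nrow(x$draws), ncol(x$draws), x$warmup))
  if (!is.null(x$warning)) cat("warning:", x$warning, "\n")
  invisible(x)
}

#' Geweke convergence diagnostic
#'
#' For each parameter, the two-sample statistic
#' \deqn{T = \frac{\bar X_1 - \bar X_2}
#'            {\sqrt{s_1^2/n_1 + s_2^2/n_2}}}
#' comparing the first `first` fraction and the last `last` fraction of the
#' post-burn-in chain (plain segment sample variances; defaults 10% vs 50%).
#' A parameter passes when `|T| <= critical`.
#'
#' @param chain A `chain_samples`, matrix of draws, or vector.
#' @param burn_in Additional fraction discarded from the front (default 0:
#'   sampler warmup is already gone).
#' @param first,last Segment fractions (defaults 0.10 and 0.50).
#' @param critical Two-sided critical value (default 1.964, the 0.05-level
#'   cutoff).
#' @return A data frame of class `geweke_result` with columns `T`, `mean1`,
#'   `mean2`, `var1`, `var2`, `n1`, `n2`, `pass`.
#' @export
geweke <- function(chain, burn_in = 0, first = 0.10, last = 0.50,
                   critical = 1.964) {
  draws <- if (inherits(chain, "chain_samples")) chain$draws
           else if (is.null(dim(chain))) matrix(chain, ncol = 1L)
           else as.matrix(chain)
  stopifnot(burn_in >= 0, burn_in < 1, first > 0, last > 0,
            first + last <= 1)
  n0 <- nrow(draws)
  keep <- draws[seq.int(floor(burn_in * n0) + 1L, n0), , drop = FALSE]
  n <- nrow(keep)
  n1 <- floor(first * n); n2 <- floor(last * n)
  if (n1 < 2L || n2 < 2L)
    stop("chain too short for Geweke segments (n1 = ", n1, ", n2 = ", n2, ")")
  seg1 <- keep[seq_len(n1), , drop = FALSE]
  seg2 <- keep[seq.int(n - n2 + 1L, n), , drop = FALSE]
  m1 <- colMeans(seg1); m2 <- colMeans(seg2)
  v1 <- apply(seg1, 2L, stats::var); v2 <- apply(seg2, 2L, stats::var)
  if (any(v1 == 0 | v2 == 0)) {
    bad <- which(v1 == 0 | v2 == 0)[1L]
    stop("degenerate chain: zero segment variance for parameter ", bad)
  }
  T <- (m1 - m2) / sqrt(v1 / n1 + v2 / n2)
  nm <- colnames(draws)
  if (is.null(nm)) nm <- paste0("par", seq_along(T))
  structure(data.frame(parameter = nm, T = T, mean1 = m1, mean2 = m2,
                       var1 = v1, var2 = v2, n1 = n1, n2 = n2,
                       pass = abs(T) <= critical, row.names = NULL),
            class = c("geweke_result", "data.frame"),
            critical = critical)
}

#' Export a chain to CSV
#'
#' One column per parameter (or expanded coefficient).
#'
#' @param chain A `chain_samples` or matrix.
#' @param path Output path.
#' @param col_names Optional column names.
#' @return Invisibly, `path`.
#' @export
chain_write <- function(chain, path, col_names = NULL) {
  draws <- if (inherits(chain, "chain_samples")) chain$draws else chain
  df <- as.data.frame(draws)
  if (!is.null(col_names)) names(df) <- col_names
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
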