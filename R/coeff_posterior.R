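## take n draws of the flat parameter vector from a posterior object:
## Gaussian posteriors are sampled natively; chains reuse the stored draws
## (thinned evenly when more are stored than requested).
posterior_theta_draws <- function(posterior, n_samples) {
  if (inherits(posterior, "gaussian_posterior"))
    return(posterior_draws(posterior, n_samples))
  if (inherits(posterior, "chain_samples")) {
    nd <- nrow(posterior$draws)
    n <- min(n_samples, nd)
    idx <- if (n == nd) seq_len(nd)
           else round(seq(1L, nd, length.out = n))
    return(posterior$draws[idx, , drop = FALSE])
  }
  stop("posterior must be a gaussian_posterior or chain_samples")
}

#' Monte Carlo propagation of a parameter posterior to coefficient posteriors
#'
#' Draws parameter vectors from the posterior (native sampling for Gaussian
#' posteriors; the stored draws for MCMC chains, capped at the chain length)
#' and expands each draw symbolically via [expand_to_polynomial()], giving
#' samples from the posterior of the expanded polynomial coefficients
#' `c ~ P(c | D)`.
#'
#' @param posterior A `gaussian_posterior` or `chain_samples` whose
#'   parameter layout matches `config`.
#' @param config The [pinet_config()] the posterior refers to.
#' @param n_samples Number of draws (default 2000).
#' @param seed Seed for Gaussian sampling.
#' @return An object of class `coefficient_samples`: a list `samples` with,
#'   per output dimension, an `n_samples x n_monomials` matrix (columns
#'   labelled by monomial), plus `labels` and `exponents`.
#' @export
sample_coefficients <- function(posterior, config, n_samples = 2000L,
                                seed = 1L) {
  p <- count_parameters(config)
  np <- if (inherits(posterior, "gaussian_posterior"))
          length(posterior$mean) else ncol(posterior$draws)
  if (np != p)
    stop("posterior has ", np, " parameters but the config needs ", p)
  Theta <- with_local_seed(seed, posterior_theta_draws(posterior, n_samples))
  basis <- pn_basis(config)
  n <- nrow(Theta); m <- config$output_dim; M <- nrow(basis$exps)
  samples <- lapply(seq_len(m), function(j) {
    out <- matrix(NA_real_, n, M)
    colnames(out) <- basis$labels
    out
  })
  for (s in seq_len(n)) {
    Cf <- expand_core(pinet_unpack(Theta[s, ], config), config, basis)
    for (j in seq_len(m)) samples[[j]][s, ] <- Cf[j, ]
  }
  names(samples) <- paste0("f", seq_len(m))
  structure(list(samples = samples, labels = basis$labels,
                 exponents = basis$exps, state_names = config$state_names,
                 n_samples = n),
            class = "coefficient_samples")
}

#' @export
print.coefficient_samples <- function(x, ...) {
  cat(sprintf("coefficient samples: %d draws x %d monomials x %d outputs\n",
              x$n_samples, length(x$labels), length(x$samples)))
  invisible(x)
}

#' Summarize coefficient samples
#'
#' @param object A `coefficient_samples`.
#' @param levels Credible levels for equal-tailed intervals.
#' @param ... Unused.
#' @return A data frame with posterior mean, SD and interval endpoints per
#'   output dimension and monomial.
#' @export
summary.coefficient_samples <- function(object, levels = c(0.95, 0.997),
                                        ...) {
  rows <- lapply(names(object$samples), function(nm) {
    S <- object$samples[[nm]]
    df <- data.frame(output = nm, monomial = colnames(S),
                     mean = colMeans(S), sd = apply(S, 2L, stats::sd),
                     row.names = NULL)
    for (lv in levels) {
      qi <- apply(S, 2L, quantile_interval, level = lv)
      df[[sprintf("lo%g", 100 * lv)]] <- qi[1L, ]
      df[[sprintf("hi%g", 100 * lv)]] <- qi[2L, ]
    }
    df
  })
  do.call(rbind, rows)
}

#' Write coefficient samples to CSV
#'
#' One file per output dimension would scatter artifacts, so all outputs are
#' stacked with columns `<output>.<monomial>`.
#'
#' @param x A `coefficient_samples`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
coefficients_write <- function(x, path) {
  blocks <- lapply(names(x$samples), function(nm) {
    S <- x$samples[[nm]]
    colnames(S) <- paste(nm, colnames(S), sep = ".")
    S
  })
  utils::write.csv(as.data.frame(do.call(cbind, blocks)), path,
                   row.names = FALSE)
  invisible(path)
}

#' Equal-tailed (quantile) credible interval
#'
#' Returns the `(1-level)/2` and `1-(1-level)/2` empirical quantiles.
#'
#' @param samples Numeric sample vector (>= 2 values).
#' @param level Credible level in (0, 1).
#' @return Numeric vector `c(lower, upper)`.
#' @export
quantile_interval <- function(samples, level) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  if (length(samples) < 2L) stop("need at least 2 samples")
  unname(stats::quantile(samples,
                         c((1 - level) / 2, 1 - (1 - level) / 2)))
}

#' Posterior-predictive trajectories or regression curves with credible bands
#'
#' Draws from the parameter posterior, evaluates the implied model for each
#' draw -- the regression polynomial at `newdata`, or the ODE integrated
#' from `y0` over `grid` (including the known-field augmentation when
#' supplied) -- and summarizes with the pointwise sample mean and
#' equal-tailed quantile bands per level.
#'
#' @param posterior `gaussian_posterior` or `chain_samples`.
#' @param config The [pinet_config()].
#' @param newdata For regression: input matrix / vector of evaluation
#'   points.
#' @param y0,grid For an ODE: initial state and output time grid.
#' @param known Optional parameter-free `ode_field` added to the learned
#'   field.
#' @param levels Credible levels (default `c(0.95, 0.997)`).
#' @param n_samples Posterior draws (default 2000).
#' @param seed Seed.
#' @param substeps Integration substeps per grid interval.
#' @return An object of class `predictive_band`: `times` (or `x`), `mean`
#'   matrix, and per-level `lower` / `upper` arrays; draws whose
#'   integration diverges are excluded with a count (an error is raised if
#'   more than 10% are excluded).
#' @export
posterior_predictive <- function(posterior, config, newdata = NULL,
                                 y0 = NULL, grid = NULL, known = NULL,
                                 levels = c(0.95, 0.997),
                                 n_samples = 2000L, seed = 1L,
                                 substeps = 10L) {
  stopifnot(all(levels > 0 & levels < 1))
  ode <- !is.null(y0)
  if (ode && is.null(grid)) stop("ODE prediction needs a time grid")
  if (!ode && is.null(newdata)) stop("regression prediction needs newdata")
  Theta <- with_local_seed(seed, posterior_theta_draws(posterior, n_samples))
  n <- nrow(Theta)
  if (ode) {
    field <- pinet_field(config)
    if (!is.null(known)) field <- augment_with_known(known, field)
    L <- length(grid); d <- config$state_dim
    vals <- array(NA_real_, c(n, L, d))
    excluded <- 0L
    for (s in seq_len(n)) {
      tr <- tryCatch(
        rkf45_batch(field, Theta[s, ], matrix(y0, 1L), matrix(grid, 1L),
                    substeps = substeps)$states[1L, , ],
        error = function(e) NULL)
      if (is.null(tr) || any(!is.finite(tr))) excluded <- excluded + 1L
      else vals[s, , ] <- tr
    }
    if (excluded > 0.10 * n)
      stop(excluded, " of ", n, " posterior draws diverged during ",
           "integration")
    if (excluded > 0)
      warning(excluded, " diverging posterior draw(s) excluded")
    keep <- which(!is.na(vals[, 1L, 1L]))
    vals <- vals[keep, , , drop = FALSE]
    axis <- grid
  } else {
    X <- if (is.null(dim(newdata))) matrix(newdata, ncol = config$state_dim)
         else as.matrix(newdata)
    L <- nrow(X); d <- config$output_dim
    vals <- array(NA_real_, c(n, L, d))
    for (s in seq_len(n)) {
      params <- pinet_unpack(Theta[s, ], config)
      vals[s, , ] <- pinet_eval(params, config, X)$y
    }
    excluded <- 0L
    axis <- if (config$state_dim == 1L) drop(X) else X
  }
  mean_tr <- apply(vals, c(2L, 3L), mean)
  lower <- upper <- vector("list", length(levels))
  names(lower) <- names(upper) <- sprintf("%g", levels)
  for (i in seq_along(levels)) {
    qs <- apply(vals, c(2L, 3L), quantile_interval, level = levels[i])
    lower[[i]] <- matrix(qs[1L, , ], L, d)
    upper[[i]] <- matrix(qs[2L, , ], L, d)
  }
  nm <- if (ode) config$state_names
        else paste0("f", seq_len(config$output_dim))
  colnames(mean_tr) <- nm
  structure(list(times = axis, mean = mean_tr, lower = lower,
                 upper = upper, levels = levels, n_draws = dim(vals)[1L],
                 n_excluded = excluded, ode = ode),
            class = "predictive_band")
}

#' @export
print.predictive_band <- function(x, ...) {
  cat(sprintf(
    "predictive band: %d points x %d states, levels %s, %d draws%s\n",
    nrow(x$mean), ncol(x$mean),
    paste(x$levels, collapse = "/"), x$n_draws,
    if (x$n_excluded) sprintf(" (%d excluded)", x$n_excluded) else ""))
  invisible(x)
}

#' @export
as.data.frame.predictive_band <- function(x, ...) {
  df <- data.frame(t = if (is.matrix(x$times)) seq_len(nrow(x$mean))
                       else x$times)
  for (j in seq_len(ncol(x$mean))) {
    nm <- colnames(x$mean)[j]
    df[[paste0(nm, ".mean")]] <- x$mean[, j]
    for (i in seq_along(x$levels)) {
      lv <- sprintf("%g", x$levels[i])
      df[[paste0(nm, ".lo", lv)]] <- x$lower[[i]][, j]
      df[[paste0(nm, ".hi", lv)]] <- x$upper[[i]][, j]
    }
  }
  df
}

#' Gaussian kernel density estimate of posterior samples
#'
#' Scott's-rule bandwidth; the default grid spans the sample mean plus or
#' minus six sample standard deviations, over which the estimate integrates
#' to 1 within 1%.
#'
#' @param samples Numeric samples (>= 2).
#' @param grid Optional evaluation grid.
#' @param n_grid Grid size when `grid` is omitted.
#' @return A list with `grid`, `density`, `bw`; or, for zero-variance
#'   samples, `point_mass = TRUE` and the `value`.
#' @export
density_summary <- function(samples, grid = NULL, n_grid = 512L) {
  if (length(samples) < 2L) stop("need at least 2 samples")
  s <- stats::sd(samples)
  if (s == 0)
    return(list(point_mass = TRUE, value = samples[1L]))
  bw <- stats::bw.nrd(samples)
  if (is.null(grid))
    grid <- seq(mean(samples) - 6 * s, mean(samples) + 6 * s,
                length.out = n_grid)
  dens <- vapply(grid, function(g) mean(stats::dnorm(g, samples, bw)),
                 numeric(1))
  list(point_mass = FALSE, grid = grid, density = dens, bw = bw)
}
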