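#' Fit a Bayesian polynomial neural network or neural ODE
#'
#' The main entry point of the package.  For time-series data (a data frame
#' with a `t` column, one column per state variable and optionally a
#' `replicate` column) it fits a polynomial neural ODE: the data are
#' optionally pre-smoothed with Gaussian process regression to supply
#' window initial conditions, batched into overlapping windows, and the
#' pi-net right-hand side is trained by MAP; the selected posterior engine
#' then yields a parameter posterior that is propagated by Monte Carlo to
#' posteriors over the expanded polynomial coefficients.  For plain
#' regression data (no `t` column) the same pipeline runs without ODE
#' integration.
#'
#' @param data Data frame: a trajectory (`t`, states, optional `replicate`)
#'   or a regression table (inputs plus a `response` column).
#' @param degree Polynomial degree of the pi-net.
#' @param method Posterior engine: `"laplace"` (default), `"nuts"`,
#'   `"hmc"`, or `"vi"`.
#' @param hidden Hidden width (default 10).
#' @param response For regression data: name of the response column
#'   (default: the last column).
#' @param window Training window length `L` (ODE only).
#' @param smooth GPR kernel for pre-smoothing (`"periodic"`, `"rq"`,
#'   `"rbf"`, `"matern"`) or `"none"` to use the observed (replicate-mean)
#'   values as window initial conditions.
#' @param known Optional parameter-free `ode_field` of known dynamics; the
#'   network then learns only the missing terms.
#' @param prior A [prior_spec()].
#' @param control A [map_control()].
#' @param mcmc_settings An [hmc_settings()] (MCMC methods).
#' @param vi_control A [vi_settings()] (VI).
#' @param substeps Integration substeps per observation interval.
#' @param n_samples Monte Carlo draws for coefficient propagation.
#' @param levels Credible levels reported by [summary.polynode()].
#' @param seed Seed governing initialization, sampling and propagation.
#' @return An object of class `polynode`; see [summary.polynode()],
#'   [coef.polynode()], [predict.polynode()], [plot.polynode()],
#'   [simulate.polynode()], [residuals.polynode()].
#' @examples
#' ds <- generate_dataset(experiment_spec("cubic", n_points = 50,
#'                                        noise_sd = 1, seed = 7))
#' fit <- polynode(ds$replicates[c("x", "y")], degree = 3, hidden = 4,
#'                 n_samples = 200, seed = 7)
#' coef(fit)
#' @export
polynode <- function(data, degree,
                     method = c("laplace", "nuts", "hmc", "vi"),
                     hidden = 10L, response = NULL, window = 12L,
                     smooth = c("auto", "none", "periodic", "rq", "rbf",
                                "matern"),
                     known = NULL, prior = prior_spec(),
                     control = map_control(),
                     mcmc_settings = hmc_settings(),
                     vi_control = vi_settings(),
                     substeps = 10L, n_samples = 2000L,
                     levels = c(0.95, 0.997), seed = 1L) {
  method <- match.arg(method)
  smooth <- match.arg(smooth)
  data <- as.data.frame(data)
  ode <- "t" %in% names(data)
  smoother <- NULL
  if (ode) {
    parts <- split_series(data)
    d <- length(parts$state_names)
    config <- pinet_config(d, d, degree, hidden,
                           state_names = parts$state_names)
    if (smooth == "auto") smooth <- "rq"
    if (smooth != "none")
      smoother <- fit_gpr(data, kernel = smooth, seed = seed)
    batches <- make_batches(data, L = window,
                            y0_source = if (is.null(smoother)) "observed"
                                        else "smoother",
                            smoother = smoother)
    field <- pinet_field(config)
    if (!is.null(known)) field <- augment_with_known(known, field)
    model <- pn_ode_model(field, batches, substeps = substeps)
  } else {
    if (is.null(response)) response <- names(data)[ncol(data)]
    xcols <- setdiff(names(data), response)
    if (!length(xcols)) stop("no input columns left for the regression")
    config <- pinet_config(length(xcols), length(response), degree, hidden,
                           state_names = xcols)
    model <- pn_regression(config, as.matrix(data[xcols]),
                           as.matrix(data[response]))
  }
  map <- train_map(model, prior = prior, control = control, seed = seed)
  if (method %in% c("nuts", "hmc") &&
      is.null(mcmc_settings$init_inv_mass)) {
    ## precondition the sampler with the (capped) Fisher curvature at the
    ## MAP; NUTS then runs in whitened coordinates
    fish <- fisher_information(map$theta_star, model, map$beta2,
                               prior = prior)
    mcmc_settings$init_inv_mass <- if (method == "nuts")
      fisher_metric(fish) else 1 / pmax(diag(fish$matrix), 1e-12)
  }
  posterior <- switch(method,
    laplace = laplace_posterior(
      map$theta_star,
      fisher_information(map$theta_star, model, map$beta2, prior = prior)),
    nuts = sample_nuts(pn_logjoint(model, map$beta2, prior),
                       map$theta_star, settings = mcmc_settings,
                       seed = seed),
    hmc = sample_hmc(pn_logjoint(model, map$beta2, prior),
                     map$theta_star, settings = mcmc_settings, seed = seed),
    vi = fit_vi(pn_loglik(model, map$beta2), map$theta_star, prior = prior,
                settings = vi_control, seed = seed))
  coef_samples <- sample_coefficients(posterior, config,
                                      n_samples = n_samples, seed = seed)
  structure(list(config = config, model = model, map = map,
                 posterior = posterior, coef_samples = coef_samples,
                 beta2 = map$beta2, smoother = smoother,
                 method = method, mode = if (ode) "ode" else "regression",
                 known = known, prior = prior, levels = levels,
                 substeps = substeps, data = data, seed = seed,
                 call = match.call()),
            class = "polynode")
}

#' @export
print.polynode <- function(x, ...) {
  cat(sprintf(
    "Bayesian polynomial neural %s (degree %d, %d parameters, %s posterior)\n",
    if (x$mode == "ode") "ODE" else "network", x$config$degree,
    count_parameters(x$config), x$method))
  cat(sprintf("noise variance estimate: %.4g\n", x$beta2))
  cat("\nPosterior-mean polynomial:\n")
  print(map_polyform(x), digits = 3)
  invisible(x)
}

## polyform at the posterior coefficient means, with ODE-style output names
map_polyform <- function(x) {
  pf <- expand_to_polynomial(x$map$theta_star, x$config)
  means <- vapply(x$coef_samples$samples, colMeans,
                  numeric(length(x$coef_samples$labels)))
  pf$coefficients <- t(means)
  colnames(pf$coefficients) <- x$coef_samples$labels
  rownames(pf$coefficients) <-
    if (x$mode == "ode") paste0("d", x$config$state_names, "/dt")
    else rownames(pf$coefficients)
  pf
}

#' Summarize a polynode fit
#'
#' Posterior mean, standard deviation, and equal-tailed credible intervals
#' for every expanded polynomial coefficient.
#'
#' @param object A [polynode()] fit.
#' @param levels Credible levels (defaults to those stored in the fit).
#' @param ... Unused.
#' @return A `summary.polynode` data frame.
#' @export
summary.polynode <- function(object, levels = object$levels, ...) {
  tab <- summary(object$coef_samples, levels = levels)
  if (object$mode == "ode") {
    map_nm <- paste0("d", object$config$state_names, "/dt")
    tab$output <- map_nm[match(tab$output,
                               paste0("f", seq_along(map_nm)))]
  }
  structure(tab, class = c("summary.polynode", "data.frame"),
            method = object$method, beta2 = object$beta2)
}

#' @export
print.summary.polynode <- function(x, digits = 4, ...) {
  cat(sprintf("coefficient posteriors (%s; noise variance %.4g):\n",
              attr(x, "method"), attr(x, "beta2")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Posterior-mean polynomial coefficients
#'
#' @param object A [polynode()] fit.
#' @param type `"posterior_mean"` (default) or `"map"` (expansion of the
#'   MAP parameters).
#' @param ... Unused.
#' @return A named vector (one output) or matrix of coefficients, columns
#'   labelled by monomial.
#' @export
coef.polynode <- function(object, type = c("posterior_mean", "map"), ...) {
  type <- match.arg(type)
  co <- if (type == "map")
    expand_to_polynomial(object$map$theta_star, object$config)$coefficients
  else t(vapply(object$coef_samples$samples, colMeans,
                numeric(length(object$coef_samples$labels))))
  rownames(co) <- paste0("f", seq_len(nrow(co)))
  colnames(co) <- object$coef_samples$labels
  if (nrow(co) == 1L) drop(co) else co
}

#' Posterior-predictive bands from a polynode fit
#'
#' @param object A [polynode()] fit.
#' @param newdata Regression inputs (regression fits).
#' @param times Output time grid (ODE fits; defaults to the training grid).
#' @param y0 Initial state (ODE fits; defaults to the smoothed -- or
#'   observed -- state at the first training time).
#' @param levels Credible levels.
#' @param n_samples Posterior draws.
#' @param ... Unused.
#' @return A `predictive_band`.
#' @export
predict.polynode <- function(object, newdata = NULL, times = NULL,
                             y0 = NULL, levels = object$levels,
                             n_samples = 500L, ...) {
  if (object$mode == "ode") {
    tgrid <- sort(unique(object$data$t))
    if (is.null(times)) times <- tgrid
    if (is.null(y0)) {
      y0 <- if (!is.null(object$smoother))
        drop(initial_conditions(object$smoother, tgrid[1L]))
      else unlist(object$data[which.min(object$data$t),
                              object$config$state_names][1L, ])
    }
    posterior_predictive(object$posterior, object$config, y0 = y0,
                         grid = times, known = object$known,
                         levels = levels, n_samples = n_samples,
                         seed = object$seed, substeps = object$substeps)
  } else {
    if (is.null(newdata)) newdata <- object$model$X
    posterior_predictive(object$posterior, object$config,
                         newdata = newdata, levels = levels,
                         n_samples = n_samples, seed = object$seed)
  }
}

#' MAP residuals of a polynode fit
#'
#' @param object A [polynode()] fit.
#' @param ... Unused.
#' @return Residual vector `y_pred - y_known` at the MAP estimate.
#' @export
residuals.polynode <- function(object, ...) {
  model_residuals(object$model, object$map$theta_star)$r
}

#' Simulate from a polynode fit's posterior
#'
#' Each simulation draws one parameter vector from the posterior and
#' evaluates the implied model (ODE trajectory or regression curve) without
#' observation noise.
#'
#' @param object A [polynode()] fit.
#' @param nsim Number of simulations.
#' @param seed Seed.
#' @param times,y0,newdata As in [predict.polynode()].
#' @param ... Unused.
#' @return A list of data frames, one per simulation.
#' @export
simulate.polynode <- function(object, nsim = 1, seed = NULL, times = NULL,
                              y0 = NULL, newdata = NULL, ...) {
  if (is.null(seed)) seed <- object$seed
  Theta <- with_local_seed(seed,
                           posterior_theta_draws(object$posterior, nsim))
  if (object$mode == "ode") {
    tgrid <- sort(unique(object$data$t))
    if (is.null(times)) times <- tgrid
    if (is.null(y0)) {
      y0 <- if (!is.null(object$smoother))
        drop(initial_conditions(object$smoother, tgrid[1L]))
      else unlist(object$data[which.min(object$data$t),
                              object$config$state_names][1L, ])
    }
    field <- pinet_field(object$config)
    if (!is.null(object$known))
      field <- augment_with_known(object$known, field)
    lapply(seq_len(nrow(Theta)), function(s) {
      tr <- integrate_rkf45(field, Theta[s, ], y0, times,
                            substeps = object$substeps)
      colnames(tr$states) <- object$config$state_names
      as.data.frame(tr)
    })
  } else {
    if (is.null(newdata)) newdata <- object$model$X
    lapply(seq_len(nrow(Theta)), function(s) {
      yhat <- pinet_forward(Theta[s, ], object$config,
                            as.matrix(newdata))
      data.frame(x = as.matrix(newdata), y = yhat)
    })
  }
}

#' Plot a polynode fit
#'
#' Base-graphics display of the data, posterior-predictive mean and
#' credible bands (one panel per state for ODE fits).
#'
#' @param x A [polynode()] fit.
#' @param band A precomputed [predict.polynode()] result (computed if
#'   omitted).
#' @param ... Passed to [plot()].
#' @return Invisibly, the band used.
#' @export
plot.polynode <- function(x, band = NULL, ...) {
  if (is.null(band)) band <- predict(x, n_samples = 200L)
  m <- ncol(band$mean)
  op <- graphics::par(mfrow = c(m, 1L), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  i_lo <- length(band$levels)
  for (j in seq_len(m)) {
    nm <- colnames(band$mean)[j]
    xv <- band$times
    ylim <- range(band$lower[[i_lo]][, j], band$upper[[i_lo]][, j])
    if (x$mode == "ode") {
      obs <- x$data[[nm]]
      ylim <- range(ylim, obs)
      plot(x$data$t, obs, pch = 16, cex = 0.4, col = "grey60",
           xlab = "t", ylab = nm, ylim = ylim, ...)
    } else {
      plot(x$model$X[, 1L], x$model$Y[, j], pch = 16, cex = 0.4,
           col = "grey60", xlab = x$config$state_names[1L], ylab = "y",
           ylim = range(ylim, x$model$Y[, j]), ...)
    }
    for (i in seq_along(band$levels)) {
      graphics::polygon(c(xv, rev(xv)),
                        c(band$lower[[i]][, j], rev(band$upper[[i]][, j])),
                        border = NA,
                        col = grDevices::adjustcolor("steelblue",
                                                     0.15 + 0.1 * i))
    }
    graphics::lines(xv, band$mean[, j], col = "firebrick", lwd = 2)
  }
  invisible(band)
}

#' Convergence diagnostics of a polynode fit
#'
#' For MCMC fits, the Geweke statistic per expanded polynomial coefficient
#' (the coefficient chains are obtained by expanding each stored draw);
#' for VI, the tail of the ELBO trace; for Laplace, the Fisher rank.
#'
#' @param object A [polynode()] fit.
#' @param ... Passed to [geweke()].
#' @return A `geweke_result` for MCMC fits, otherwise a summary list.
#' @export
diagnostics <- function(object, ...) {
  stopifnot(inherits(object, "polynode"))
  if (inherits(object$posterior, "chain_samples")) {
    chains <- do.call(cbind, lapply(seq_along(object$coef_samples$samples),
      function(j) {
        S <- object$coef_samples$samples[[j]]
        colnames(S) <- paste0("f", j, ".", colnames(S))
        S
      }))
    geweke(chains, ...)
  } else if (object$method == "vi") {
    tr <- attr(object$posterior, "elbo_trace")
    list(method = "vi", final_elbo = tr[length(tr)],
         elbo_tail = utils::tail(tr, 10L))
  } else {
    list(method = "laplace",
         fisher_rank = attr(object$posterior, "fisher_rank"))
  }
}
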