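#' Gaussian prior specification for network parameters
#'
#' A zero-mean isotropic Gaussian prior applied i.i.d. to every weight and
#' bias.  The default standard deviation of 1e5 is deliberately
#' noninformative: network parameters are not expected to be large, but
#' nothing more is assumed.
#'
#' @param alpha Prior standard deviation (> 0; default `1e5`).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(alpha = 1e5) {
  stopifnot(alpha > 0)
  structure(list(alpha = alpha), class = "prior_spec")
}

#' Gaussian log-likelihood of residuals
#'
#' Computes \eqn{-\frac{1}{2\beta^2}\sum (y_{pred} - y_{known})^2}, i.e. the
#' log-density of i.i.d. zero-mean Gaussian observation noise with variance
#' `beta2`, up to the additive normalization constant.
#'
#' @param y_pred,y_known Predicted and observed values (same shape).
#' @param beta2 Observation noise variance (> 0).
#' @return Scalar log-likelihood (up to an additive constant).
#' @export
log_likelihood <- function(y_pred, y_known, beta2) {
  if (beta2 <= 0) stop("beta2 must be positive")
  if (length(y_pred) != length(y_known))
    stop("y_pred and y_known differ in length")
  -sum((y_pred - y_known)^2) / (2 * beta2)
}

#' Gaussian log-prior on parameters
#'
#' \eqn{-\frac{1}{2}\theta^T \theta / \alpha^2} for the isotropic zero-mean
#' prior of [prior_spec()].
#'
#' @param theta Parameter vector.
#' @param prior A [prior_spec()].
#' @return Scalar log-prior (up to an additive constant).
#' @export
log_prior <- function(theta, prior = prior_spec()) {
  -sum(theta^2) / (2 * prior$alpha^2)
}

#' Log-joint density (log-likelihood + log-prior)
#'
#' @inheritParams log_likelihood
#' @inheritParams log_prior
#' @return Scalar log-joint, up to an additive constant.
#' @export
log_joint <- function(y_pred, y_known, theta, beta2, prior = prior_spec()) {
  log_likelihood(y_pred, y_known, beta2) + log_prior(theta, prior)
}

#' Residual-based estimate of the observation noise variance
#'
#' The sample variance (denominator `n`) of the pooled residual vector,
#' centered at its own mean; residuals from all state dimensions, windows,
#' and replicates are pooled into this single scalar.
#'
#' @param residuals Numeric vector of residuals `y_pred - y_known`
#'   (length >= 2).
#' @return The estimated noise variance.
#' @export
estimate_noise_variance <- function(residuals) {
  if (length(residuals) < 2L) stop("need at least 2 residuals")
  r <- residuals - mean(residuals)
  sum(r^2) / length(r)
}

#' Define a pi-net regression model
#'
#' Pairs a pi-net with a plain regression dataset `y = net(x) + noise`
#' (no ODE integration); used for the univariate cubic benchmark.
#'
#' @param config A [pinet_config()].
#' @param X `n x state_dim` input matrix.
#' @param Y `n x output_dim` response matrix (a vector is accepted when
#'   `output_dim == 1`).
#' @return An object of class `pn_model`.
#' @export
pn_regression <- function(config, X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(ncol(X) == config$state_dim, ncol(Y) == config$output_dim,
            nrow(X) == nrow(Y))
  model <- structure(list(type = "regression", config = config, X = X,
                          Y = Y, n_params = count_parameters(config),
                          n_obs = length(Y)),
                     class = "pn_model")
  ## Sufficient-statistic compression: the network output lies in the span
  ## of the monomial basis, so the SSE over n points is a quadratic form in
  ## the M expanded coefficients, recoverable from evaluations at M
  ## well-conditioned collocation points.  Exact for any parameter value.
  exps <- monomial_basis(config$state_dim, config$degree)
  M <- nrow(exps)
  if (nrow(X) > M) {
    Xc <- colloc_points(X, exps)
    if (!is.null(Xc)) {
      B <- design_matrix(X, exps)
      model$proj <- list(Xc = Xc, Vinv = solve(design_matrix(Xc, exps)),
                         G2 = crossprod(B), By = crossprod(B, Y),
                         yss = sum(Y^2))
    }
  }
  model
}

#' Define a linear-in-parameters regression model
#'
#' `y = X theta + noise`, sharing the training / Fisher / posterior
#' machinery of the pi-net models.  On such a model the Laplace
#' approximation is exact and coincides with closed-form Bayesian linear
#' regression ([blr_posterior()]), which makes it the reference case for
#' validating the nonlinear pipeline.
#'
#' @param X Design matrix.
#' @param y Response vector.
#' @return An object of class `pn_model` with `type = "linear"`.
#' @export
pn_linear <- function(X, y) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  structure(list(type = "linear", X = X, Y = as.numeric(y),
                 n_params = ncol(X), n_obs = length(y)),
            class = "pn_model")
}

## M collocation points with a well-conditioned monomial design matrix:
## Chebyshev nodes for one input variable, otherwise a seeded random
## search over the data bounding box.  NULL when no well-conditioned set
## is found (callers then evaluate the objective directly).
colloc_points <- function(X, exps) {
  M <- nrow(exps); d <- ncol(X)
  if (d == 1L) {
    rng <- range(X)
    nodes <- cos((2 * seq_len(M) - 1) / (2 * M) * pi)
    Xc <- matrix(mean(rng) + diff(rng) / 2 * nodes, ncol = 1L)
    if (kappa(design_matrix(Xc, exps)) < 1e8) return(Xc)
    return(NULL)
  }
  lo <- apply(X, 2L, min); hi <- apply(X, 2L, max)
  with_local_seed(202L, {
    best <- NULL; best_k <- Inf
    for (try in 1:50) {
      Xc <- sapply(seq_len(d), function(j) runif(M, lo[j], hi[j]))
      k <- kappa(design_matrix(Xc, exps))
      if (k < best_k) { best <- Xc; best_k <- k }
      if (best_k < 1e6) break
    }
    if (best_k < 1e8) best else NULL
  })
}

#' Define a pi-net neural-ODE model over batched windows
#'
#' Each evaluation integrates all windows of `batches` simultaneously with
#' the fixed-step RKF45 scheme and compares the integrated states to every
#' replicate's observations.
#'
#' @param field An `ode_field` ([pinet_field()] or [augment_with_known()]).
#' @param batches A [make_batches()] object.
#' @param substeps Fixed integration substeps per observation interval.
#' @return An object of class `pn_model`.
#' @export
pn_ode_model <- function(field, batches, substeps = 10L) {
  stopifnot(inherits(field, "ode_field"),
            inherits(batches, "trajectory_batch"))
  if (field$state_dim != batches$state_dim)
    stop("field and batches disagree on state dimension")
  cfg <- if (field$kind == "sum") field$learned$config else field$config
  structure(list(type = "ode", field = field, batches = batches,
                 substeps = as.integer(substeps), config = cfg,
                 n_params = field$n_params,
                 n_obs = length(batches$targets)),
            class = "pn_model")
}

#' @export
print.pn_model <- function(x, ...) {
  cat(sprintf("pi-net %s model: %d parameters, %d observations\n",
              x$type, x$n_params, x$n_obs))
  invisible(x)
}

## Residual vector r = y_pred - y_known (and its Jacobian d r / d theta).
## Regression: residuals are stacked column-major over (observation, output).
## ODE: entries ordered (window, time, state, replicate), column-major; the
## Jacobian rows for replicate copies are identical because all replicates
## share each window's integrated prediction.
model_residuals <- function(model, theta, jacobian = FALSE) {
  if (model$type == "linear") {
    r <- drop(model$X %*% theta) - model$Y
    return(list(r = r, J = if (jacobian) model$X, pred = r + model$Y))
  }
  if (model$type == "regression") {
    params <- pinet_unpack(theta, model$config)
    ev <- pinet_eval(params, model$config, model$X,
                     jacobian = if (jacobian) "theta" else "none")
    r <- as.vector(ev$y - model$Y)
    J <- if (jacobian) do.call(rbind, ev$jtheta)
    return(list(r = r, J = J, pred = ev$y))
  }
  b <- model$batches
  res <- rkf45_batch(model$field, theta, b$y0, b$times,
                     substeps = model$substeps, sens = jacobian)
  Nt <- b$n_windows; L <- b$L; d <- b$state_dim; R <- b$n_replicates
  resid <- array(res$states, c(Nt, L, d, R)) - b$targets
  r <- as.vector(resid)
  J <- NULL
  if (jacobian) {
    Jbase <- do.call(rbind, lapply(seq_len(d), function(a)
      do.call(rbind, lapply(seq_len(L), function(l) res$sens[[l]][[a]]))))
    J <- Jbase[rep.int(seq_len(Nt * L * d), R), , drop = FALSE]
  }
  list(r = r, J = J, pred = res$states)
}

## SSE and its gradient.  Regression models use a single reverse pass
## (vector-Jacobian product); ODE models go through the forward
## sensitivities.
model_sse_grad <- function(model, theta) {
  if (model$type == "linear") {
    r <- drop(model$X %*% theta) - model$Y
    return(list(sse = sum(r^2), grad = 2 * drop(crossprod(model$X, r))))
  }
  if (model$type == "regression") {
    cfg <- model$config
    h <- cfg$hidden_widths[1L]; h2 <- cfg$hidden_widths[cfg$degree + 1L]
    out <- if (!is.null(model$proj))
      pinet_proj_sse_grad_cpp(theta, cfg$degree, h, h2, cfg$output_dim,
                              model$proj$Xc, model$proj$Vinv,
                              model$proj$G2, model$proj$By,
                              model$proj$yss)
    else pinet_sse_grad_cpp(theta, cfg$degree, h, h2, cfg$output_dim,
                            model$X, model$Y)
    list(sse = out$sse, grad = drop(out$grad))
  } else {
    rj <- model_residuals(model, theta, jacobian = TRUE)
    list(sse = sum(rj$r^2), grad = 2 * drop(crossprod(rj$J, rj$r)))
  }
}

#' Training control settings
#'
#' @param optimizer `"auto"` (default: Adam for regression models,
#'   Levenberg-Marquardt for ODE models), `"adam"` (first-order gradient
#'   descent of the penalised least-squares objective, starting from the
#'   tiny-coefficient initialization -- which keeps the selected optimum at
#'   small parameter norm, a property the posterior engines benefit from),
#'   or `"lm"` (Levenberg-Marquardt with the exact analytic residual
#'   Jacobian from the forward sensitivities; far fewer objective
#'   evaluations, which matters when every evaluation integrates all
#'   training windows).
#' @param epochs Adam epochs; defaults to 5000 for regression models and
#'   10000 for ODE models.
#' @param lr Adam learning rate (default `1e-3`).
#' @param maxit Maximum Levenberg-Marquardt iterations (default 200).
#' @param include_prior Keep the (numerically tiny, at the default prior)
#'   ridge term in the MAP objective (default `TRUE`); with `FALSE` the MAP
#'   is a pure least-squares fit.
#' @return A list of class `map_control`.
#' @export
map_control <- function(optimizer = c("auto", "lm", "adam"), epochs = NULL,
                        lr = 1e-3, maxit = 200L, include_prior = TRUE) {
  structure(list(optimizer = match.arg(optimizer), epochs = epochs,
                 lr = lr, maxit = as.integer(maxit),
                 include_prior = isTRUE(include_prior)),
            class = "map_control")
}

#' MAP training of a pi-net (regression or neural-ODE) model
#'
#' Maximizes the log-joint density with the constant \eqn{1/(2\beta^2)}
#' likelihood scale dropped, i.e. minimizes
#' \eqn{\sum (y_{pred} - y_{known})^2 + \theta^T\theta / (2\alpha^2)}.
#' Every evaluation integrates (for ODE models) all batch windows
#' simultaneously.  The observation noise variance \eqn{\beta^2} is not
#' learned during training; it is estimated afterwards as the sample
#' variance of the pooled residuals at the optimum and reinstated for all
#' posterior computations.
#'
#' @param model A [pn_regression()] or [pn_ode_model()].
#' @param prior A [prior_spec()].
#' @param control A [map_control()].
#' @param init Initial parameters (list or flat vector); defaults to
#'   [pinet_init()] with `seed`.
#' @param seed Seed for the default initialization.
#' @return An object of class `map_result` with `theta_star`, `value` (the
#'   minimized objective), `trace` (objective per iteration), `beta2`, and
#'   `converged`.
#' @export
train_map <- function(model, prior = prior_spec(), control = map_control(),
                      init = NULL, seed = 1L) {
  stopifnot(inherits(model, "pn_model"))
  if (is.null(init))
    init <- if (model$type == "linear") numeric(model$n_params)
            else pinet_init(model$config, seed)
  theta0 <- if (is.numeric(init) && is.null(dim(init))) init
            else pinet_pack(init, model$config)
  if (length(theta0) != model$n_params)
    stop("initial parameter vector has the wrong length")
  optimizer <- control$optimizer
  if (optimizer == "auto")
    optimizer <- if (model$type == "regression") "adam" else "lm"
  lambda <- if (control$include_prior) 1 / (2 * prior$alpha^2) else 0
  n_obs <- model$n_obs
  guarded <- function(theta, jacobian) {
    tryCatch(model_residuals(model, theta, jacobian = jacobian),
             error = function(e) list(
               r = rep(1e6, n_obs),
               J = if (jacobian) matrix(0, n_obs, length(theta)),
               pred = NULL))
  }
  if (optimizer == "lm") {
    sl <- sqrt(lambda)
    fn <- function(theta) {
      r <- guarded(theta, FALSE)$r
      r[!is.finite(r)] <- 1e6
      c(r, sl * theta)
    }
    jac <- function(theta) {
      J <- guarded(theta, TRUE)$J
      J[!is.finite(J)] <- 0
      rbind(J, diag(sl, length(theta)))
    }
    fit <- minpack.lm::nls.lm(par = theta0, fn = fn, jac = jac,
                              control = minpack.lm::nls.lm.control(
                                maxiter = control$maxit, nprint = 0))
    theta_star <- fit$par
    trace <- fit$rsstrace
    value <- fit$deviance
    converged <- fit$info %in% 1:4
  } else {
    epochs <- control$epochs
    if (is.null(epochs)) epochs <- if (model$type == "ode") 10000L else 5000L
    theta <- theta0
    m1 <- v1 <- numeric(length(theta))
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    trace <- numeric(epochs)
    for (e in seq_len(epochs)) {
      sg <- tryCatch(model_sse_grad(model, theta),
                     error = function(err) list(sse = NaN, grad = theta))
      g <- sg$grad + 2 * lambda * theta
      obj <- sg$sse + lambda * sum(theta^2)
      if (!is.finite(obj)) stop("NaN objective at epoch ", e)
      trace[e] <- obj
      m1 <- b1 * m1 + (1 - b1) * g
      v1 <- b2 * v1 + (1 - b2) * g^2
      mh <- m1 / (1 - b1^e); vh <- v1 / (1 - b2^e)
      theta <- theta - control$lr * mh / (sqrt(vh) + eps)
    }
    theta_star <- theta
    value <- trace[epochs]
    converged <- TRUE
  }
  resid <- model_residuals(model, theta_star, jacobian = FALSE)$r
  structure(list(theta_star = theta_star, value = value, trace = trace,
                 beta2 = estimate_noise_variance(resid),
                 converged = converged, model_type = model$type,
                 n_obs = n_obs),
            class = "map_result")
}

#' @export
print.map_result <- function(x, ...) {
  cat(sprintf(
    "MAP fit (%s): %d parameters, objective %.6g, noise variance %.4g%s\n",
    x$model_type, length(x$theta_star), x$value, x$beta2,
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Serialize a MAP result to JSON
#'
#' @param x A `map_result`.
#' @param path Optional output path.
#' @return JSON string (invisibly when written).
#' @export
map_to_json <- function(x, path = NULL) {
  js <- jsonlite::toJSON(list(theta_star = x$theta_star, value = x$value,
                              beta2 = x$beta2, converged = x$converged),
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
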