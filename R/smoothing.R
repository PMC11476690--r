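#' Gaussian-process kernel specification
#'
#' All kernels are scaled by a constant kernel `c2` and accompanied by a
#' white-noise term `sigma2` that contributes only on the diagonal:
#' \itemize{
#' \item `periodic` (exp-sine-squared):
#'   \eqn{c^2 \exp(-2 \sin^2(\pi d / p) / l^2)}
#' \item `rq` (rational quadratic):
#'   \eqn{c^2 (1 + d^2 / (2 \alpha_{rq} l^2))^{-\alpha_{rq}}}
#' \item `rbf`: \eqn{c^2 \exp(-d^2 / (2 l^2))}
#' \item `matern` (smoothness 5/2)
#' }
#' with `d` the Euclidean distance on scalar time.
#'
#' @param variant One of `"periodic"`, `"rq"`, `"rbf"`, `"matern"`.
#' @param c2 Constant-kernel scale (> 0).
#' @param l Length-scale (> 0).
#' @param p Periodicity (periodic kernel only).
#' @param alpha_rq Scale-mixture parameter (rational quadratic only).
#' @param sigma2 White-noise variance (> 0).
#' @return A list of class `kernel_spec`.
#' @export
kernel_spec <- function(variant = c("periodic", "rq", "rbf", "matern"),
                        c2 = 1, l = 1, p = 1, alpha_rq = 1, sigma2 = 0.1) {
  variant <- match.arg(variant)
  if (any(c(c2, l, p, alpha_rq, sigma2) <= 0))
    stop("kernel hyperparameters must be strictly positive")
  structure(list(variant = variant, c2 = c2, l = l, p = p,
                 alpha_rq = alpha_rq, sigma2 = sigma2),
            class = "kernel_spec")
}

## kernel matrix without the white term, for time vectors t1, t2
kernel_matrix <- function(spec, t1, t2) {
  D <- abs(outer(t1, t2, `-`))
  switch(spec$variant,
    periodic = spec$c2 * exp(-2 * sin(pi * D / spec$p)^2 / spec$l^2),
    rq = spec$c2 * (1 + D^2 / (2 * spec$alpha_rq * spec$l^2))^
           (-spec$alpha_rq),
    rbf = spec$c2 * exp(-D^2 / (2 * spec$l^2)),
    matern = {
      u <- sqrt(5) * D / spec$l
      spec$c2 * (1 + u + u^2 / 3) * exp(-u)
    })
}

#' Evaluate a kernel between two time points
#'
#' The white-noise variance is added only when `same_index` is `TRUE`
#' (i.e. on the Gram-matrix diagonal), never from mere coincidence of time
#' values.
#'
#' @param spec A [kernel_spec()].
#' @param t_i,t_j Scalar times.
#' @param same_index Whether the two points are the same observation.
#' @return Scalar kernel value.
#' @export
kernel_eval <- function(spec, t_i, t_j, same_index = FALSE) {
  stopifnot(inherits(spec, "kernel_spec"))
  kernel_matrix(spec, t_i, t_j)[1L] + if (same_index) spec$sigma2 else 0
}

## pack/unpack free hyperparameters in log space
kernel_free <- function(variant) {
  switch(variant,
         periodic = c("c2", "l", "p", "sigma2"),
         rq = c("c2", "l", "alpha_rq", "sigma2"),
         c("c2", "l", "sigma2"))
}

## Exact pooled marginal log-likelihood for R replicates sharing the time
## grid: a GP term on the replicate means (white variance sigma2 / R) plus
## the within-replicate scatter under the white-noise model.
gpr_negloglik <- function(logh, variant, tgrid, ybar, ssw, R) {
  free <- kernel_free(variant)
  h <- as.list(exp(logh)); names(h) <- free
  spec <- do.call(kernel_spec, c(list(variant = variant), h))
  n <- length(tgrid)
  K <- kernel_matrix(spec, tgrid, tgrid) +
    diag(spec$sigma2 / R + 1e-8 * spec$c2, n)
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  a <- backsolve(ch, backsolve(ch, ybar, transpose = TRUE))
  nll <- 0.5 * sum(ybar * a) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi)
  if (R > 1L)
    nll <- nll + 0.5 * n * (R - 1L) * log(2 * pi * spec$sigma2) +
      ssw / (2 * spec$sigma2)
  if (!is.finite(nll)) 1e10 else nll
}

#' Fit a Gaussian-process smoother to (replicated) noisy trajectories
#'
#' One independent GP per state dimension, with kernel hyperparameters
#' maximizing the marginal likelihood (multi-restart L-BFGS-B in log space,
#' bounded three decades around data-driven initial guesses).  Replicate
#' trajectories share the time grid, so they are pooled exactly: the
#' marginal likelihood factorizes into a GP on the replicate means (white
#' variance `sigma2 / R`) plus the within-replicate scatter term.
#'
#' @param series Trajectory data frame (`t`, state columns, optional
#'   `replicate`).
#' @param kernel Kernel variant (see [kernel_spec()]); the periodic kernel
#'   suits oscillatory systems, the rational quadratic the others.
#' @param restarts Number of random restarts (default 5).
#' @param seed Seed for the restart draws; the fit is deterministic given
#'   it.
#' @param max_points Hyperparameters are optimized on an evenly thinned
#'   subset of at most this many time points (default 400; the cubic cost
#'   of the marginal likelihood makes longer grids wasteful, and kernel
#'   hyperparameters are insensitive to the thinning); the final predictive
#'   equations always use the full grid.
#' @return An object of class `gpr_fit` with per-dimension fitted
#'   [kernel_spec()]s, predictive-mean state, and the total marginal
#'   log-likelihood.
#' @export
fit_gpr <- function(series, kernel = c("periodic", "rq", "rbf", "matern"),
                    restarts = 5L, seed = 1L, max_points = 400L) {
  kernel <- match.arg(kernel)
  parts <- split_series(series)
  tgrid <- parts$times; R <- length(parts$states)
  n <- length(tgrid)
  if (n < 5L) stop("need at least 5 time points per state dimension")
  d <- ncol(parts$states[[1L]])
  Ybar <- Reduce(`+`, parts$states) / R
  dims <- vector("list", d)
  total_ll <- 0
  span <- diff(range(tgrid))
  sub <- if (n > max_points)
    unique(round(seq(1L, n, length.out = max_points))) else seq_len(n)
  with_local_seed(seed, {
    for (j in seq_len(d)) {
      yj <- Ybar[, j]
      center <- mean(yj)
      yc <- yj - center
      ssw <- if (R > 1L)
        sum(vapply(parts$states, function(S) sum((S[, j] - yj)^2),
                   numeric(1)))
      else 0
      v <- stats::var(yc)
      init <- c(c2 = v, l = span / 10, p = span / 2, alpha_rq = 1,
                sigma2 = max(0.1 * v, 1e-6))
      free <- kernel_free(kernel)
      l0 <- log(init[free])
      lo <- l0 - log(1e3); hi <- l0 + log(1e3)
      best <- NULL
      for (s in seq_len(max(1L, restarts))) {
        start <- if (s == 1L) l0 else l0 + stats::runif(length(l0), -3, 3)
        start <- pmin(pmax(start, lo), hi)
        op <- tryCatch(
          stats::optim(start, gpr_negloglik, method = "L-BFGS-B",
                       lower = lo, upper = hi, variant = kernel,
                       tgrid = tgrid[sub], ybar = yc[sub],
                       ssw = ssw * length(sub) / n, R = R),
          error = function(e) NULL)
        if (!is.null(op) && (is.null(best) || op$value < best$value))
          best <- op
      }
      if (is.null(best)) stop("GPR hyperparameter optimization failed")
      h <- as.list(exp(best$par)); names(h) <- free
      spec <- do.call(kernel_spec, c(list(variant = kernel), h))
      K <- kernel_matrix(spec, tgrid, tgrid) +
        diag(spec$sigma2 / R + 1e-8 * spec$c2, n)
      ch <- chol(K)
      alpha <- backsolve(ch, backsolve(ch, yc, transpose = TRUE))
      dims[[j]] <- list(spec = spec, alpha = alpha, center = center)
      total_ll <- total_ll - best$value
    }
  })
  structure(list(dims = dims, times = tgrid, state_names = parts$state_names,
                 kernel = kernel, n_replicates = R, loglik = total_ll),
            class = "gpr_fit")
}

#' @export
print.gpr_fit <- function(x, ...) {
  cat(sprintf(
    "GPR smoother (%s kernel): %d states, %d time points, %d replicate(s), log-marginal-likelihood %.4g\n",
    x$kernel, length(x$dims), length(x$times), x$n_replicates, x$loglik))
  invisible(x)
}

#' Predictive mean of a GPR smoother
#'
#' @param object A [fit_gpr()] result.
#' @param newtimes Times at which to evaluate (must be inside the training
#'   span; the smoother interpolates, it does not extrapolate).
#' @param ... Unused.
#' @return Matrix `length(newtimes) x state_dim` of predictive means.
#' @export
predict.gpr_fit <- function(object, newtimes, ...) {
  initial_conditions(object, newtimes)
}

#' Smoothed initial conditions for training windows
#'
#' Returns the GP predictive mean at the requested window start times, per
#' state dimension.
#'
#' @param fit A [fit_gpr()] result.
#' @param times Window start times (inside the training span).
#' @return Matrix `length(times) x state_dim`.
#' @export
initial_conditions <- function(fit, times) {
  stopifnot(inherits(fit, "gpr_fit"))
  rng <- range(fit$times)
  if (any(times < rng[1L] - 1e-12) || any(times > rng[2L] + 1e-12))
    stop("requested times outside the smoother's training span [",
         rng[1L], ", ", rng[2L], "]; the smoother only interpolates")
  out <- vapply(fit$dims, function(dm) {
    Ks <- kernel_matrix(dm$spec, times, fit$times)
    drop(Ks %*% dm$alpha) + dm$center
  }, numeric(length(times)))
  matrix(out, nrow = length(times),
         dimnames = list(NULL, fit$state_names))
}

#' Export the smoothed trajectory as a standard trajectory CSV
#'
#' @param fit A [fit_gpr()] result.
#' @param path Output path.
#' @param times Evaluation times (defaults to the training grid).
#' @return Invisibly, `path`.
#' @export
smoother_write <- function(fit, path, times = fit$times) {
  M <- initial_conditions(fit, times)
  df <- data.frame(t = times)
  df[fit$state_names] <- as.data.frame(M)
  df$replicate <- 1L
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
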