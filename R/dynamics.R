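## ODE field abstraction.  A field is a right-hand-side contract
## f(t, y, theta) -> dy/dt, tagged by kind ("pinet", "known", "sum"), with a
## batched evaluator used by the fixed-step integrator and by training.  The
## batched evaluator optionally returns, per state dimension, the Jacobians
## of f with respect to the flat parameter vector and the state.

#' Wrap a pi-net as an ODE right-hand side
#'
#' The resulting field evaluates `dy/dt = pinet(y)` (autonomous); parameters
#' are passed as the flat vector of [pinet_pack()].
#'
#' @param config A [pinet_config()] with `output_dim == state_dim`.
#' @return An object of class `ode_field`.
#' @export
pinet_field <- function(config) {
  if (config$output_dim != config$state_dim)
    stop("a pi-net ODE field needs output_dim == state_dim")
  structure(list(kind = "pinet", state_dim = config$state_dim,
                 config = config, n_params = count_parameters(config)),
            class = "ode_field")
}

#' Wrap a known right-hand-side function as an ODE field
#'
#' @param fn Function `(t, y) -> dy/dt` (no trainable parameters).
#' @param state_dim State dimension.
#' @param jx Optional function `(t, y) -> state_dim x state_dim` Jacobian
#'   `d f / d y`; when omitted it is obtained by central finite differences
#'   where needed.
#' @return An object of class `ode_field`.
#' @export
known_field <- function(fn, state_dim, jx = NULL) {
  structure(list(kind = "known", state_dim = as.integer(state_dim),
                 fn = fn, jx = jx, n_params = 0L),
            class = "ode_field")
}

#' Sum of a known and a learned ODE field
#'
#' Implements missing-term learning: the trainable field only has to capture
#' the dynamics the known mechanistic model leaves unexplained, because the
#' effective right-hand side is `known(t, y) + learned(t, y, theta)`.
#'
#' @param known,learned `ode_field` objects sharing `state_dim`; `known` must
#'   be parameter-free.
#' @return An `ode_field` of kind `"sum"`.
#' @export
augment_with_known <- function(known, learned) {
  stopifnot(inherits(known, "ode_field"), inherits(learned, "ode_field"))
  if (known$state_dim != learned$state_dim)
    stop("state dimensions differ: ", known$state_dim, " vs ",
         learned$state_dim)
  if (known$n_params != 0L)
    stop("the known field must be parameter-free")
  structure(list(kind = "sum", state_dim = learned$state_dim,
                 known = known, learned = learned,
                 n_params = learned$n_params),
            class = "ode_field")
}

#' @export
print.ode_field <- function(x, ...) {
  cat(sprintf("ODE field (%s), %d states, %d parameters\n",
              x$kind, x$state_dim, x$n_params))
  invisible(x)
}

## numeric Jacobian d f / d y for a known field, batched over rows of Y
known_jx_numeric <- function(field, tvec, Y, eps = 1e-6) {
  d <- field$state_dim
  n <- nrow(Y)
  out <- lapply(seq_len(d), function(a) matrix(0, n, d))
  for (b in seq_len(d)) {
    Yp <- Y; Yp[, b] <- Yp[, b] + eps
    Ym <- Y; Ym[, b] <- Ym[, b] - eps
    Fp <- known_eval_rows(field, tvec, Yp)
    Fm <- known_eval_rows(field, tvec, Ym)
    for (a in seq_len(d)) out[[a]][, b] <- (Fp[, a] - Fm[, a]) / (2 * eps)
  }
  out
}

known_eval_rows <- function(field, tvec, Y) {
  n <- nrow(Y)
  t(vapply(seq_len(n), function(i) field$fn(tvec[i], Y[i, ]),
           numeric(field$state_dim)))
}

## Batched field evaluation.  tvec: time per row (length n or scalar),
## Y: n x d.  Returns list(f = n x d, and when jacobian = TRUE also
## jtheta = list of d matrices n x p, jx = list of d matrices n x d).
field_eval <- function(field, tvec, Y, theta, jacobian = FALSE) {
  n <- nrow(Y)
  if (length(tvec) == 1L) tvec <- rep(tvec, n)
  switch(field$kind,
    pinet = {
      params <- pinet_unpack(theta, field$config)
      ev <- pinet_eval(params, field$config, Y,
                       jacobian = if (jacobian) "both" else "none")
      list(f = ev$y, jtheta = ev$jtheta, jx = ev$jx)
    },
    known = {
      f <- known_eval_rows(field, tvec, Y)
      if (!jacobian) return(list(f = f))
      jx <- if (is.null(field$jx)) known_jx_numeric(field, tvec, Y)
            else {
              J <- lapply(seq_len(n), function(i) field$jx(tvec[i], Y[i, ]))
              lapply(seq_len(field$state_dim), function(a)
                t(vapply(J, function(Ji) Ji[a, ], numeric(field$state_dim))))
            }
      list(f = f, jtheta = NULL, jx = jx)
    },
    sum = {
      evk <- field_eval(field$known, tvec, Y, NULL, jacobian)
      evl <- field_eval(field$learned, tvec, Y, theta, jacobian)
      out <- list(f = evk$f + evl$f)
      if (jacobian) {
        out$jtheta <- evl$jtheta
        out$jx <- lapply(seq_len(field$state_dim), function(a)
          evk$jx[[a]] + evl$jx[[a]])
      }
      out
    },
    stop("unknown field kind"))
}

## Runge-Kutta-Fehlberg stage coefficients; only the 4th-order solution
## (stages k1..k5) is used, the 5th-order embedded estimate is not computed.
.rkf45 <- list(
  c = c(0, 1 / 4, 3 / 8, 12 / 13, 1),
  a = list(NULL,
           c(1 / 4),
           c(3 / 32, 9 / 32),
           c(1932 / 2197, -7200 / 2197, 7296 / 2197),
           c(439 / 216, -8, 3680 / 513, -845 / 4104)),
  b = c(25 / 216, 0, 1408 / 2565, 2197 / 4104, -1 / 5))

## Batched fixed-step RKF45 with optional exact forward sensitivities.
## Y0: n x d initial states; Tmat: n x L times (strictly increasing per row).
## Differentiating the explicit scheme w.r.t. theta is identical to applying
## the same scheme to the variational equations dS/dt = J_y S + J_theta, so
## the sensitivities returned are the exact gradients of the discrete states.
rkf45_batch <- function(field, theta, Y0, Tmat, substeps = 10L,
                        sens = FALSE) {
  n <- nrow(Y0); d <- ncol(Y0); L <- ncol(Tmat)
  p <- if (sens) field$n_params else 0L
  states <- array(NA_real_, c(n, L, d))
  states[, 1L, ] <- Y0
  Y <- Y0
  S <- if (sens) lapply(seq_len(d), function(a) matrix(0, n, p))
  Souts <- if (sens) vector("list", L)
  if (sens) Souts[[1L]] <- lapply(S, identity)
  nstage <- length(.rkf45$b)
  for (l in seq_len(L - 1L)) {
    hobs <- (Tmat[, l + 1L] - Tmat[, l]) / substeps
    for (s in seq_len(substeps)) {
      t0 <- Tmat[, l] + (s - 1L) * hobs
      K <- vector("list", nstage)
      KS <- if (sens) vector("list", nstage)
      for (st in seq_len(nstage)) {
        Yst <- Y
        Sst <- if (sens) lapply(S, identity)
        if (st > 1L) {
          aa <- .rkf45$a[[st]]
          for (q in seq_along(aa)) {
            if (aa[q] == 0) next
            Yst <- Yst + (hobs * aa[q]) * K[[q]]
            if (sens) for (a in seq_len(d))
              Sst[[a]] <- Sst[[a]] + (hobs * aa[q]) * KS[[q]][[a]]
          }
        }
        ev <- field_eval(field, t0 + .rkf45$c[st] * hobs, Yst, theta,
                         jacobian = sens)
        K[[st]] <- ev$f
        if (sens) {
          KS[[st]] <- lapply(seq_len(d), function(a) {
            acc <- if (is.null(ev$jtheta)) matrix(0, n, p) else ev$jtheta[[a]]
            for (b in seq_len(d)) acc <- acc + ev$jx[[a]][, b] * Sst[[b]]
            acc
          })
        }
      }
      for (st in seq_len(nstage)) {
        bb <- .rkf45$b[st]
        if (bb == 0) next
        Y <- Y + (hobs * bb) * K[[st]]
        if (sens) for (a in seq_len(d))
          S[[a]] <- S[[a]] + (hobs * bb) * KS[[st]][[a]]
      }
    }
    if (any(!is.finite(Y))) {
      bad <- which(!is.finite(rowSums(Y)))[1L]
      stop(sprintf(
        "integration diverged near t = %.6g (window %d)",
        Tmat[bad, l + 1L], bad))
    }
    states[, l + 1L, ] <- Y
    if (sens) Souts[[l + 1L]] <- lapply(S, identity)
  }
  list(states = states, sens = if (sens) Souts)
}

#' Fixed-step Runge-Kutta-Fehlberg integration of an ODE field
#'
#' Integrates with the explicit fourth-order Runge-Kutta-Fehlberg scheme
#' (stages `k1..k5`; the fifth-order embedded estimate is not computed),
#' taking `substeps` equal fixed steps inside each inter-observation
#' interval.  Because every stage is an explicit function of the parameters,
#' exact gradients of the discrete solution are available by forward
#' sensitivity propagation through the same scheme (used internally for
#' training).
#'
#' @param field An `ode_field`.
#' @param theta Flat parameter vector (or `NULL` for parameter-free fields).
#' @param y0 Initial state vector.
#' @param grid Strictly increasing vector of output times.
#' @param substeps Fixed steps per grid interval (>= 1; default 10).
#' @return A list of class `pn_trajectory` with `times` and the
#'   `length(grid) x state_dim` matrix `states`.
#' @export
integrate_rkf45 <- function(field, theta = NULL, y0, grid, substeps = 10L) {
  stopifnot(inherits(field, "ode_field"), substeps >= 1L)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (length(y0) != field$state_dim)
    stop("y0 has length ", length(y0), ", expected ", field$state_dim)
  res <- rkf45_batch(field, theta, matrix(y0, 1L), matrix(grid, 1L),
                     substeps = as.integer(substeps))
  states <- matrix(res$states[1L, , ], ncol = field$state_dim)
  structure(list(times = grid, states = states), class = "pn_trajectory")
}

#' @export
print.pn_trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d time points, %d states, t in [%g, %g]\n",
              length(x$times), ncol(x$states), min(x$times), max(x$times)))
  invisible(x)
}

#' @export
as.data.frame.pn_trajectory <- function(x, ...) {
  df <- data.frame(t = x$times)
  nm <- colnames(x$states)
  if (is.null(nm)) nm <- paste0("y", seq_len(ncol(x$states)))
  df[nm] <- as.data.frame(x$states)
  df
}

#' Batch a time series into overlapping training windows
#'
#' Slices a (possibly replicated) series of `n` observations into all
#' `n - L + 1` overlapping windows of `L` consecutive points (stride 1); the
#' window count therefore equals `n - L + 1`.  Each window carries one
#' initial state -- the observation (replicate mean) at the window's first
#' time, or the smoother's predictive mean there -- together with the
#' observed targets of every replicate.
#'
#' @param series A data frame with a time column `t`, one column per state
#'   variable, and optionally a `replicate` column; all replicates must share
#'   the same time grid.
#' @param L Window length (2 <= L <= n).
#' @param y0_source `"observed"` or `"smoother"`.
#' @param smoother A [fit_gpr()] fit, required when
#'   `y0_source = "smoother"`.
#' @return An object of class `trajectory_batch` with elements `y0`
#'   (`N_t x d`), `times` (`N_t x L`), `targets`
#'   (`N_t x L x d x n_replicates`), and metadata.
#' @export
make_batches <- function(series, L, y0_source = c("observed", "smoother"),
                         smoother = NULL) {
  y0_source <- match.arg(y0_source)
  parts <- split_series(series)
  tgrid <- parts$times; Ys <- parts$states   # list over replicates, n x d
  n <- length(tgrid); d <- ncol(Ys[[1L]]); R <- length(Ys)
  L <- as.integer(L)
  if (L < 2L || L > n)
    stop("window length L = ", L, " must be in [2, ", n, "]")
  Nt <- n - L + 1L
  idx <- seq_len(Nt)
  times <- t(vapply(idx, function(i) tgrid[i:(i + L - 1L)], numeric(L)))
  targets <- array(NA_real_, c(Nt, L, d, R))
  for (r in seq_len(R)) for (l in seq_len(L))
    targets[, l, , r] <- Ys[[r]][idx + l - 1L, , drop = FALSE]
  y0 <- if (y0_source == "observed") {
    Ybar <- Reduce(`+`, Ys) / R
    unname(Ybar[idx, , drop = FALSE])
  } else {
    if (is.null(smoother)) stop("y0_source = 'smoother' needs a smoother")
    initial_conditions(smoother, tgrid[idx])
  }
  structure(list(y0 = y0, times = times, targets = targets,
                 n_windows = Nt, L = L, state_dim = d, n_replicates = R,
                 state_names = parts$state_names, y0_source = y0_source),
            class = "trajectory_batch")
}

#' @export
print.trajectory_batch <- function(x, ...) {
  cat(sprintf(
    "trajectory batch: %d windows of %d points, %d states, %d replicate(s), y0 from %s\n",
    x$n_windows, x$L, x$state_dim, x$n_replicates, x$y0_source))
  invisible(x)
}

## Split a trajectory data frame into a shared time grid and per-replicate
## state matrices; validates monotone times and a common grid.
split_series <- function(series) {
  series <- as.data.frame(series)
  if (!"t" %in% names(series)) stop("series must have a 't' column")
  state_names <- setdiff(names(series), c("t", "replicate"))
  if (!length(state_names)) stop("series has no state columns")
  if (!"replicate" %in% names(series)) series$replicate <- 1L
  reps <- split(series, series$replicate)
  tgrid <- reps[[1L]]$t
  if (any(diff(tgrid) <= 0))
    stop("times must be strictly increasing within a replicate")
  states <- lapply(reps, function(df) {
    if (!isTRUE(all.equal(df$t, tgrid)))
      stop("all replicates must share the same time grid")
    as.matrix(df[state_names])
  })
  list(times = tgrid, states = states, state_names = state_names)
}
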