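#' Polynomial network (pi-net) configuration
#'
#' A pi-net is a neural network built exclusively from linear layers combined
#' by Hadamard (elementwise) products, so its output is an exact polynomial of
#' its input.  The wiring used here is
#' \deqn{z_1 = L_1(x), \qquad z_k = L_k(x) \circ z_{k-1} + z_{k-1}
#'       \ (k = 2, \ldots, degree),}
#' followed by a linear mixing layer \eqn{z_{mix} = M z_{degree} + b} and a
#' bias-free linear read-out.  Each Hadamard product raises the attainable
#' polynomial degree by one, so the network output has total degree at most
#' `degree`.  For `degree = 3`, one input, one output and hidden widths 10 the
#' network has exactly 180 scalar parameters.
#'
#' @param state_dim Number of input (state) variables.
#' @param output_dim Number of outputs (for an ODE field, equal to
#'   `state_dim`).
#' @param degree Maximum total polynomial degree (>= 1).
#' @param hidden_widths Integer vector of length `degree + 1`: widths of the
#'   product stages `z_1 .. z_degree` (which must all be equal, since Hadamard
#'   products and skip connections require conformable operands) followed by
#'   the width of the mixing layer.  A single number is recycled.
#' @param state_names Names used for input variables in expanded polynomials.
#'   Defaults to `x`, `y`, `z` for up to three states, `x1, x2, ...` beyond.
#'
#' @return An object of class `pinet_config`.
#' @seealso [pinet_init()], [pinet_forward()], [expand_to_polynomial()],
#'   [count_parameters()]
#' @export
pinet_config <- function(state_dim, output_dim, degree,
                         hidden_widths = 10L, state_names = NULL) {
  stopifnot(state_dim >= 1, output_dim >= 1, degree >= 1)
  hw <- as.integer(hidden_widths)
  if (length(hw) == 1L) hw <- rep(hw, degree + 1L)
  if (length(hw) != degree + 1L)
    stop("hidden_widths must have length degree + 1 (or length 1)")
  if (any(hw < 1L)) stop("hidden widths must be positive")
  if (degree >= 2L && length(unique(hw[seq_len(degree)])) != 1L)
    stop("product-stage widths must all be equal (Hadamard wiring)")
  if (is.null(state_names)) {
    state_names <- if (state_dim <= 3L) c("x", "y", "z")[seq_len(state_dim)]
                   else paste0("x", seq_len(state_dim))
  }
  stopifnot(length(state_names) == state_dim)
  structure(list(state_dim = as.integer(state_dim),
                 output_dim = as.integer(output_dim),
                 degree = as.integer(degree),
                 hidden_widths = hw,
                 state_names = state_names),
            class = "pinet_config")
}

#' @export
print.pinet_config <- function(x, ...) {
  cat(sprintf("pi-net: %d -> [%s] -> %d, degree %d, %d parameters\n",
              x$state_dim, paste(x$hidden_widths, collapse = "x"),
              x$output_dim, x$degree, count_parameters(x)))
  invisible(x)
}

#' Number of scalar parameters of a pi-net
#'
#' Counts all weight-matrix and bias entries across the network's linear
#' layers: `degree` input layers of shape `h x state_dim` with bias, the
#' `h2 x h` mixing layer with bias, and the bias-free `output_dim x h2`
#' read-out.
#'
#' @param config A [pinet_config()].
#' @return Integer parameter count.
#' @export
count_parameters <- function(config) {
  d <- config$state_dim; m <- config$output_dim
  h <- config$hidden_widths[1L]; h2 <- config$hidden_widths[config$degree + 1L]
  as.integer(config$degree * (d + 1L) * h + h2 * (h + 1L) + m * h2)
}

## Parameter container: list(A = list of h x d, a = list of h-vectors,
## M = h2 x h, mb = h2-vector, W = m x h2).  Flat layout (column-major):
## A1, a1, ..., AD, aD, M, mb, W.

pinet_check_params <- function(params, config) {
  d <- config$state_dim; m <- config$output_dim
  h <- config$hidden_widths[1L]; h2 <- config$hidden_widths[config$degree + 1L]
  ok <- length(params$A) == config$degree &&
    all(vapply(params$A, function(A) all(dim(A) == c(h, d)), logical(1))) &&
    all(vapply(params$a, length, integer(1)) == h) &&
    all(dim(params$M) == c(h2, h)) && length(params$mb) == h2 &&
    all(dim(params$W) == c(m, h2))
  if (!ok) stop("pi-net parameters do not match the configuration")
  if (!all(is.finite(unlist(params[c("A", "a", "M", "mb", "W")]))))
    stop("pi-net parameters contain non-finite values")
  invisible(TRUE)
}

#' Flatten pi-net parameters to a vector
#'
#' The layout is, in order: for each product stage `k = 1..degree` the weight
#' matrix `A_k` (column-major) then its bias; then the mixing weight matrix
#' (column-major) and bias; then the read-out matrix (column-major).
#'
#' @param params Parameter list as returned by [pinet_init()].
#' @param config The matching [pinet_config()].
#' @return Numeric vector of length [count_parameters()].
#' @export
pinet_pack <- function(params, config) {
  pinet_check_params(params, config)
  unlist(c(mapply(function(A, a) c(as.numeric(A), a), params$A, params$a,
                  SIMPLIFY = FALSE),
           list(c(as.numeric(params$M), params$mb, as.numeric(params$W)))),
         use.names = FALSE)
}

#' Rebuild the pi-net parameter list from a flat vector
#'
#' Inverse of [pinet_pack()].
#'
#' @param theta Flat parameter vector.
#' @param config A [pinet_config()].
#' @return Parameter list.
#' @export
pinet_unpack <- function(theta, config) {
  d <- config$state_dim; m <- config$output_dim
  h <- config$hidden_widths[1L]; h2 <- config$hidden_widths[config$degree + 1L]
  if (length(theta) != count_parameters(config))
    stop("theta has length ", length(theta), ", expected ",
         count_parameters(config))
  pos <- 0L
  take <- function(n) {
    out <- theta[pos + seq_len(n)]; pos <<- pos + n; out
  }
  A <- vector("list", config$degree); a <- vector("list", config$degree)
  for (k in seq_len(config$degree)) {
    A[[k]] <- matrix(take(h * d), h, d)
    a[[k]] <- take(h)
  }
  M <- matrix(take(h2 * h), h2, h)
  mb <- take(h2)
  W <- matrix(take(m * h2), m, h2)
  list(A = A, a = a, M = M, mb = mb, W = W)
}

## Core batched evaluation.  X: n x d matrix.  Returns y (n x m) and, when
## requested, per-output-dimension Jacobians with respect to the flat
## parameter vector (list of n x p matrices) and the state (list of n x d).
pinet_eval <- function(params, config, X, jacobian = "none") {
  d <- config$state_dim; m <- config$output_dim; D <- config$degree
  h <- config$hidden_widths[1L]; h2 <- config$hidden_widths[D + 1L]
  if (is.null(dim(X))) X <- matrix(X, ncol = d)
  stopifnot(ncol(X) == d)
  n <- nrow(X)
  U <- vector("list", D); Z <- vector("list", D)
  for (k in seq_len(D)) {
    U[[k]] <- X %*% t(params$A[[k]]) +
      matrix(params$a[[k]], n, h, byrow = TRUE)
    Z[[k]] <- if (k == 1L) U[[1L]] else U[[k]] * Z[[k - 1L]] + Z[[k - 1L]]
  }
  Zm <- Z[[D]] %*% t(params$M) + matrix(params$mb, n, h2, byrow = TRUE)
  y <- Zm %*% t(params$W)
  out <- list(y = y)
  if (jacobian == "none") return(out)

  p <- count_parameters(config)
  jtheta <- vector("list", m)
  jx <- vector("list", m)
  ## column offsets of the flat layout
  blkA <- (seq_len(D) - 1L) * (d + 1L) * h            # start of A_k block
  off_M <- D * (d + 1L) * h
  off_mb <- off_M + h2 * h
  off_W <- off_mb + h2
  iA <- rep(seq_len(h), d); jA <- rep(seq_len(d), each = h)
  iM <- rep(seq_len(h2), h); jM <- rep(seq_len(h), each = h2)
  for (j in seq_len(m)) {
    J <- matrix(0, n, p)
    Gm <- matrix(params$W[j, ], n, h2, byrow = TRUE)
    ## read-out block: column (b-1)*m + j holds Zm[, b]
    J[, off_W + (seq_len(h2) - 1L) * m + j] <- Zm
    ## mixing layer
    J[, off_M + seq_len(h2 * h)] <- Gm[, iM] * Z[[D]][, jM]
    J[, off_mb + seq_len(h2)] <- Gm
    G <- Gm %*% params$M                 # gradient w.r.t. Z[[D]]
    GX <- matrix(0, n, d)
    for (k in rev(seq_len(D))) {
      gradU <- if (k == 1L) G else G * Z[[k - 1L]]
      J[, blkA[k] + seq_len(h * d)] <- gradU[, iA] * X[, jA, drop = FALSE]
      J[, blkA[k] + h * d + seq_len(h)] <- gradU
      GX <- GX + gradU %*% params$A[[k]]
      if (k > 1L) G <- G * (U[[k]] + 1)
    }
    jtheta[[j]] <- J
    jx[[j]] <- GX
  }
  out$jtheta <- jtheta
  out$jx <- jx
  out
}

## Vector-Jacobian product: sum_{i,j} w[i, j] * d y_j(x_i) / d theta,
## returned as a flat vector in the pinet_pack() layout.  One reverse pass
## over summed adjoints; much cheaper than materializing per-sample
## Jacobians when only a loss gradient is needed.
pinet_vjp <- function(params, config, X, w) {
  d <- config$state_dim; m <- config$output_dim; D <- config$degree
  h <- config$hidden_widths[1L]; h2 <- config$hidden_widths[D + 1L]
  if (is.null(dim(X))) X <- matrix(X, ncol = d)
  n <- nrow(X)
  w <- matrix(w, n, m)
  U <- vector("list", D); Z <- vector("list", D)
  for (k in seq_len(D)) {
    U[[k]] <- X %*% t(params$A[[k]]) +
      matrix(params$a[[k]], n, h, byrow = TRUE)
    Z[[k]] <- if (k == 1L) U[[1L]] else U[[k]] * Z[[k - 1L]] + Z[[k - 1L]]
  }
  Zm <- Z[[D]] %*% t(params$M) + matrix(params$mb, n, h2, byrow = TRUE)
  gW <- crossprod(w, Zm)                       # m x h2
  G <- w %*% params$W                          # adjoint of Zm, n x h2
  gM <- crossprod(G, Z[[D]])                   # h2 x h
  gmb <- colSums(G)
  G <- G %*% params$M                          # adjoint of Z[[D]]
  gA <- vector("list", D); ga <- vector("list", D)
  for (k in rev(seq_len(D))) {
    gradU <- if (k == 1L) G else G * Z[[k - 1L]]
    gA[[k]] <- crossprod(gradU, X)
    ga[[k]] <- colSums(gradU)
    if (k > 1L) G <- G * (U[[k]] + 1)
  }
  unlist(c(mapply(function(A, a) c(as.numeric(A), a), gA, ga,
                  SIMPLIFY = FALSE),
           list(c(as.numeric(gM), gmb, as.numeric(gW)))),
         use.names = FALSE)
}

#' Evaluate a pi-net at a state vector
#'
#' Pure forward pass: no nonlinear activation is applied anywhere, so the
#' output is a polynomial of the input with total degree at most
#' `config$degree`.
#'
#' @param params Parameter list ([pinet_init()]) or flat vector
#'   ([pinet_pack()] layout).
#' @param config A [pinet_config()].
#' @param x State vector of length `state_dim`, or an `n x state_dim` matrix
#'   of states to evaluate in a batch.
#' @return Output vector of length `output_dim` (or an `n x output_dim`
#'   matrix for matrix input).
#' @export
pinet_forward <- function(params, config, x) {
  if (is.numeric(params) && is.null(dim(params)))
    params <- pinet_unpack(params, config)
  pinet_check_params(params, config)
  single <- is.null(dim(x))
  if (single && length(x) != config$state_dim)
    stop("x has length ", length(x), ", expected ", config$state_dim)
  y <- pinet_eval(params, config, x)$y
  if (single) drop(y) else y
}

## Run code with a private, restored RNG stream.
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Initialize pi-net parameters with tiny expanded coefficients
#'
#' Weights and biases are drawn from a small uniform distribution and the
#' read-out layer is rescaled by a single factor so that every nonzero
#' coefficient of the expanded polynomial has magnitude inside
#' `[coeff_lo, coeff_hi]`.  Because the expanded coefficients are exactly
#' linear in the read-out weights, the rescaling is exact; draws whose
#' coefficient dynamic range exceeds `coeff_hi / coeff_lo` are rejected and
#' redrawn.  Training therefore starts from a network that is numerically
#' close to the zero polynomial.
#'
#' @param config A [pinet_config()].
#' @param seed Integer seed; the result is deterministic given the seed.
#' @param coeff_lo,coeff_hi Magnitude band for the initial expanded
#'   coefficients (defaults 1e-10 and 1e-5).
#' @param attempts Maximum number of redraws before failing.
#' @return Parameter list with components `A`, `a` (product-stage weights and
#'   biases), `M`, `mb` (mixing layer) and `W` (read-out).
#' @export
pinet_init <- function(config, seed, coeff_lo = 1e-10, coeff_hi = 1e-5,
                       attempts = 100L) {
  stopifnot(coeff_lo < coeff_hi, coeff_lo > 0)
  d <- config$state_dim; m <- config$output_dim; D <- config$degree
  h <- config$hidden_widths[1L]; h2 <- config$hidden_widths[D + 1L]
  with_local_seed(seed, {
    for (try in seq_len(attempts)) {
      params <- list(
        A = lapply(seq_len(D), function(k) matrix(runif(h * d, -0.5, 0.5), h, d)),
        a = lapply(seq_len(D), function(k) runif(h, -0.5, 0.5)),
        M = matrix(runif(h2 * h, -0.5, 0.5), h2, h),
        mb = runif(h2, -0.5, 0.5),
        W = matrix(runif(m * h2, -0.5, 0.5), m, h2))
      cf <- abs(unlist(expand_to_polynomial(params, config)$coefficients))
      cf <- cf[cf > 0]
      if (!length(cf)) next
      if (max(cf) / min(cf) <= coeff_hi / coeff_lo) {
        ## geometric centering: place coefficients symmetrically in the band
        gamma <- sqrt(coeff_lo * coeff_hi / (max(cf) * min(cf)))
        params$W <- params$W * gamma
        return(params)
      }
    }
    stop("pi-net initialization failed: could not place expanded ",
         "coefficients in [", coeff_lo, ", ", coeff_hi, "] after ",
         attempts, " attempts")
  })
}
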