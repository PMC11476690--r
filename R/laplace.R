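#' Fisher information of a pi-net model at the MAP
#'
#' In the default `"gradient"` mode the Fisher information is assembled from
#' per-observation predicted-value Jacobians \eqn{J_i} as
#' \eqn{I_\theta = \sum_i J_i^T J_i / \beta^2 + I/\alpha^2}, i.e. the
#' model-expectation of the per-observation log-likelihood gradient outer
#' products (with the noise variance reinstated), plus the exact prior
#' precision.  For a linear-in-parameters model this reduces exactly to
#' \eqn{X^T X / \beta^2 + I/\alpha^2}, so the Laplace posterior coincides
#' with closed-form Bayesian linear regression.  `"hessian"` mode instead
#' differentiates the full log-joint gradient numerically (negated Hessian);
#' it is quadratic in the parameter count and intended as a cross-check on
#' small models.  `"diagonal"` keeps only the diagonal of the gradient-mode
#' matrix, a cheap fallback for large networks.
#'
#' @param theta_star MAP parameter vector ([train_map()]).
#' @param model The fitted [pn_regression()] / [pn_ode_model()].
#' @param beta2 Observation noise variance (> 0), normally the
#'   [train_map()] estimate.
#' @param prior A [prior_spec()].
#' @param mode `"gradient"` (default), `"hessian"`, or `"diagonal"`.
#' @return An object of class `fisher_matrix`: the `p x p` matrix `I_theta`
#'   plus the construction mode and a numerical rank estimate.
#' @export
fisher_information <- function(theta_star, model, beta2,
                               prior = prior_spec(),
                               mode = c("gradient", "hessian", "diagonal")) {
  mode <- match.arg(mode)
  if (beta2 <= 0) stop("beta2 must be positive")
  p <- length(theta_star)
  if (mode %in% c("gradient", "diagonal")) {
    rj <- model_residuals(model, theta_star, jacobian = TRUE)
    if (any(!is.finite(rj$J)))
      stop("non-finite gradient at observation ",
           which(!is.finite(rowSums(rj$J)))[1L])
    I <- crossprod(rj$J) / beta2 + diag(1 / prior$alpha^2, p)
    if (mode == "diagonal") I <- diag(diag(I), p)
  } else {
    ## negated Hessian of the log-joint, by central differences of the
    ## analytic gradient
    grad_lj <- function(theta) {
      rj <- model_residuals(model, theta, jacobian = TRUE)
      -drop(crossprod(rj$J, rj$r)) / beta2 - theta / prior$alpha^2
    }
    eps <- 1e-5 * pmax(abs(theta_star), 1)
    I <- matrix(0, p, p)
    for (j in seq_len(p)) {
      tp <- theta_star; tp[j] <- tp[j] + eps[j]
      tm <- theta_star; tm[j] <- tm[j] - eps[j]
      I[, j] <- -(grad_lj(tp) - grad_lj(tm)) / (2 * eps[j])
    }
    I <- (I + t(I)) / 2
  }
  sv <- svd(I, nu = 0, nv = 0)$d
  rank <- sum(sv > max(sv) * 1e-10)
  structure(list(matrix = I, mode = mode, rank = rank),
            class = "fisher_matrix")
}

#' @export
print.fisher_matrix <- function(x, ...) {
  cat(sprintf("Fisher information (%s mode): %d x %d, numerical rank %d\n",
              x$mode, nrow(x$matrix), ncol(x$matrix), x$rank))
  invisible(x)
}

#' Curvature-based sampling metric from a Fisher information matrix
#'
#' Builds a dense preconditioning covariance for the samplers by
#' eigendecomposing the Fisher information and inverting its spectrum with
#' a cap: directions the data constrain strongly get their (small) Laplace
#' variance, while nearly-flat prior directions -- whose curvature-implied
#' scale lies far outside the locally-quadratic region -- are capped at
#' `cap`.  Used as the `init_inv_mass` of [sample_nuts()].
#'
#' @param fisher A [fisher_information()] result (or bare symmetric
#'   matrix).
#' @param cap Upper bound on the per-direction variance (default 1).
#' @return A symmetric positive-definite matrix.
#' @export
fisher_metric <- function(fisher, cap = 1) {
  I <- if (inherits(fisher, "fisher_matrix")) fisher$matrix else fisher
  e <- eigen((I + t(I)) / 2, symmetric = TRUE)
  lam <- pmin(1 / pmax(e$values, 1e-12), cap)
  S <- e$vectors %*% (lam * t(e$vectors))
  (S + t(S)) / 2
}

#' Moore-Penrose pseudoinverse of a symmetric PSD matrix
#'
#' Singular values below `rcond` times the largest are truncated.  Used for
#' the (often singular) Fisher information of overparameterized networks.
#'
#' @param A Symmetric matrix.
#' @param rcond Relative truncation threshold (default `1e-10`).
#' @return The pseudoinverse, symmetrized.
#' @export
pseudo_inverse <- function(A, rcond = 1e-10) {
  s <- svd(A)
  keep <- s$d > rcond * max(s$d)
  if (!any(keep)) return(matrix(0, nrow(A), ncol(A)))
  P <- s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
  (P + t(P)) / 2
}

#' Laplace approximation of the parameter posterior
#'
#' The Gaussian posterior \eqn{\theta \sim N(\theta^*, I_\theta^{-1})}
#' centred at the MAP, with the covariance computed as the Moore-Penrose
#' pseudoinverse of the Fisher information (singular values below
#' `rcond * sigma_max` truncated).
#'
#' @param theta_star MAP estimate (posterior mean).
#' @param fisher A [fisher_information()] result (or a bare matrix).
#' @param rcond Pseudoinverse truncation threshold.
#' @param max_params Refuse pseudoinversion beyond this parameter count
#'   (default 50000, past which the dense SVD becomes impractical).
#' @return An object of class `gaussian_posterior` with `mean`,
#'   `covariance`, and `diagonal = FALSE`.
#' @export
laplace_posterior <- function(theta_star, fisher, rcond = 1e-10,
                              max_params = 50000L) {
  I <- if (inherits(fisher, "fisher_matrix")) fisher$matrix else fisher
  p <- length(theta_star)
  stopifnot(nrow(I) == p, ncol(I) == p)
  if (p > max_params)
    stop("pseudoinverse of a ", p, "-parameter Fisher matrix exceeds the ",
         "configured ceiling (", max_params, ")")
  if (max(abs(I - t(I))) > 1e-8 * max(abs(I), 1))
    stop("Fisher matrix is not symmetric")
  gaussian_posterior(theta_star, pseudo_inverse(I, rcond = rcond))
}

#' Construct a Gaussian parameter posterior
#'
#' @param mean Mean vector.
#' @param covariance Symmetric PSD covariance matrix, or a vector of
#'   per-parameter variances for diagonal (mean-field) posteriors.
#' @return An object of class `gaussian_posterior`.
#' @export
gaussian_posterior <- function(mean, covariance) {
  diagonal <- is.null(dim(covariance))
  if (diagonal) {
    stopifnot(length(covariance) == length(mean), all(covariance >= 0))
  } else {
    stopifnot(nrow(covariance) == length(mean),
              ncol(covariance) == length(mean))
    if (max(abs(covariance - t(covariance))) > 1e-8)
      stop("covariance is not symmetric")
  }
  structure(list(mean = mean, covariance = covariance, diagonal = diagonal),
            class = "gaussian_posterior")
}

#' @export
print.gaussian_posterior <- function(x, ...) {
  cat(sprintf("Gaussian posterior over %d parameters (%s covariance)\n",
              length(x$mean), if (x$diagonal) "diagonal" else "full"))
  invisible(x)
}

## draw n samples from a gaussian_posterior (PSD covariance, possibly
## singular: eigendecomposition with negative eigenvalues clamped to zero)
posterior_draws <- function(post, n) {
  p <- length(post$mean)
  if (post$diagonal) {
    Z <- matrix(rnorm(n * p), n, p)
    return(sweep(Z, 2L, sqrt(post$covariance), `*`) +
             matrix(post$mean, n, p, byrow = TRUE))
  }
  e <- eigen(post$covariance, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  Lhalf <- e$vectors %*% diag(sqrt(lam), p)
  Z <- matrix(rnorm(n * p), n, p)
  Z %*% t(Lhalf) + matrix(post$mean, n, p, byrow = TRUE)
}

#' Write a Gaussian posterior to plain-text files
#'
#' Writes `<stem>_mean.csv`, `<stem>_cov.csv` and a JSON sidecar
#' `<stem>.json` describing the parameter layout (see [pinet_pack()]).
#'
#' @param post A `gaussian_posterior`.
#' @param stem Output path stem.
#' @param config Optional [pinet_config()] recorded in the sidecar.
#' @return Invisibly, the paths written.
#' @export
posterior_write <- function(post, stem, config = NULL) {
  mean_path <- paste0(stem, "_mean.csv")
  cov_path <- paste0(stem, "_cov.csv")
  utils::write.csv(data.frame(mean = post$mean), mean_path,
                   row.names = FALSE)
  covm <- if (post$diagonal) diag(post$covariance,
                                  length(post$mean)) else post$covariance
  utils::write.table(covm, cov_path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  side <- list(n_params = length(post$mean), diagonal = post$diagonal,
               layout = "A1,a1,...,AD,aD,M,mb,W (column-major)")
  if (!is.null(config))
    side$config <- list(state_dim = config$state_dim,
                        output_dim = config$output_dim,
                        degree = config$degree,
                        hidden_widths = config$hidden_widths)
  writeLines(jsonlite::toJSON(side, auto_unbox = TRUE),
             paste0(stem, ".json"))
  invisible(c(mean_path, cov_path, paste0(stem, ".json")))
}
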