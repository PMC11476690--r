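## Monomial basis utilities.  A basis for state dimension d and maximum total
## degree D is the set of exponent vectors alpha (length d, nonnegative
## integers) with sum(alpha) <= D, ordered by total degree and then
## lexicographically on the exponent vector (first variable varies slowest,
## higher exponents first).  So for two variables and degree 2:
## 1, x, y, x^2, x*y, y^2.

monomial_basis <- function(state_dim, degree) {
  grid <- as.matrix(expand.grid(rep(list(0:degree), state_dim),
                                KEEP.OUT.ATTRS = FALSE))
  grid <- grid[rowSums(grid) <= degree, , drop = FALSE]
  ## order: total degree, then lexicographic with var 1 most significant,
  ## larger exponents first within a degree (x^2 before x*y)
  key <- do.call(order, c(list(rowSums(grid)),
                          lapply(seq_len(state_dim), function(j) -grid[, j])))
  exps <- grid[key, , drop = FALSE]
  dimnames(exps) <- NULL
  exps
}

monomial_labels <- function(exps, vars) {
  apply(exps, 1L, function(a) {
    if (all(a == 0)) return("1")
    parts <- vapply(seq_along(a), function(j) {
      if (a[j] == 0) "" else if (a[j] == 1) vars[j]
      else paste0(vars[j], "^", a[j])
    }, character(1))
    paste(parts[parts != ""], collapse = "*")
  })
}

## index lookup and pairwise product table for a basis
monomial_table <- function(exps) {
  keys <- apply(exps, 1L, paste, collapse = ",")
  idx <- seq_along(keys); names(idx) <- keys
  M <- nrow(exps)
  prod_idx <- matrix(NA_integer_, M, M)
  for (i in seq_len(M)) for (j in seq_len(M)) {
    s <- exps[i, ] + exps[j, ]
    k <- idx[paste(s, collapse = ",")]
    if (!is.na(k)) prod_idx[i, j] <- k
  }
  prod_idx
}

## Hadamard product of two vectors of polynomials, each stored as a
## width x n_monomials coefficient matrix over the same basis.
poly_hadamard <- function(C1, C2, prod_idx) {
  out <- matrix(0, nrow(C1), ncol(C1))
  for (i in seq_len(ncol(C1))) {
    ci <- C1[, i]
    if (all(ci == 0)) next
    for (j in seq_len(ncol(C2))) {
      cj <- C2[, j]
      if (all(cj == 0)) next
      k <- prod_idx[i, j]
      if (is.na(k)) stop("monomial product exceeds the basis degree")
      out[, k] <- out[, k] + ci * cj
    }
  }
  out
}

## precomputed basis bundle for repeated expansions of one architecture
pn_basis <- function(config) {
  exps <- monomial_basis(config$state_dim, config$degree)
  d <- config$state_dim
  lin_cols <- vapply(seq_len(d), function(j) {
    which(rowSums(exps) == 1 & exps[, j] == 1)
  }, integer(1))
  list(exps = exps,
       prod_idx = monomial_table(exps),
       const_col = which(rowSums(exps) == 0),
       lin_cols = lin_cols,
       labels = monomial_labels(exps, config$state_names))
}

## bare coefficient matrix (output_dim x n_monomials) for given params
expand_core <- function(params, config, basis) {
  d <- config$state_dim; M <- nrow(basis$exps)
  Cx <- matrix(0, d, M)
  Cx[cbind(seq_len(d), basis$lin_cols)] <- 1
  lin_layer <- function(Wmat, bias, C) {
    out <- Wmat %*% C
    out[, basis$const_col] <- out[, basis$const_col] + bias
    out
  }
  Cz <- NULL
  for (k in seq_len(config$degree)) {
    Cu <- lin_layer(params$A[[k]], params$a[[k]], Cx)
    Cz <- if (k == 1L) Cu else poly_hadamard(Cu, Cz, basis$prod_idx) + Cz
  }
  params$W %*% lin_layer(params$M, params$mb, Cz)
}

#' Expand a pi-net into its polynomial coefficients
#'
#' Performs exact polynomial arithmetic on coefficient vectors (no string
#' manipulation) to multiply out the network's factorized form, combining
#' like terms, so that evaluating the returned polynomial reproduces
#' [pinet_forward()] exactly up to floating-point roundoff.  Coefficients are
#' not pruned, however small.
#'
#' @param params Parameter list or flat parameter vector.
#' @param config A [pinet_config()].
#' @return An object of class `polyform`: a list with `coefficients` (an
#'   `output_dim x n_monomials` matrix, columns labelled by monomial),
#'   `exponents` (the `n_monomials x state_dim` exponent matrix), `vars`,
#'   and `degree`.
#' @export
expand_to_polynomial <- function(params, config) {
  if (is.numeric(params) && is.null(dim(params)))
    params <- pinet_unpack(params, config)
  pinet_check_params(params, config)
  basis <- pn_basis(config)
  Cout <- expand_core(params, config, basis)
  dimnames(Cout) <- list(paste0("f", seq_len(config$output_dim)),
                         basis$labels)
  structure(list(coefficients = Cout, exponents = basis$exps,
                 vars = config$state_names, degree = config$degree),
            class = "polyform")
}

#' Evaluate a polyform at states
#'
#' @param object A `polyform` from [expand_to_polynomial()].
#' @param newdata State vector or `n x state_dim` matrix.
#' @param ... Unused.
#' @return Output vector / matrix matching [pinet_forward()].
#' @export
predict.polyform <- function(object, newdata, ...) {
  X <- if (is.null(dim(newdata))) matrix(newdata, ncol = length(object$vars))
       else as.matrix(newdata)
  B <- design_matrix(X, object$exponents)
  out <- B %*% t(object$coefficients)
  if (is.null(dim(newdata))) unname(drop(out)) else out
}

## monomial design matrix: n x n_monomials
design_matrix <- function(X, exps) {
  n <- nrow(X)
  B <- matrix(1, n, nrow(exps))
  for (k in seq_len(nrow(exps))) {
    for (j in seq_len(ncol(exps))) {
      e <- exps[k, j]
      if (e > 0) B[, k] <- B[, k] * X[, j]^e
    }
  }
  B
}

#' @export
print.polyform <- function(x, digits = 4, tol = 0, ...) {
  labels <- colnames(x$coefficients)
  m <- nrow(x$coefficients)
  for (i in seq_len(m)) {
    co <- x$coefficients[i, ]
    keep <- which(abs(co) > tol)
    if (!length(keep)) {
      cat(rownames(x$coefficients)[i], "= 0\n")
      next
    }
    terms <- vapply(keep, function(k) {
      val <- formatC(co[k], digits = digits, format = "g")
      if (labels[k] == "1") val else paste0(val, "*", labels[k])
    }, character(1))
    cat(rownames(x$coefficients)[i], "=", paste(terms, collapse = " + "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.polyform <- function(x, ...) {
  data.frame(output = rep(rownames(x$coefficients),
                          each = ncol(x$coefficients)),
             monomial = rep(colnames(x$coefficients),
                            times = nrow(x$coefficients)),
             coefficient = as.vector(t(x$coefficients)),
             stringsAsFactors = FALSE)
}

#' Serialize a polyform to JSON
#'
#' Writes `{output_name: {monomial: coefficient}}` with monomials ordered by
#' total degree, then lexicographically (first variable most significant).
#'
#' @param x A `polyform`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
polyform_to_json <- function(x, path = NULL) {
  obj <- lapply(seq_len(nrow(x$coefficients)), function(i)
    as.list(stats::setNames(x$coefficients[i, ], colnames(x$coefficients))))
  names(obj) <- rownames(x$coefficients)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
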