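#' Assemble a generalized partly linear model dataset
#'
#' Bundles the response with the three covariate blocks: a high-dimensional
#' numeric block `X` (penalized, subject to selection), a low-dimensional
#' categorical/indicator block `W` (unpenalized), and a low-dimensional
#' continuous block `Z` whose effects enter through the Bernstein sieve.
#' Either `W` or `Z` (or both) may be absent.
#'
#' `X` columns are standardized internally at fit time with the n-denominator
#' convention (`mean 0`, `sum x^2 / n = 1`), so that the penalty acts on a
#' common scale; this constructor only validates shapes and the response.
#'
#' @param y response: 0/1 for `family = "logistic"`, nonnegative integers for
#'   `family = "poisson"`.
#' @param X numeric matrix `n x p` (may have `p = 0`).
#' @param W optional numeric matrix `n x qw` of indicator covariates.
#' @param Z optional numeric matrix `n x qz` of continuous covariates.
#' @param family `"logistic"` or `"poisson"`.
#' @return object of class `gplm_data`.
#' @export
gplm_data <- function(y, X, W = NULL, Z = NULL,
                      family = c("logistic", "poisson")) {
  family <- match.arg(family)
  y <- as.numeric(y)
  n <- length(y)
  X <- as_block(X, n, "X")
  W <- if (is.null(W)) matrix(numeric(0), n, 0) else as_block(W, n, "W")
  Z <- if (is.null(Z)) matrix(numeric(0), n, 0) else as_block(Z, n, "Z")
  if (anyNA(y)) stop("missing values in the response", call. = FALSE)
  if (family == "logistic" && !all(y %in% c(0, 1))) {
    stop("family mismatch: logistic family requires a 0/1 response",
         call. = FALSE)
  }
  if (family == "poisson" && (any(y < 0) || any(y != round(y)))) {
    stop("family mismatch: poisson family requires nonnegative integer counts",
         call. = FALSE)
  }
  if (is.null(colnames(X)) && ncol(X))  colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(colnames(W)) && ncol(W))  colnames(W) <- paste0("w", seq_len(ncol(W)))
  if (is.null(colnames(Z)) && ncol(Z))  colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  structure(list(y = y, X = X, W = W, Z = Z, family = family, n = n),
            class = "gplm_data")
}

as_block <- function(M, n, what) {
  M <- as.matrix(M)
  if (!is.numeric(M)) stop(sprintf("block %s must be numeric", what),
                           call. = FALSE)
  if (nrow(M) != n) {
    stop(sprintf("block %s has %d rows but the response has %d",
                 what, nrow(M), n), call. = FALSE)
  }
  if (anyNA(M)) stop(sprintf("missing values in block %s", what),
                     call. = FALSE)
  M
}

#' @export
print.gplm_data <- function(x, ...) {
  cat(sprintf("gplm_data: n = %d, family = %s | p = %d (X), qw = %d (W), qz = %d (Z)\n",
              x$n, x$family, ncol(x$X), ncol(x$W), ncol(x$Z)))
  invisible(x)
}

#' Partitioned GPLM coefficient vector
#'
#' @param beta penalized block coefficients (length p).
#' @param alpha unpenalized indicator-block coefficients (length qw).
#' @param gamma sieve coefficients (length `sum_j (m_j + 1)`).
#' @param intercept scalar free intercept.
#' @return object of class `gplm_coef`.
#' @export
gplm_coef <- function(beta, alpha = numeric(0), gamma = numeric(0),
                      intercept = 0) {
  structure(list(beta = as.numeric(beta), alpha = as.numeric(alpha),
                 gamma = as.numeric(gamma),
                 intercept = as.numeric(intercept)[1L]),
            class = "gplm_coef")
}

#' @export
print.gplm_coef <- function(x, ...) {
  cat(sprintf("gplm_coef: intercept %.4g | %d beta (%d nonzero) | %d alpha | %d gamma\n",
              x$intercept, length(x$beta), sum(x$beta != 0), length(x$alpha),
              length(x$gamma)))
  invisible(x)
}

# linear predictor eta_i for given (possibly standardized) design blocks
gplm_eta <- function(coef, X, W, B) {
  eta <- rep(coef$intercept, nrow(X))
  if (length(coef$beta))  eta <- eta + drop(X %*% coef$beta)
  if (length(coef$alpha)) eta <- eta + drop(W %*% coef$alpha)
  if (length(coef$gamma)) eta <- eta + drop(B %*% coef$gamma)
  eta
}

# internal standardization of the X block: mean 0, sum(x^2)/n = 1
standardize_x <- function(X) {
  n <- nrow(X)
  if (!ncol(X)) {
    return(list(X = X, center = numeric(0), scale = numeric(0)))
  }
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr, "-")
  scl <- sqrt(colSums(Xc^2) / n)
  if (any(scl <= .Machine$double.eps^0.5)) {
    bad <- which(scl <= .Machine$double.eps^0.5)[1L]
    stop(sprintf("constant X column '%s' (zero variance): remove it before fitting",
                 colnames(X)[bad]), call. = FALSE)
  }
  list(X = sweep(Xc, 2L, scl, "/"), center = ctr, scale = scl)
}
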