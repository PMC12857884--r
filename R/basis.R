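#' Bernstein basis polynomials on an interval
#'
#' Evaluates the degree-`m` Bernstein basis at `z` on `[c, u]`:
#' \deqn{B_k(z, m, c, u) = \binom{m}{k} t^k (1-t)^{m-k}, \quad
#'       t = (z - c)/(u - c), \quad k = 0, \dots, m.}
#' The basis is nonnegative and forms a partition of unity, which makes it a
#' knot-free sieve for bounded continuous functions.
#'
#' Values of `z` outside `[c, u]` are clamped to the nearest endpoint (with a
#' warning), so prediction beyond the observed training range degrades to the
#' boundary value rather than extrapolating a polynomial.
#'
#' @param z numeric vector of evaluation points.
#' @param m polynomial degree (integer, at least 1); the basis has `m + 1`
#'   functions.
#' @param c,u interval endpoints, `c < u`.
#' @param warn_clamp warn when values are clamped to the interval.
#' @return a `length(z) x (m + 1)` matrix; rows sum to 1.
#' @examples
#' bernstein_basis(0.5, 3, 0, 1)   # 1/8 3/8 3/8 1/8
#' @export
bernstein_basis <- function(z, m, c, u, warn_clamp = TRUE) {
  if (!is.numeric(c) || !is.numeric(u) || length(c) != 1L || length(u) != 1L ||
      !(c < u)) {
    stop("invalid range: 'c' must be strictly less than 'u'", call. = FALSE)
  }
  if (length(m) != 1L || m < 1 || m != round(m)) {
    stop("invalid degree: 'm' must be a positive integer", call. = FALSE)
  }
  m <- as.integer(m)
  if (any(z < c | z > u)) {
    if (warn_clamp) {
      warning(sprintf("%d value(s) outside [%g, %g] clamped to the boundary",
                      sum(z < c | z > u), c, u), call. = FALSE)
    }
    z <- pmin(pmax(z, c), u)
  }
  t <- (z - c) / (u - c)
  k <- 0:m
  # dbinom(k, m, t) is exactly choose(m, k) t^k (1-t)^(m-k), computed stably
  B <- outer(t, k, function(tt, kk) dbinom(kk, m, tt))
  dimnames(B) <- NULL
  B
}

#' Sieve basis specification for the nonparametric additive block
#'
#' Records, for each continuous covariate, the Bernstein degree and the
#' interval over which its smooth effect is represented.  The default degree
#' is 3 (four basis functions), which trades approximation quality against
#' parameter count well for smooth index functions; ranges default to the
#' observed column minima and maxima.
#'
#' Identifiability: each expanded block can be centered at the interval
#' midpoint `Mid_j = (c_j + u_j) / 2`, which forces \eqn{\psi_j(Mid_j) = 0}
#' for every coefficient vector; the level lost this way is carried by a free
#' unpenalized global intercept.
#'
#' @param Z numeric matrix (or data.frame) of continuous covariates, or NULL
#'   when ranges are supplied explicitly.
#' @param degree integer degree(s), recycled across columns.
#' @param lower,upper optional numeric vectors of interval endpoints per
#'   column; default to observed ranges of `Z`.
#' @param center logical; center each block at its midpoint (default TRUE).
#' @return an object of class `sieve_spec`.
#' @export
sieve_basis_spec <- function(Z = NULL, degree = 3L, lower = NULL, upper = NULL,
                             center = TRUE) {
  if (is.null(Z)) {
    if (is.null(lower) || is.null(upper)) {
      stop("either 'Z' or both 'lower' and 'upper' must be given",
           call. = FALSE)
    }
    qz <- length(lower)
    nms <- names(lower)
  } else {
    Z <- as.matrix(Z)
    qz <- ncol(Z)
    nms <- colnames(Z)
    if (is.null(lower)) lower <- apply(Z, 2L, min)
    if (is.null(upper)) upper <- apply(Z, 2L, max)
  }
  if (is.null(nms)) nms <- paste0("z", seq_len(qz))
  degree <- as.integer(rep_len(degree, qz))
  if (any(degree < 1L)) stop("invalid degree: 'degree' must be >= 1",
                             call. = FALSE)
  if (any(!(lower < upper))) {
    bad <- which(!(lower < upper))[1L]
    stop(sprintf("invalid range for continuous covariate '%s': lower %g >= upper %g (constant column?)",
                 nms[bad], lower[bad], upper[bad]), call. = FALSE)
  }
  structure(
    list(degree = degree, lower = as.numeric(lower), upper = as.numeric(upper),
         midpoint = (as.numeric(lower) + as.numeric(upper)) / 2,
         center = isTRUE(center), names = nms),
    class = "sieve_spec")
}

#' @export
print.sieve_spec <- function(x, ...) {
  cat("Bernstein sieve spec:", length(x$degree), "covariate(s),",
      if (x$center) "centered" else "uncentered", "\n")
  for (j in seq_along(x$degree)) {
    cat(sprintf("  %s: degree %d on [%g, %g], midpoint %g\n", x$names[j],
                x$degree[j], x$lower[j], x$upper[j], x$midpoint[j]))
  }
  invisible(x)
}

#' Expand continuous covariates into a (centered) Bernstein sieve design
#'
#' Builds the `n x sum_j (m_j + 1)` design whose block `j` holds the Bernstein
#' basis of covariate `j`.  When the spec requests centering, the basis row at
#' the interval midpoint is subtracted from each block, so that any
#' coefficient vector yields a smooth estimate vanishing at the midpoint.
#'
#' @param Z numeric matrix of continuous covariates (columns match `spec`).
#' @param spec a [sieve_basis_spec()]; defaults to degree-3 centered blocks on
#'   the observed ranges.
#' @param warn_clamp warn about out-of-range values (clamped).
#' @return an object of class `sieve_design`: list with `B` (expanded matrix),
#'   `spec`, `block` (column index list per covariate) and `mid_row` (the
#'   uncentered basis evaluated at each midpoint).
#' @export
build_sieve_design <- function(Z, spec = NULL, warn_clamp = TRUE) {
  Z <- as.matrix(Z)
  if (is.null(spec)) spec <- sieve_basis_spec(Z)
  qz <- length(spec$degree)
  if (ncol(Z) != qz) {
    stop(sprintf("Z has %d columns but the sieve spec describes %d",
                 ncol(Z), qz), call. = FALSE)
  }
  blocks <- vector("list", qz)
  mids <- vector("list", qz)
  for (j in seq_len(qz)) {
    Bj <- bernstein_basis(Z[, j], spec$degree[j], spec$lower[j],
                          spec$upper[j], warn_clamp = warn_clamp)
    mid <- bernstein_basis(spec$midpoint[j], spec$degree[j], spec$lower[j],
                           spec$upper[j], warn_clamp = FALSE)
    if (spec$center) Bj <- sweep(Bj, 2L, as.numeric(mid), "-")
    colnames(Bj) <- paste0(spec$names[j], ".B", 0:spec$degree[j])
    blocks[[j]] <- Bj
    mids[[j]] <- as.numeric(mid)
  }
  sizes <- spec$degree + 1L
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  structure(
    list(B = do.call(cbind, blocks), spec = spec,
         block = lapply(seq_len(qz), function(j) starts[j]:ends[j]),
         mid_row = mids),
    class = "sieve_design")
}

#' Evaluate a fitted smooth on a grid
#'
#' Applies one covariate's sieve coefficient block to a grid of covariate
#' values, reproducing the estimate \eqn{\hat\psi_j}.  Under a centered spec
#' the returned curve is exactly zero at the interval midpoint.
#'
#' @param gamma_block numeric vector of length `m_j + 1`.
#' @param grid numeric vector of evaluation points (clamped to the interval).
#' @param spec a [sieve_basis_spec()].
#' @param j which covariate block of `spec` to use.
#' @return numeric vector of `psi_hat` values on `grid`.
#' @export
evaluate_psi <- function(gamma_block, grid, spec, j = 1L) {
  stopifnot(inherits(spec, "sieve_spec"))
  if (length(gamma_block) != spec$degree[j] + 1L) {
    stop(sprintf("gamma block has length %d but covariate %d needs %d",
                 length(gamma_block), j, spec$degree[j] + 1L), call. = FALSE)
  }
  B <- bernstein_basis(grid, spec$degree[j], spec$lower[j], spec$upper[j])
  if (spec$center) {
    mid <- bernstein_basis(spec$midpoint[j], spec$degree[j], spec$lower[j],
                           spec$upper[j], warn_clamp = FALSE)
    B <- sweep(B, 2L, as.numeric(mid), "-")
  }
  as.numeric(B %*% gamma_block)
}
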