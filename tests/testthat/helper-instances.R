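# Small random GPLM instances and black-box oracles used across tests.

# draw a small logistic partly linear instance
small_instance <- function(seed, n = 60, p = 4, qw = 2, qz = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  X <- standardize_cols(X)
  W <- if (qw) matrix(rbinom(n * qw, 1, 0.5), n, qw)
  Z <- if (qz) matrix(runif(n * qz, 1, 5), n, qz)
  eta <- drop(X %*% c(1, -1, rep(0, p - 2)))
  if (qw) eta <- eta + drop(W %*% rep(0.5, qw))
  if (qz) eta <- eta + 0.1 * (Z[, 1] - 3)^2 - 0.4
  y <- rbinom(n, 1, 1 / (1 + exp(-eta)))
  gplm_data(y, X, W, Z)
}

standardize_cols <- function(X) {
  n <- nrow(X)
  Xc <- sweep(X, 2L, colMeans(X), "-")
  sweep(Xc, 2L, sqrt(colSums(Xc^2) / n), "/")
}

# the exact objective every inner solve minimizes:
# -2 loglik + sum(w_pen beta^2) + eps * ||(alpha, gamma, intercept)||^2
make_objective <- function(data, design, w_pen, eps, active = NULL) {
  B <- if (is.null(design)) matrix(numeric(0), data$n, 0) else design$B
  U <- cbind(data$W, B, 1)
  p <- ncol(data$X)
  if (is.null(active)) active <- rep(TRUE, p)
  act <- which(active)
  function(theta) {
    beta <- numeric(p)
    beta[act] <- theta[seq_along(act)]
    u <- theta[-seq_along(act)]
    eta <- drop(data$X %*% beta + U %*% u)
    dev <- if (data$family == "logistic") {
      -2 * sum(data$y * eta - ifelse(eta > 0, eta + log1p(exp(-eta)),
                                     log1p(exp(eta))))
    } else {
      -2 * sum(data$y * eta - exp(eta))
    }
    dev + sum(w_pen[act] * beta[act]^2) + eps * sum(u^2)
  }
}

# generic numerical minimizer of the same objective (the independent oracle)
optim_oracle <- function(data, design, w_pen, eps, active = NULL,
                         start = NULL) {
  B <- if (is.null(design)) matrix(numeric(0), data$n, 0) else design$B
  p_free <- if (is.null(active)) ncol(data$X) else sum(active)
  d <- p_free + ncol(data$W) + ncol(B) + 1L
  f <- make_objective(data, design, w_pen, eps, active)
  th0 <- if (is.null(start)) numeric(d) else start
  o <- stats::optim(th0, f, method = "BFGS",
                    control = list(maxit = 5000, reltol = 1e-15))
  o$par
}

# dense-matrix oracle for the AR(1) quadratic form
ar1_quadform_ref <- function(d, rho) {
  p <- length(d)
  S <- rho^abs(outer(seq_len(p), seq_len(p), "-"))
  drop(t(d) %*% S %*% d)
}

flatten_coef <- function(co, active = NULL) {
  beta <- co$beta
  if (!is.null(active)) beta <- beta[active]
  c(beta, co$alpha, co$gamma, co$intercept)
}
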