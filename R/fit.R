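#' Control settings for the BAR estimator
#'
#' @param xi_n positive ridge tuning parameter for the initialization step.
#'   Provided the value is not large, downstream selection is insensitive to
#'   it; the default is 1.
#' @param lambda_rule tuning rule for the BAR penalty `lambda_n`: `"aic"`
#'   (`lambda_n = 2`), `"bic"` (`log n`), `"hbic"` (`log(log n) * log p`),
#'   or `"fixed"` (use `lambda_value`).
#' @param lambda_value numeric penalty used when `lambda_rule = "fixed"`.
#' @param eps_out outer convergence tolerance on the maximum absolute change
#'   in `beta` between BAR iterations.
#' @param max_outer cap on BAR iterations.
#' @param delta_drop coordinates with `|beta| < delta_drop` are set to exact
#'   zero and permanently removed from the active set (their ridge weight
#'   would diverge).
#' @param inner_tol,max_inner tolerance and iteration cap for the inner
#'   penalized solver.
#' @param eps_stab tiny ridge on the unpenalized block guarding against
#'   separation-induced divergence in logistic fits; set `stab = FALSE` to
#'   disable.
#' @param stab logical, apply `eps_stab`.
#' @param p_switch active-set size above which the inner solver switches from
#'   a joint Newton solve to cyclic coordinate descent over the penalized
#'   block.
#' @param standardize standardize `X` internally (n-denominator convention);
#'   coefficients are reported on the standardized scale unless
#'   `unstandardize = TRUE`.
#' @param unstandardize report `beta` on the original `X` scale.
#' @return a list of class `bar_control`.
#' @export
bar_control <- function(xi_n = 1, lambda_rule = c("bic", "aic", "hbic", "fixed"),
                        lambda_value = NULL, eps_out = 1e-6, max_outer = 100L,
                        delta_drop = 1e-6, inner_tol = 1e-8, max_inner = 100L,
                        eps_stab = 1e-8, stab = TRUE, p_switch = 1000L,
                        standardize = TRUE, unstandardize = FALSE) {
  lambda_rule <- match.arg(lambda_rule)
  stopifnot(xi_n > 0, eps_out > 0, delta_drop > 0, inner_tol > 0)
  structure(list(xi_n = xi_n, lambda_rule = lambda_rule,
                 lambda_value = lambda_value, eps_out = eps_out,
                 max_outer = as.integer(max_outer), delta_drop = delta_drop,
                 inner_tol = inner_tol, max_inner = as.integer(max_inner),
                 eps_stab = eps_stab, stab = stab,
                 p_switch = as.integer(p_switch), standardize = standardize,
                 unstandardize = unstandardize),
            class = "bar_control")
}

#' Fixed tuning-parameter presets for the BAR penalty
#'
#' Rather than cross-validating, the BAR penalty is fixed at an
#' information-criterion value: `lambda_n = 2` mirrors AIC, `log n` mirrors
#' BIC, and the high-dimensional BIC uses `log(log n) * log p`.
#'
#' @param rule one of `"aic"`, `"bic"`, `"hbic"`, `"fixed"`.
#' @param n sample size (`n >= 2`; `n >= 3` for `"hbic"`).
#' @param p number of penalized covariates (used by `"hbic"`).
#' @param value the penalty for `rule = "fixed"`.
#' @return a positive scalar `lambda_n`.
#' @export
choose_lambda <- function(rule = c("bic", "aic", "hbic", "fixed"), n, p = NULL,
                          value = NULL) {
  rule <- match.arg(rule)
  switch(rule,
    aic = 2,
    bic = {
      stopifnot(n >= 2)
      log(n)
    },
    hbic = {
      if (n <= exp(1)) stop("HBIC requires n > e so that log(log n) > 0",
                            call. = FALSE)
      if (is.null(p) || p < 1) stop("HBIC requires p >= 1", call. = FALSE)
      log(log(n)) * log(p)
    },
    fixed = {
      if (is.null(value) || !(value >= 0)) {
        stop("rule 'fixed' requires a nonnegative 'value'", call. = FALSE)
      }
      value
    })
}

#' Sieve log-likelihood of a generalized partly linear model
#'
#' Evaluates the log-likelihood at a partitioned coefficient vector, with the
#' nonparametric part replaced by its Bernstein sieve expansion:
#' for the logistic family
#' \deqn{\ell_n = \sum_i [y_i \eta_i - \log(1 + e^{\eta_i})]} and for the
#' Poisson family \eqn{\sum_i [y_i \eta_i - e^{\eta_i} - \log(y_i!)]}, where
#' \eqn{\eta_i} is the linear predictor with the sieve design row.
#'
#' Coefficients are interpreted on the scale of the covariates as supplied in
#' `data` (no internal standardization happens here).
#'
#' @param data a [gplm_data()].
#' @param coef a [gplm_coef()].
#' @param design a `sieve_design` built from `data$Z` (optional when the
#'   dataset has no continuous block).
#' @return scalar log-likelihood.
#' @export
sieve_loglik <- function(data, coef, design = NULL) {
  stopifnot(inherits(data, "gplm_data"), inherits(coef, "gplm_coef"))
  B <- design_block(data, design)
  eta <- gplm_eta(coef, data$X, data$W, B)
  ll <- -glm_dev(data$y, eta, data$family) / 2
  if (data$family == "poisson") ll <- ll - sum(lgamma(data$y + 1))
  ll
}

design_block <- function(data, design) {
  if (is.null(design)) {
    if (ncol(data$Z) > 0L) design <- build_sieve_design(data$Z)
    else return(matrix(numeric(0), data$n, 0))
  }
  stopifnot(inherits(design, "sieve_design"))
  design$B
}

# split an unpenalized solution u = (alpha, gamma, intercept) back into parts;
# U is built as cbind(W, B, 1)
split_u <- function(u, qw, K) {
  list(alpha = u[seq_len(qw)],
       gamma = u[qw + seq_len(K)],
       intercept = u[qw + K + 1L])
}

build_u_design <- function(data, B) {
  cbind(data$W, B, `(Intercept)` = rep(1, data$n))
}

#' Ridge initialization of the BAR recursion
#'
#' Minimizes \eqn{-2\ell_n(\alpha,\beta,\gamma) + \xi_n \sum_j \beta_j^2}:
#' only the high-dimensional block is penalized, so the estimate exists even
#' for `p > n` and provides the weights of the first BAR step.  The data are
#' used exactly as supplied (standardize `X` beforehand, or call
#' [fit_gplm_bar()], which does so internally).
#'
#' @param data a [gplm_data()].
#' @param design sieve design for `data$Z` (built automatically when NULL).
#' @param xi_n positive ridge tuning parameter.
#' @param control a [bar_control()].
#' @return a [gplm_coef()].
#' @export
ridge_init <- function(data, design = NULL, xi_n = 1,
                       control = bar_control()) {
  stopifnot(xi_n > 0)
  B <- design_block(data, design)
  U <- build_u_design(data, B)
  p <- ncol(data$X)
  fit <- solve_inner(data$y, data$X, U, data$family,
                     w_pen = rep(xi_n, p), active = rep(TRUE, p),
                     control = control)
  parts <- split_u(fit$u, ncol(data$W), ncol(B))
  gplm_coef(fit$beta, parts$alpha, parts$gamma, parts$intercept)
}

#' One broken-adaptive-ridge update
#'
#' Given the previous estimate `beta_prev`, solves the reweighted ridge
#' problem \eqn{-2\ell_n + \lambda_n \sum_j \beta_j^2 / \hat\beta_{j,prev}^2}
#' over the coordinates still active (those with
#' `|beta_prev| >= control$delta_drop`); dropped coordinates are pinned at
#' exact zero and the unpenalized block is refit alongside.  An empty active
#' set is not an error: the X-free model is returned with `beta = 0`.
#'
#' @inheritParams ridge_init
#' @param beta_prev numeric p-vector from the previous iterate.
#' @param lambda_n nonnegative BAR penalty.
#' @return a [gplm_coef()].
#' @export
bar_step <- function(data, design = NULL, beta_prev, lambda_n,
                     control = bar_control()) {
  stopifnot(lambda_n >= 0)
  B <- design_block(data, design)
  U <- build_u_design(data, B)
  p <- ncol(data$X)
  stopifnot(length(beta_prev) == p)
  active <- abs(beta_prev) >= control$delta_drop
  w <- rep(0, p)
  w[active] <- lambda_n / beta_prev[active]^2
  fit <- solve_inner(data$y, data$X, U, data$family, w_pen = w,
                     active = active, control = control,
                     beta_start = beta_prev)
  parts <- split_u(fit$u, ncol(data$W), ncol(B))
  gplm_coef(fit$beta, parts$alpha, parts$gamma, parts$intercept)
}

#' Fit a generalized partly linear model with BAR variable selection
#'
#' Runs the full estimator: internal standardization of `X`, Bernstein sieve
#' expansion of `Z` (centered at the interval midpoints, with a free
#' unpenalized intercept), ridge initialization at `xi_n`, then iteratively
#' reweighted ridge updates until the maximum absolute change in `beta` falls
#' below `eps_out`.  Coordinates falling below `delta_drop` in absolute value
#' are set to exact zero permanently, so the limit is sparse.
#'
#' @param data a [gplm_data()].
#' @param spec optional [sieve_basis_spec()] for `data$Z`; defaults to
#'   centered degree-3 blocks on the observed ranges.
#' @param control a [bar_control()].
#' @return object of class `gplm_bar_fit` with elements `coef`
#'   ([gplm_coef()]), `active_set`, `iterations`, `converged`, `lambda`,
#'   `xi`, `objective`, `loglik`, `spec`, plus the standardization record.
#' @export
fit_gplm_bar <- function(data, spec = NULL, control = bar_control()) {
  stopifnot(inherits(data, "gplm_data"))
  p <- ncol(data$X)
  std <- if (control$standardize) standardize_x(data$X)
         else list(X = data$X, center = rep(0, p), scale = rep(1, p))
  sdata <- data
  sdata$X <- std$X
  if (ncol(data$Z) > 0L) {
    if (is.null(spec)) spec <- sieve_basis_spec(data$Z)
    design <- build_sieve_design(data$Z, spec)
  } else {
    spec <- NULL
    design <- NULL
  }
  lambda <- choose_lambda(control$lambda_rule, data$n, p,
                          control$lambda_value)
  coef <- ridge_init(sdata, design, control$xi_n, control)
  beta <- coef$beta
  dropped <- rep(FALSE, p)
  converged <- FALSE
  iter <- 0L
  while (iter < control$max_outer) {
    iter <- iter + 1L
    beta_prev <- beta
    beta_prev[dropped] <- 0
    coef <- bar_step(sdata, design, beta_prev, lambda, control)
    beta <- coef$beta
    dropped <- dropped | abs(beta) < control$delta_drop
    beta[dropped] <- 0
    coef$beta <- beta
    if (max(abs(beta - beta_prev)) < control$eps_out) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("BAR did not converge in %d outer iterations", iter),
            call. = FALSE)
  }
  B <- design_block(sdata, design)
  eta <- gplm_eta(coef, sdata$X, sdata$W, B)
  # at the fixed point the BAR penalty equals lambda * #active (weights are
  # the inverse squares of the limit itself)
  obj <- glm_dev(data$y, eta, data$family) + lambda * sum(beta != 0)
  ll <- -glm_dev(data$y, eta, data$family) / 2
  if (data$family == "poisson") ll <- ll - sum(lgamma(data$y + 1))
  coef_out <- coef
  if (control$unstandardize && control$standardize && p > 0L) {
    coef_out$beta <- coef$beta / std$scale
    coef_out$intercept <- coef$intercept - sum(coef_out$beta * std$center)
  }
  structure(list(coef = coef_out, active_set = which(beta != 0),
                 iterations = iter, converged = converged, lambda = lambda,
                 xi = control$xi_n, objective = obj, loglik = ll,
                 spec = spec, family = data$family,
                 x_center = std$center, x_scale = std$scale,
                 standardized_scale = !control$unstandardize &&
                   control$standardize,
                 control = control, n = data$n, p = p,
                 x_names = colnames(data$X)),
            class = "gplm_bar_fit")
}

#' @export
print.gplm_bar_fit <- function(x, ...) {
  cat(sprintf("GPLM-BAR fit (%s family): n = %d, p = %d\n", x$family, x$n,
              x$p))
  cat(sprintf("  lambda = %.4g, xi = %.4g | %d outer iterations (%s)\n",
              x$lambda, x$xi, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  selected %d covariate(s); log-likelihood %.4f\n",
              length(x$active_set), x$loglik))
  if (length(x$active_set)) {
    nm <- if (!is.null(x$x_names)) x$x_names[x$active_set] else x$active_set
    est <- x$coef$beta[x$active_set]
    cat("  ", paste(sprintf("%s=%.3f", nm, est), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.gplm_bar_fit <- function(object, ...) {
  c(`(Intercept)` = object$coef$intercept,
    stats::setNames(object$coef$alpha,
                    paste0("w", seq_along(object$coef$alpha))),
    stats::setNames(object$coef$gamma,
                    paste0("g", seq_along(object$coef$gamma))),
    stats::setNames(object$coef$beta,
                    if (!is.null(object$x_names)) object$x_names
                    else paste0("x", seq_along(object$coef$beta))))
}

#' Predict from a fitted GPLM-BAR model
#'
#' Applies the stored standardization to new `X`, rebuilds the sieve design
#' with the training ranges (new `Z` values outside a training interval are
#' clamped to its endpoint, with a warning), and returns the inverse-link
#' transform of the linear predictor.
#'
#' @param object a `gplm_bar_fit`.
#' @param X,W,Z new covariate blocks conforming to the training dimensions.
#' @param type `"response"` (probability / mean) or `"link"`.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.gplm_bar_fit <- function(object, X, W = NULL, Z = NULL,
                                 type = c("response", "link"), ...) {
  type <- match.arg(type)
  X <- as.matrix(X)
  if (ncol(X) != object$p) {
    stop(sprintf("new X has %d columns; the fit used %d", ncol(X), object$p),
         call. = FALSE)
  }
  n <- nrow(X)
  if (object$standardized_scale && object$p > 0L) {
    X <- sweep(sweep(X, 2L, object$x_center, "-"), 2L, object$x_scale, "/")
  }
  qw <- length(object$coef$alpha)
  W <- if (is.null(W)) matrix(numeric(0), n, 0) else as.matrix(W)
  if (ncol(W) != qw) {
    stop(sprintf("new W has %d columns; the fit used %d", ncol(W), qw),
         call. = FALSE)
  }
  if (!is.null(object$spec)) {
    Z <- as.matrix(Z)
    if (ncol(Z) != length(object$spec$degree)) {
      stop("new Z does not match the fitted sieve spec", call. = FALSE)
    }
    B <- build_sieve_design(Z, object$spec)$B
  } else {
    B <- matrix(numeric(0), n, 0)
  }
  eta <- gplm_eta(object$coef, X, W, B)
  if (type == "link") return(eta)
  glm_mu(eta, object$family)
}

#' Bootstrap standard errors for a GPLM-BAR fit
#'
#' Resamples the `n` observations with replacement `B` times, refits the full
#' BAR estimator on each resample, and returns the sample standard deviation
#' of each unpenalized coefficient and of each `beta` coordinate selected in
#' the original fit.  Resamples whose refit fails are excluded and counted.
#'
#' @param data a [gplm_data()].
#' @param spec optional sieve spec, as in [fit_gplm_bar()].
#' @param control a [bar_control()].
#' @param B number of bootstrap resamples (default 100).
#' @param seed integer seed driving the resampling.
#' @param fit optional original fit (refit when NULL).
#' @return list with `se` (named vector), `selected` (indices), `B_used`,
#'   `failures`, and the resample estimates matrix `draws`.
#' @export
bootstrap_se <- function(data, spec = NULL, control = bar_control(), B = 100L,
                         seed = 1L, fit = NULL) {
  stopifnot(B >= 2)
  if (is.null(fit)) fit <- fit_gplm_bar(data, spec, control)
  sel <- fit$active_set
  set.seed(seed)
  idx <- replicate(B, sample.int(data$n, data$n, replace = TRUE),
                   simplify = FALSE)
  one <- function(ii) {
    d <- gplm_data(data$y[ii], data$X[ii, , drop = FALSE],
                   if (ncol(data$W)) data$W[ii, , drop = FALSE],
                   if (ncol(data$Z)) data$Z[ii, , drop = FALSE],
                   family = data$family)
    f <- suppressWarnings(fit_gplm_bar(d, spec, control))
    c(intercept = f$coef$intercept, f$coef$alpha, f$coef$gamma,
      f$coef$beta[sel])
  }
  draws <- vector("list", B)
  fails <- 0L
  for (b in seq_len(B)) {
    draws[[b]] <- tryCatch(one(idx[[b]]), error = function(e) NULL)
    if (is.null(draws[[b]])) fails <- fails + 1L
  }
  if (fails > 0L) {
    warning(sprintf("%d of %d bootstrap refits failed and were excluded",
                    fails, B), call. = FALSE)
  }
  M <- do.call(rbind, draws[!vapply(draws, is.null, logical(1))])
  nm <- c("(Intercept)",
          if (length(fit$coef$alpha)) paste0("w", seq_along(fit$coef$alpha)),
          if (length(fit$coef$gamma)) paste0("g", seq_along(fit$coef$gamma)),
          if (length(sel)) {
            if (!is.null(fit$x_names)) fit$x_names[sel] else paste0("x", sel)
          })
  colnames(M) <- nm
  list(se = apply(M, 2L, stats::sd), selected = sel,
       B_used = nrow(M), failures = fails, draws = M)
}
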