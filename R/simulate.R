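#' True nonlinear covariate effects used by the simulation scenarios
#'
#' The four smooths attached to the continuous covariates: a parabola, a
#' shifted cosine, a sine, and a cubic,
#' \deqn{\psi_1(z) = 0.1 (z - 3)^2, \quad \psi_2(z) = 0.2(\cos(2\pi z) + 1),}
#' \deqn{\psi_3(z) = 0.2 \sin(2\pi z), \quad \psi_4(z) = 0.2 (z + 1)^3,}
#' on domains (1,5), (0,1), (0,1) and (-3,1).  Each is symmetric about and
#' vanishes at its domain midpoint, which matches the midpoint-centering
#' identifiability convention of the sieve.
#'
#' @param j which function, 1 to 4.
#' @param z numeric vector of evaluation points.
#' @return numeric vector `psi_j(z)`.
#' @export
true_psi <- function(j, z) {
  switch(as.character(j),
         "1" = 0.1 * (z - 3)^2,
         "2" = 0.2 * (cos(2 * pi * z) + 1),
         "3" = 0.2 * sin(2 * pi * z),
         "4" = 0.2 * (z + 1)^3,
         stop("j must be 1, 2, 3 or 4", call. = FALSE))
}

# true beta vectors; nonzeros sit at coordinates (1, 2, p-2, p-1, p)
scenario_beta <- function(scenario, p) {
  vals <- switch(as.character(scenario),
                 "1" = c(1, -1, -1, 0.75, 0.75),
                 "2" = c(1, -0.5, -1, 0.4, 0.75),
                 "3" = c(2, -2, -2, 1.5, 1.5),
                 "3-weak" = c(1, -0.5, -1, 0.4, 0.75),
                 stop(sprintf("unknown scenario '%s'", scenario),
                      call. = FALSE))
  if (p < 6) stop("scenarios require p >= 6", call. = FALSE)
  beta <- numeric(p)
  beta[c(1L, 2L, p - 2L, p - 1L, p)] <- vals
  beta
}

#' Ground truth of a simulation scenario
#'
#' @param scenario `"1"` (strong signals), `"2"` (mixed weak/strong),
#'   `"3"` (high-dimensional, strong) or `"3-weak"` (high-dimensional with
#'   Scenario 2's weak signals).
#' @param p number of high-dimensional covariates.
#' @return list of class `scenario_truth`: `beta0`, `alpha0`, `support`,
#'   `rho` (AR(1) correlation of the X design), the true smooths, and the
#'   family.
#' @export
scenario_truth <- function(scenario, p) {
  beta0 <- scenario_beta(scenario, p)
  structure(list(scenario = as.character(scenario), p = as.integer(p),
                 beta0 = beta0, support = which(beta0 != 0),
                 alpha0 = c(1, -0.5, -0.5, 0.75, -1), rho = 0.25,
                 psi = lapply(1:4, function(j) function(z) true_psi(j, z)),
                 z_lower = c(1, 0, 0, -3), z_upper = c(5, 1, 1, 1),
                 family = "logistic"),
            class = "scenario_truth")
}

# n x p draw from N(0, Sigma) with AR(1) Sigma_{ij} = rho^|i-j|, built
# column-sequentially (exact, O(np), no p x p factorization)
rmvnorm_ar1 <- function(n, p, rho) {
  X <- matrix(0, n, p)
  X[, 1L] <- rnorm(n)
  if (p > 1L) {
    s <- sqrt(1 - rho^2)
    for (j in 2:p) X[, j] <- rho * X[, j - 1L] + s * rnorm(n)
  }
  X
}

#' Generate one simulated dataset from a benchmark scenario
#'
#' Draws `X` from a mean-zero multivariate normal with AR(1) covariance
#' (`rho = 0.25`), then standardizes each column (n-denominator); draws five
#' Bernoulli(0.5) indicator covariates `W`; draws four continuous covariates
#' `z1 ~ U(1,5)`, `z2, z3 ~ U(0,1)`, `z4 ~ U(-3,1)`; and generates a binary
#' response with success probability
#' \eqn{\pi_i = 1/(1 + \exp\{-\beta_0^\top x_i - \alpha_0^\top w_i -
#' \sum_j \psi_j(z_{ij})\})}.
#'
#' @param scenario scenario id, see [scenario_truth()].
#' @param n sample size.
#' @param p number of high-dimensional covariates.
#' @param seed integer seed (the call is fully deterministic given it).
#' @return list with `data` (a [gplm_data()]) and `truth`
#'   (a [scenario_truth()]).
#' @export
gen_scenario <- function(scenario, n, p, seed) {
  truth <- scenario_truth(scenario, p)
  set.seed(seed)
  X <- rmvnorm_ar1(n, p, truth$rho)
  X <- standardize_x(X)$X
  W <- matrix(rbinom(n * 5L, 1L, 0.5), n, 5L)
  Z <- cbind(runif(n, 1, 5), runif(n), runif(n), runif(n, -3, 1))
  psi_sum <- rowSums(vapply(1:4, function(j) true_psi(j, Z[, j]),
                            numeric(n)))
  eta <- drop(X %*% truth$beta0) + drop(W %*% truth$alpha0) + psi_sum
  y <- rbinom(n, 1L, 1 / (1 + exp(-eta)))
  list(data = gplm_data(y, X, W, Z, family = truth$family), truth = truth)
}

# quadratic form d' Sigma d for AR(1) Sigma, using only the nonzero entries
# of d (d is sparse here: estimated support plus true support)
ar1_quadform <- function(d, rho) {
  idx <- which(d != 0)
  if (!length(idx)) return(0)
  v <- d[idx]
  S <- rho^abs(outer(idx, idx, "-"))
  drop(t(v) %*% S %*% v)
}

#' Selection and estimation metrics for one replication
#'
#' Compares an estimated coefficient vector with the scenario truth:
#' the quadratic-form error \eqn{(\hat\beta - \beta_0)^\top \Sigma_X
#' (\hat\beta - \beta_0)} with the true AR(1) covariance, true/false
#' positives, false negatives, model size `MS = TP + FP`, misclassification
#' `MC = FN + FP`, and the exact-support indicator `TM`.
#'
#' @param beta_hat estimated p-vector (exact zeros denote exclusion).
#' @param truth a [scenario_truth()].
#' @return one-row data.frame with columns `mse, TP, FP, FN, MS, MC, TM`.
#' @export
compute_metrics <- function(beta_hat, truth) {
  stopifnot(length(beta_hat) == truth$p)
  sel <- which(beta_hat != 0)
  tp <- length(intersect(sel, truth$support))
  fp <- length(setdiff(sel, truth$support))
  fn <- length(truth$support) - tp
  data.frame(mse = ar1_quadform(beta_hat - truth$beta0, truth$rho),
             TP = tp, FP = fp, FN = fn, MS = tp + fp, MC = fn + fp,
             TM = as.integer(fp == 0L && fn == 0L))
}

# unpenalized fit on the true support (the infeasible oracle benchmark)
fit_oracle <- function(data, truth, control = bar_control()) {
  design <- if (ncol(data$Z)) build_sieve_design(data$Z) else NULL
  B <- design_block(data, design)
  U <- build_u_design(data, B)
  supp <- truth$support
  Xs <- data$X[, supp, drop = FALSE]
  D <- cbind(Xs, U)
  eps <- if (isTRUE(control$stab)) control$eps_stab else 0
  w <- rep(eps, ncol(D))
  fit <- newton_penalized(data$y, D, w, data$family,
                          tol = control$inner_tol, maxit = control$max_inner)
  beta <- numeric(ncol(data$X))
  beta[supp] <- fit$theta[seq_along(supp)]
  beta
}

#' Run a replicated simulation study
#'
#' Replicates a scenario `reps` times; replication `r` uses seed
#' `base_seed + r`, so any row of the aggregate can be rerun in isolation.
#' Each method in `methods` is either a [bar_control()] or the string
#' `"oracle"` (unpenalized fit on the true support).  Aggregates match the
#' usual benchmark table: median MSE (with the SD of the per-replication MSE
#' in `MMSE_SD`), mean TP/FP/MS/MC, and the percentage of replications
#' selecting the exact true model.
#'
#' @param scenario,n,p scenario id and dimensions, see [gen_scenario()].
#' @param reps number of replications.
#' @param methods named list; each element a [bar_control()] or `"oracle"`.
#' @param base_seed integer; replication `r` uses `base_seed + r`.
#' @param jobs parallel workers (forked; keep 1 for strict reproducibility
#'   across platforms — per-replication seeding makes results identical
#'   either way).
#' @return list with `table` (one aggregate row per method: `method, MMSE,
#'   MMSE_SD, TP, FP, MS, MC, TM_pct`), `per_rep` (all replication records)
#'   and `failures`.
#' @export
run_study <- function(scenario, n, p, reps, methods, base_seed = 0L,
                      jobs = 1L) {
  stopifnot(reps >= 1, length(methods) >= 1, !is.null(names(methods)))
  one_rep <- function(r) {
    sim <- gen_scenario(scenario, n, p, seed = base_seed + r)
    out <- lapply(names(methods), function(m) {
      spec <- methods[[m]]
      res <- tryCatch({
        beta <- if (identical(spec, "oracle")) {
          fit_oracle(sim$data, sim$truth)
        } else {
          suppressWarnings(fit_gplm_bar(sim$data, control = spec)$coef$beta)
        }
        compute_metrics(beta, sim$truth)
      }, error = function(e) NULL)
      if (is.null(res)) return(NULL)
      cbind(method = m, rep = r, res)
    })
    do.call(rbind, out)
  }
  per_rep <- if (jobs > 1L) {
    do.call(rbind, parallel::mclapply(seq_len(reps), one_rep,
                                      mc.cores = jobs))
  } else {
    do.call(rbind, lapply(seq_len(reps), one_rep))
  }
  agg <- do.call(rbind, lapply(names(methods), function(m) {
    d <- per_rep[per_rep$method == m, , drop = FALSE]
    data.frame(method = m, MMSE = median(d$mse), MMSE_SD = sd(d$mse),
               TP = mean(d$TP), FP = mean(d$FP), MS = mean(d$MS),
               MC = mean(d$MC), TM_pct = 100 * mean(d$TM))
  }))
  failures <- reps * length(methods) - nrow(per_rep)
  if (failures > 0L) {
    warning(sprintf("%d method/replication fit(s) failed and were excluded",
                    failures), call. = FALSE)
  }
  list(table = agg, per_rep = per_rep, failures = failures)
}
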