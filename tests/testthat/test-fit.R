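test_that("total shrinkage: enormous lambda gives the X-free model", {
  d <- small_instance(70, n = 100, p = 5)
  fit <- suppressWarnings(
    fit_gplm_bar(d, control = bar_control(lambda_rule = "fixed",
                                          lambda_value = 1e8)))
  expect_identical(fit$coef$beta, rep(0, 5))
  expect_length(fit$active_set, 0)
  d0 <- gplm_data(d$y, matrix(numeric(0), d$n, 0), d$W, d$Z)
  co0 <- ridge_init(d0, NULL, xi_n = 1)
  expect_equal(fit$coef$alpha, co0$alpha, tolerance = 1e-4)
})

test_that("the returned estimate is a fixed point of bar_step", {
  sim <- gen_scenario("1", 80, 6, seed = 4)
  ctrl <- bar_control(lambda_rule = "bic")
  fit <- fit_gplm_bar(sim$data, control = ctrl)
  des <- build_sieve_design(sim$data$Z, fit$spec)
  again <- bar_step(sim$data, des, fit$coef$beta, fit$lambda, ctrl)
  expect_lt(max(abs(again$beta - fit$coef$beta)), ctrl$eps_out * 10)
})

test_that("exact zeros, active set consistency and determinism", {
  sim <- gen_scenario("1", 200, 20, seed = 8)
  fit1 <- fit_gplm_bar(sim$data, control = bar_control(lambda_rule = "bic"))
  fit2 <- fit_gplm_bar(sim$data, control = bar_control(lambda_rule = "bic"))
  # beta is exactly zero off the active set (not merely small)
  expect_identical(which(fit1$coef$beta != 0), fit1$active_set)
  expect_true(all(fit1$coef$beta[-fit1$active_set] == 0))
  # deterministic given data and config
  expect_identical(fit1$coef, fit2$coef)
  expect_identical(fit1$iterations, fit2$iterations)
})

test_that("fitted smooths vanish at the interval midpoints exactly", {
  sim <- gen_scenario("1", 300, 10, seed = 12)
  fit <- fit_gplm_bar(sim$data, control = bar_control(lambda_rule = "aic"))
  ix <- 0L
  for (j in seq_along(fit$spec$degree)) {
    kj <- fit$spec$degree[j] + 1L
    gam <- fit$coef$gamma[ix + seq_len(kj)]
    ix <- ix + kj
    expect_identical(evaluate_psi(gam, fit$spec$midpoint[j], fit$spec, j), 0)
  }
})

test_that("fitted smooths track the true functions on scenario data", {
  sim <- gen_scenario("1", 800, 10, seed = 3)
  fit <- fit_gplm_bar(sim$data, control = bar_control(lambda_rule = "aic"))
  # psi_1: 0.1 (z - 3)^2 centered at 3 means the target is psi_1(z) - 0
  grid <- seq(1.2, 4.8, length.out = 50)
  gam1 <- fit$coef$gamma[1:4]
  psi_hat <- evaluate_psi(gam1, grid, fit$spec, 1)
  mad <- mean(abs(psi_hat - 0.1 * (grid - 3)^2))
  expect_lt(mad, 0.25)
})

test_that("selection is insensitive to the ridge initialization xi_n", {
  sim <- gen_scenario("1", 250, 15, seed = 21)
  sets <- lapply(c(0.1, 1, 10), function(xi)
    fit_gplm_bar(sim$data,
                 control = bar_control(xi_n = xi,
                                       lambda_rule = "bic"))$active_set)
  expect_identical(sets[[1]], sets[[2]])
  expect_identical(sets[[2]], sets[[3]])
})

test_that("poisson family fits and selects", {
  set.seed(90)
  n <- 300; p <- 8
  X <- standardize_cols(matrix(rnorm(n * p), n, p))
  eta <- 0.8 * X[, 1] - 0.8 * X[, 2] + 0.3
  y <- rpois(n, exp(eta))
  d <- gplm_data(y, X, family = "poisson")
  fit <- fit_gplm_bar(d, control = bar_control(lambda_rule = "bic"))
  expect_true(all(c(1, 2) %in% fit$active_set))
  expect_true(all(predict(fit, X) > 0))
})

test_that("bootstrap standard errors are deterministic and calibrated", {
  # one strong binary covariate: compare against the closed-form Wald SE
  set.seed(17)
  n <- 400
  x <- rbinom(n, 1, 0.5)
  eta <- -0.2 + 1.2 * x
  y <- rbinom(n, 1, 1 / (1 + exp(-eta)))
  # X must be standardized scale-free: use W for the unpenalized route and
  # a noise X column so the model shape is exercised
  X <- standardize_cols(matrix(rnorm(n), n, 1))
  d <- gplm_data(y, X, W = matrix(x, n, 1))
  ctrl <- bar_control(lambda_rule = "bic")
  fit <- fit_gplm_bar(d, control = ctrl)
  bs1 <- bootstrap_se(d, NULL, ctrl, B = 60, seed = 5, fit = fit)
  bs2 <- bootstrap_se(d, NULL, ctrl, B = 60, seed = 5, fit = fit)
  expect_identical(bs1$se, bs2$se)
  expect_equal(bs1$B_used + bs1$failures, 60)
  # Wald SE for the w-coefficient from the information matrix of the
  # intercept + x logistic model
  g <- stats::glm(y ~ x, family = stats::binomial())
  wald <- summary(g)$coefficients["x", "Std. Error"]
  expect_lt(abs(bs1$se[["w1"]] - wald) / wald, 0.25)
})
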