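# Oracle equivalence: every inner solve must agree with a generic black-box
# minimizer of the identical objective.  The instances use a moderately large
# stabilizing ridge (through bar_control(eps_stab =)) so that the objective
# is well conditioned for BFGS too; the equivalence is a property of the
# solver, not of the default settings.

oracle_ctrl <- bar_control(eps_stab = 1e-3)

test_that("ridge_init agrees with a generic optimizer on random instances", {
  worst <- 0
  set.seed(1)
  for (seed in 1:12) {
    d <- small_instance(seed, n = sample(40:100, 1), p = sample(2:6, 1))
    des <- build_sieve_design(d$Z)
    xi <- sample(c(0.5, 1, 2), 1)
    co <- ridge_init(d, des, xi_n = xi, control = oracle_ctrl)
    w <- rep(xi, ncol(d$X))
    ours <- flatten_coef(co)
    ref <- optim_oracle(d, des, w, eps = 1e-3, start = ours)
    worst <- max(worst, max(abs(ours - ref)))
  }
  expect_lt(worst, 1e-5)
})

test_that("bar_step agrees with a generic optimizer of the weighted objective", {
  worst <- 0
  set.seed(99)
  for (seed in 13:22) {
    d <- small_instance(seed, n = sample(50:100, 1), p = 4)
    des <- build_sieve_design(d$Z)
    init <- ridge_init(d, des, xi_n = 1, control = oracle_ctrl)
    beta_prev <- init$beta
    # occasionally force a dropped coordinate
    if (seed %% 3 == 0) beta_prev[2] <- 0
    lam <- sample(c(2, log(d$n)), 1)
    co <- bar_step(d, des, beta_prev, lam, control = oracle_ctrl)
    active <- abs(beta_prev) >= oracle_ctrl$delta_drop
    expect_true(all(co$beta[!active] == 0))
    w <- rep(0, 4)
    w[active] <- lam / beta_prev[active]^2
    ours <- flatten_coef(co, active)
    ref <- optim_oracle(d, des, w, eps = 1e-3, active = active, start = ours)
    worst <- max(worst, max(abs(ours - ref)))
  }
  expect_lt(worst, 1e-5)
})

test_that("coordinate-descent route matches the Newton route", {
  # forcing p_switch = 0 sends the same problems through the large-p solver
  ccd_ctrl <- bar_control(eps_stab = 1e-3, p_switch = 0L)
  for (seed in c(2, 8, 15)) {
    d <- small_instance(seed, n = 80, p = 6)
    des <- build_sieve_design(d$Z)
    a <- ridge_init(d, des, xi_n = 1, control = oracle_ctrl)
    b <- ridge_init(d, des, xi_n = 1, control = ccd_ctrl)
    expect_equal(flatten_coef(a), flatten_coef(b), tolerance = 1e-5)
    stepA <- bar_step(d, des, a$beta, log(d$n), control = oracle_ctrl)
    stepB <- bar_step(d, des, a$beta, log(d$n), control = ccd_ctrl)
    expect_equal(flatten_coef(stepA), flatten_coef(stepB), tolerance = 1e-5)
  }
})

test_that("ridge penalty domination: huge xi_n shrinks beta toward zero", {
  d <- small_instance(30, n = 80, p = 4)
  des <- build_sieve_design(d$Z)
  co <- ridge_init(d, des, xi_n = 1e8)
  expect_lt(sqrt(sum(co$beta^2)), 1e-3)
  # alpha/gamma approach the X-free fit
  d0 <- gplm_data(d$y, matrix(numeric(0), d$n, 0), d$W, d$Z)
  co0 <- ridge_init(d0, des, xi_n = 1)
  expect_equal(co$alpha, co0$alpha, tolerance = 1e-3)
  expect_equal(co$intercept, co0$intercept, tolerance = 1e-3)
})

test_that("bar_step weight asymptotics: tiny previous coordinates vanish", {
  d <- small_instance(41, n = 60, p = 3)
  des <- build_sieve_design(d$Z)
  # previous iterate: one dominant coordinate, the others at delta/2
  beta_prev <- c(1e6, 5e-7, 5e-7)
  co <- bar_step(d, des, beta_prev, lambda_n = log(d$n))
  expect_identical(co$beta[2:3], c(0, 0))
  # with a negligible weight lambda/1e12 the survivor is close to the
  # single-covariate (unpenalized) MLE
  mle <- bar_step(d, des, c(1e6, 5e-7, 5e-7), lambda_n = 0)
  expect_equal(co$beta[1], mle$beta[1], tolerance = 1e-4)
})

test_that("bar_step with lambda = 0 returns the unpenalized fit", {
  d <- small_instance(55, n = 70, p = 3)
  des <- build_sieve_design(d$Z)
  beta_prev <- rep(1, 3)
  co <- bar_step(d, des, beta_prev, lambda_n = 0,
                 control = oracle_ctrl)
  ref <- optim_oracle(d, des, rep(0, 3), eps = 1e-3,
                      start = flatten_coef(co))
  expect_equal(flatten_coef(co), ref, tolerance = 1e-5)
})

test_that("empty active set returns the X-free fit, not an error", {
  d <- small_instance(60, n = 50, p = 3)
  des <- build_sieve_design(d$Z)
  co <- bar_step(d, des, rep(0, 3), lambda_n = 2)
  expect_identical(co$beta, rep(0, 3))
  expect_true(all(is.finite(c(co$alpha, co$gamma, co$intercept))))
})

test_that("inner solves never increase the objective they minimize", {
  for (seed in c(3, 14)) {
    d <- small_instance(seed, n = 80, p = 5)
    des <- build_sieve_design(d$Z)
    init <- ridge_init(d, des, xi_n = 1)
    beta_prev <- init$beta
    for (s in 1:4) {
      active <- abs(beta_prev) >= 1e-6
      lam <- log(d$n)
      w <- rep(0, 5)
      w[active] <- lam / beta_prev[active]^2
      f <- make_objective(d, des, w, eps = 1e-8, active = active)
      start_val <- f(c(beta_prev[active], init$alpha, init$gamma,
                       init$intercept))
      co <- bar_step(d, des, beta_prev, lam)
      end_val <- f(flatten_coef(co, active))
      expect_lte(end_val, start_val + 1e-9)
      beta_prev <- co$beta
    }
  }
})
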