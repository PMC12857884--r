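test_that("true smooths: closed-form values and midpoint zeros", {
  expect_equal(true_psi(1, c(1, 5)), c(0.4, 0.4))
  expect_equal(true_psi(4, -1), 0)
  expect_equal(true_psi(2, c(0, 0.25, 0.5)), c(0.4, 0.2, 0),
               tolerance = 1e-15)
  # all four vanish at the domain midpoints
  mids <- c(3, 0.5, 0.5, -1)
  for (j in 1:4) expect_equal(true_psi(j, mids[j]), 0, tolerance = 1e-15)
  expect_error(true_psi(5, 0), "must be")
})

test_that("scenario truths carry the stated coefficient patterns", {
  for (sc in c("1", "2", "3", "3-weak")) {
    tr <- scenario_truth(sc, 50)
    expect_identical(tr$support, c(1L, 2L, 48L, 49L, 50L))
    expect_length(tr$alpha0, 5)
    expect_identical(tr$rho, 0.25)
  }
  expect_equal(scenario_truth("1", 10)$beta0[c(1, 2, 8, 9, 10)],
               c(1, -1, -1, 0.75, 0.75))
  expect_equal(scenario_truth("2", 10)$beta0[c(1, 2, 8, 9, 10)],
               c(1, -0.5, -1, 0.4, 0.75))
  expect_equal(scenario_truth("3", 10)$beta0[c(1, 2, 8, 9, 10)],
               c(2, -2, -2, 1.5, 1.5))
  expect_error(gen_scenario("9", 100, 10, 1), "unknown scenario")
})

test_that("generator is deterministic and matches its stated laws", {
  a <- gen_scenario("1", 50, 8, seed = 77)
  b <- gen_scenario("1", 50, 8, seed = 77)
  expect_identical(a$data$X, b$data$X)
  expect_identical(a$data$y, b$data$y)
  # law-of-large-numbers checks at n = 1e5
  big <- gen_scenario("1", 1e5, 6, seed = 3)
  expect_true(all(abs(colMeans(big$data$W) - 0.5) < 0.005))
  expect_lt(abs(cor(big$data$X[, 1], big$data$X[, 2]) - 0.25), 0.01)
  # Z ranges as stated
  expect_true(all(big$data$Z[, 1] > 1 & big$data$Z[, 1] < 5))
  expect_true(all(big$data$Z[, 4] > -3 & big$data$Z[, 4] < 1))
  # X standardized with the n-denominator convention
  expect_equal(unname(colMeans(big$data$X)), rep(0, 6), tolerance = 1e-10)
  expect_equal(unname(colSums(big$data$X^2)) / 1e5, rep(1, 6),
               tolerance = 1e-10)
})

test_that("selection metrics: exact cases and the quadratic form", {
  tr <- scenario_truth("1", 20)
  m <- compute_metrics(tr$beta0, tr)
  expect_equal(unlist(m), c(mse = 0, TP = 5, FP = 0, FN = 0, MS = 5,
                            MC = 0, TM = 1))
  m0 <- compute_metrics(rep(0, 20), tr)
  expect_equal(unlist(m0), c(mse = ar1_quadform_ref(tr$beta0, 0.25),
                             TP = 0, FP = 0, FN = 5, MS = 0, MC = 5,
                             TM = 0), tolerance = 1e-12)
  # unit bump on coordinate 1: MSE = Sigma[1,1] = 1
  m1 <- compute_metrics(tr$beta0 + c(1, rep(0, 19)), tr)
  expect_equal(m1$mse, 1)
  expect_identical(m1$TM, 1L)  # support unchanged by the bump
})

test_that("metric algebra holds for random estimates", {
  set.seed(13)
  tr <- scenario_truth("2", 30)
  for (i in 1:20) {
    bh <- rbinom(30, 1, 0.2) * rnorm(30)
    m <- compute_metrics(bh, tr)
    expect_identical(m$MS, m$TP + m$FP)
    expect_identical(m$MC, m$FN + m$FP)
    expect_identical(m$TP + m$FN, 5L)
    expect_equal(m$mse, ar1_quadform_ref(bh - tr$beta0, 0.25),
                 tolerance = 1e-10)
  }
})

test_that("run_study: plumbing, reproducibility and oracle dominance", {
  methods <- list(bar_bic = bar_control(lambda_rule = "bic"),
                  oracle = "oracle")
  r1 <- run_study("1", 200, 10, reps = 5, methods, base_seed = 40)
  r2 <- run_study("1", 200, 10, reps = 5, methods, base_seed = 40)
  expect_identical(r1$table, r2$table)
  expect_identical(dim(r1$per_rep), c(10L, 9L))
  # oracle dominance on the same seeds
  expect_lte(r1$table$MMSE[r1$table$method == "oracle"],
             r1$table$MMSE[r1$table$method == "bar_bic"])
  # single-rep oracle recovers the truth on strong signals
  r3 <- run_study("1", 400, 10, reps = 1,
                  methods = list(oracle = "oracle"), base_seed = 7)
  expect_identical(r3$table$TM_pct, 100)
  expect_identical(r3$table$MS, 5)
})

test_that("TM frequency does not degrade from n=600 to n=800 (reduced reps)", {
  methods <- list(bar_bic = bar_control(lambda_rule = "bic"))
  t600 <- run_study("1", 600, 30, reps = 10, methods, base_seed = 500)
  t800 <- run_study("1", 800, 30, reps = 10, methods, base_seed = 500)
  # Monte-Carlo tolerance: one rep out of ten
  expect_gte(t800$table$TM_pct, t600$table$TM_pct - 10)
})
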