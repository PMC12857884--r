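test_that("Bernstein basis: endpoint, midpoint and direct-evaluation values", {
  # left endpoint: t = 0
  expect_equal(drop(bernstein_basis(0, 3, 0, 1)), c(1, 0, 0, 0),
               tolerance = 1e-15)
  # midpoint, m = 3: binomial coefficients at t = 1/2
  expect_equal(drop(bernstein_basis(0.5, 3, 0, 1)),
               c(1, 3, 3, 1) / 8, tolerance = 1e-14)
  # the same on a shifted interval
  expect_equal(drop(bernstein_basis(3, 3, 1, 5)), c(1, 3, 3, 1) / 8,
               tolerance = 1e-14)
  # brute-force binomial expansion at z = 0.3
  k <- 0:3
  expect_equal(drop(bernstein_basis(0.3, 3, 0, 1)),
               choose(3, k) * 0.3^k * 0.7^(3 - k), tolerance = 1e-14)
})

test_that("Bernstein basis: partition of unity, nonnegativity, endpoints", {
  set.seed(11)
  for (case in 1:25) {
    m <- sample(1:6, 1)
    c0 <- runif(1, -5, 2)
    u0 <- c0 + runif(1, 0.5, 6)
    z <- runif(20, c0, u0)
    B <- bernstein_basis(z, m, c0, u0)
    expect_true(all(B >= 0) && all(B <= 1))
    expect_equal(rowSums(B), rep(1, 20), tolerance = 1e-12)
    expect_equal(bernstein_basis(c0, m, c0, u0)[1, 1], 1)
    expect_equal(bernstein_basis(u0, m, c0, u0)[1, m + 1], 1)
  }
})

test_that("Bernstein basis: invalid inputs and clamping", {
  expect_error(bernstein_basis(0.5, 3, 1, 1), "invalid range")
  expect_error(bernstein_basis(0.5, 3, 2, 1), "invalid range")
  expect_error(bernstein_basis(0.5, 0, 0, 1), "invalid degree")
  expect_warning(B <- bernstein_basis(c(-1, 2), 2, 0, 1), "clamped")
  expect_equal(B[1, ], c(1, 0, 0))
  expect_equal(B[2, ], c(0, 0, 1))
})

test_that("degree elevation: a low-degree polynomial is reproduced exactly", {
  # q(z) = 2 - z + 0.5 z^2 on [1, 5], expressed in the degree-3 basis via
  # interpolation at 4 nodes, must match brute-force evaluation everywhere
  q <- function(z) 2 - z + 0.5 * z^2
  nodes <- seq(1, 5, length.out = 4)
  gamma <- solve(bernstein_basis(nodes, 3, 1, 5), q(nodes))
  grid <- seq(1, 5, length.out = 201)
  expect_equal(drop(bernstein_basis(grid, 3, 1, 5) %*% gamma), q(grid),
               tolerance = 1e-10)
})

test_that("sieve design: partition of unity per block and midpoint centering", {
  set.seed(21)
  Z <- cbind(runif(5, 1, 5), runif(5))
  spec_off <- sieve_basis_spec(Z, degree = 3, center = FALSE)
  des_off <- build_sieve_design(Z, spec_off)
  for (j in 1:2) {
    expect_equal(rowSums(des_off$B[, des_off$block[[j]]]), rep(1, 5),
                 tolerance = 1e-12)
  }
  spec_on <- sieve_basis_spec(Z, degree = 3, center = TRUE)
  des_on <- build_sieve_design(Z, spec_on)
  # a midpoint row of the centered design is exactly zero
  Zmid <- matrix(spec_on$midpoint, 1)
  des_mid <- build_sieve_design(Zmid, spec_on)
  expect_equal(unname(drop(des_mid$B)), rep(0, ncol(des_mid$B)))
  # centering idempotence: the centered basis evaluated at the midpoint is
  # zero, so subtracting it again changes nothing
  again <- sweep(des_on$B, 2L, drop(des_mid$B), "-")
  expect_identical(again, des_on$B)
  expect_equal(ncol(des_on$B), sum(spec_on$degree + 1))
})

test_that("sieve design rejects constant columns", {
  Z <- cbind(runif(10), rep(2, 10))
  expect_error(build_sieve_design(Z), "invalid range.*constant",
               ignore.case = TRUE)
})

test_that("least-squares projection recovers a smooth function", {
  set.seed(31)
  z <- runif(100, 1, 5)
  f <- 0.1 * (z - 3)^2
  spec <- sieve_basis_spec(matrix(z), degree = 3, lower = 1, upper = 5,
                           center = FALSE)
  B <- build_sieve_design(matrix(z), spec)$B
  gam <- qr.solve(B, f)
  grid <- seq(1, 5, length.out = 200)
  approx_err <- abs(evaluate_psi(gam, grid, spec) - 0.1 * (grid - 3)^2)
  expect_lt(max(approx_err), 0.05)
})

test_that("evaluate_psi: degenerate coefficient blocks and length checks", {
  spec <- sieve_basis_spec(lower = c(z1 = 0), upper = c(z1 = 1),
                           center = FALSE)
  grid <- seq(0, 1, 0.1)
  expect_equal(evaluate_psi(rep(0, 4), grid, spec), rep(0, length(grid)))
  # constant gamma, centering off: partition of unity gives the constant back
  expect_equal(evaluate_psi(rep(2.5, 4), grid, spec),
               rep(2.5, length(grid)), tolerance = 1e-12)
  expect_error(evaluate_psi(rep(0, 3), grid, spec), "length")
  # centered spec: psi at the midpoint is exactly zero whatever gamma is
  spec_c <- sieve_basis_spec(lower = c(z1 = 0), upper = c(z1 = 1))
  expect_identical(evaluate_psi(rnorm(4), 0.5, spec_c), 0)
})
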