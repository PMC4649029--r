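# Small helper: wrap a bare (A, b) pair as a lyap_system so the solvers can
# be exercised on textbook examples independent of any covariance.
toy_system <- function(A, b) {
  A <- as.matrix(A)
  p <- ncol(A)
  side <- ceiling(sqrt(p))
  mask <- matrix(FALSE, side, side)
  mask[seq_len(p)] <- TRUE
  pat <- jacobian_pattern(t(mask))  # row-major filling
  structure(list(A = A, b = as.numeric(b), index_map = pat$index_map,
                 row_map = cbind(i = seq_len(nrow(A)), k = rep(1L, nrow(A))),
                 kappa_A = condition_number(A), n = side, p = p,
                 species_ids = pat$species_ids, pattern = pat),
            class = "lyap_system")
}

test_that("OLS solves textbook systems and matches the normal equations", {
  expect_equal(solve_ols(toy_system(diag(3), c(1, -2, 5)))$x, c(1, -2, 5))
  # two observations of one unknown -> their mean
  expect_equal(solve_ols(toy_system(matrix(1, 2, 1), c(1, 3)))$x, 2)
  # explicit (A^T A)^{-1} A^T b oracle on a well-conditioned random system
  set.seed(1)
  A <- matrix(rnorm(48), 12, 4); b <- rnorm(12)
  sys <- toy_system(A, b)
  expect_lt(sys$kappa_A, 1e6)
  expect_equal(solve_ols(sys)$x,
               as.numeric(solve(crossprod(A), crossprod(A, b))),
               tolerance = 1e-9)
})

test_that("OLS returns the minimum-norm solution with a warning when rank-deficient", {
  A <- cbind(c(1, 1), c(1, 1))
  expect_warning(f <- solve_ols(toy_system(A, c(2, 2))), "rank-deficient")
  expect_equal(f$x, c(1, 1))  # minimum-norm among x1 + x2 = 2
})

test_that("TSVD truncation behaves as the spectral filter formula", {
  set.seed(2)
  A <- matrix(rnorm(40), 10, 4); b <- rnorm(10)
  sys <- toy_system(A, b)
  # t = 0 is exactly OLS
  expect_lt(max(abs(solve_tsvd(sys, 0)$x - solve_ols(sys)$x)), 1e-12)
  # auto mode zeroes the component with a vanishing singular value
  sys2 <- toy_system(diag(c(1, 1e-12)), c(1, 1))
  f2 <- solve_tsvd(sys2, "auto")
  expect_equal(f2$hyper$t, 1L)
  expect_equal(f2$x, c(1, 0))
  # t = p - 1 keeps only the leading singular triplet
  sv <- svd(A)
  x1 <- as.numeric((sum(sv$u[, 1] * b) / sv$d[1]) * sv$v[, 1])
  expect_equal(solve_tsvd(sys, 3)$x, x1, tolerance = 1e-12)
  expect_error(solve_tsvd(sys, 4), "t < p")
})

test_that("TTLS agrees with OLS on consistent systems and solves scalars", {
  set.seed(3)
  A <- matrix(rnorm(60), 20, 3)
  x_true <- c(1, -0.5, 2)
  sys <- toy_system(A, as.numeric(A %*% x_true))
  expect_lt(max(abs(solve_ttls(sys, 0)$x - solve_ols(sys)$x)), 1e-8)
  expect_equal(solve_ttls(toy_system(matrix(2), 4))$x, 2, tolerance = 1e-12)
})

test_that("TTLS beats OLS under errors in the design matrix", {
  # errors-in-variables: noise on A only, averaged over 100 seeded draws
  set.seed(4)
  A <- matrix(rnorm(40), 20, 2)
  x_true <- c(2, -1)
  b <- as.numeric(A %*% x_true)
  err <- matrix(NA_real_, 100, 2)
  for (r in 1:100) {
    An <- A + matrix(rnorm(40, sd = 0.05), 20, 2)
    sys <- toy_system(An, b)
    err[r, 1] <- sqrt(sum((solve_ols(sys)$x - x_true)^2))
    err[r, 2] <- sqrt(sum((solve_ttls(sys, 0)$x - x_true)^2))
  }
  expect_lt(mean(err[, 2]), mean(err[, 1]))
})

test_that("Tikhonov limits and scalar closed form are exact", {
  set.seed(5)
  A <- matrix(rnorm(36), 12, 3); b <- rnorm(12)
  sys <- toy_system(A, b)
  ols <- solve_ols(sys)$x
  expect_lt(max(abs(solve_tikhonov(sys, 0)$x - ols)), 1e-10)
  # lambda -> infinity pins the solution to the prior x0
  v <- c(0.3, -1, 2)
  f_inf <- solve_tikhonov(sys, 1e12, x0 = v)
  expect_lt(max(abs(f_inf$x - v)) / max(abs(v)), 1e-5)
  # scalar: x = (a b + lambda x0) / (a^2 + lambda)
  expect_equal(solve_tikhonov(toy_system(matrix(1), 1), 1)$x, 0.5)
  expect_error(solve_tikhonov(sys, -1), "non-negative")
})

test_that("Tikhonov residual and solution norms are monotone along a lambda grid", {
  set.seed(6)
  A <- matrix(rnorm(60), 20, 3); b <- rnorm(20)
  sys <- toy_system(A, b)
  grid <- 10^seq(-8, 4, length.out = 30)
  rn <- sn <- numeric(30)
  for (i in seq_along(grid)) {
    f <- solve_tikhonov(sys, grid[i])
    rn[i] <- f$residual_norm; sn[i] <- f$solution_norm
  }
  expect_true(all(diff(rn) >= -1e-10))
  expect_true(all(diff(sn) <= 1e-10))
})

test_that("lambda selection respects the grid and prefers weak regularization on clean data", {
  set.seed(7)
  A <- qr.Q(qr(matrix(rnorm(100), 10, 10)))[, 1:3] %*% diag(c(3, 2, 1))
  x_true <- c(1, 2, -1)
  sys <- toy_system(A, as.numeric(A %*% x_true))
  expect_lt(sys$kappa_A, 10)
  expect_warning(l1 <- select_lambda(sys, method = "lcurve", grid = 0.1),
                 "single candidate")
  expect_equal(l1, 0.1)
  grid <- 10^seq(-10, 2, length.out = 25)
  for (meth in c("lcurve", "cv")) {
    lam <- select_lambda(sys, method = meth, grid = grid)
    expect_lte(lam, stats::median(grid))
    # the selected lambda barely biases the solution on exact data
    expect_lt(max(abs(solve_tikhonov(sys, lam)$x - x_true)), 1e-3)
  }
})

test_that("truncation selection counts singular values under the threshold", {
  expect_equal(select_truncation(c(1, 0.5, 1e-12), 1e-8), 1L)
  expect_equal(select_truncation(rep(2, 5), 1e-8), 0L)
  expect_equal(select_truncation(c(1, 1e-3, 1e-6, 1e-9), 1e-5), 2L)
})

test_that("devectorize inverts the row-major vectorization", {
  pat <- jacobian_pattern(matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2))
  expect_equal(devectorize(numeric(pat$p), pat), matrix(0, 2, 2),
               ignore_attr = TRUE)
  # full pattern is a plain row-major reshape
  full <- jacobian_pattern(matrix(TRUE, 2, 2))
  expect_equal(unname(devectorize(1:4, full)),
               matrix(1:4, 2, 2, byrow = TRUE))
  expect_error(devectorize(1:5, full), "length")
})

test_that("all four solvers agree with the truth on clean well-conditioned systems", {
  m <- make_random_mass_action_network(7, density = 0.3, seed = 21)
  ss <- attr(m, "steady_state")
  J0 <- numerical_jacobian(m, ss$state)
  pat <- pattern_from_stoichiometry(m)
  D0 <- default_fluctuation(ss)
  sys <- build_linear_system(solve_lyapunov_forward(J0, D0), D0, pat)
  x0 <- vectorize_jacobian(J0, pat)
  lam_small <- 1e-10 * svd(sys$A, nu = 0, nv = 0)$d[sys$p]^2
  fits <- list(solve_ols(sys), solve_tsvd(sys), solve_ttls(sys),
               solve_tikhonov(sys, lam_small))
  for (f in fits) {
    expect_true(all(is.finite(f$x)))
    expect_lt(max(abs(f$x - x0)), 1e-6)
    # estimates are exactly zero off-pattern
    expect_true(all(f$J[!pat$mask] == 0))
  }
})
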