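test_that("forward Lyapunov solve handles diagonal cases exactly", {
  # J = -I: J C + C J^T = -2C, so C = D
  expect_equal(solve_lyapunov_forward(-diag(2), diag(2))$C, diag(2))
  # diagonal J: C_ii = D_ii / |J_ii|
  expect_equal(solve_lyapunov_forward(diag(c(-1, -2)), diag(2))$C,
               diag(c(1, 0.5)))
})

test_that("forward solve matches the Kronecker brute-force oracle", {
  for (s in 1:5) {
    jd <- stable_JD(6, seed = s)
    C <- solve_lyapunov_forward(jd$J, jd$D)$C
    expect_lt(max(abs(C - kron_lyap(jd$J, jd$D))), 1e-8)
    expect_lt(norm(jd$J %*% C + C %*% t(jd$J) + 2 * jd$D, "F"),
              1e-10 * norm(2 * jd$D, "F"))
  }
})

test_that("forward solve rejects unstable Jacobians", {
  expect_error(solve_lyapunov_forward(diag(c(1, -1)), diag(2)), "Hurwitz")
})

test_that("scalar linear system encodes 2jc = -2d", {
  pat <- jacobian_pattern(matrix(TRUE, 1, 1))
  sys <- build_linear_system(matrix(3), matrix(1.5), pat)
  expect_equal(as.numeric(sys$A), 6)   # 2c
  expect_equal(sys$b, -3)              # -2d
  expect_equal(solve_ols(sys)$x, -0.5) # x = -d/c
})

test_that("identity covariance yields unit coefficients per equation", {
  # with C = I the equation (i,k) reads J(i,k) + J(k,i) = -2 D(i,k)
  pat <- jacobian_pattern(matrix(TRUE, 2, 2))
  D <- matrix(c(1, 0.25, 0.25, 2), 2, 2)
  sys <- suppressWarnings(build_linear_system(diag(2), D, pat))
  expect_equal(nrow(sys$A), 4)
  for (r in seq_len(4)) {
    i <- sys$row_map[r, "i"]; k <- sys$row_map[r, "k"]
    expected <- numeric(4)
    q_ik <- which(sys$index_map[, 1] == i & sys$index_map[, 2] == k)
    q_ki <- which(sys$index_map[, 1] == k & sys$index_map[, 2] == i)
    expected[q_ik] <- expected[q_ik] + 1
    expected[q_ki] <- expected[q_ki] + 1
    expect_equal(sys$A[r, ], expected)
    expect_equal(sys$b[r], -2 * D[i, k])
  }
})

test_that("the true Jacobian satisfies the built system exactly", {
  # forward-solve consistency: A vec_p(J0) = b to machine precision
  for (s in c(3, 8)) {
    m <- make_random_mass_action_network(4 + s %% 4, density = 0.35, seed = s)
    ss <- attr(m, "steady_state")
    J0 <- numerical_jacobian(m, ss$state)
    pat <- pattern_from_stoichiometry(m)
    D0 <- default_fluctuation(ss)
    C0 <- solve_lyapunov_forward(J0, D0)
    sys <- build_linear_system(C0, D0, pat)
    x0 <- vectorize_jacobian(J0, pat)
    expect_lt(max(abs(sys$A %*% x0 - sys$b)),
              1e-10 * max(abs(sys$b)))
  }
})

test_that("duplicated equation rows (i,k)/(k,i) are identical for symmetric D", {
  jd <- stable_JD(4, seed = 2)
  C <- solve_lyapunov_forward(jd$J, jd$D)
  pat <- jacobian_pattern(matrix(TRUE, 4, 4))
  sys <- suppressWarnings(build_linear_system(C, jd$D, pat))
  rm_ <- sys$row_map
  for (r in seq_len(nrow(rm_))) {
    twin <- which(rm_[, "i"] == rm_[r, "k"] & rm_[, "k"] == rm_[r, "i"])
    expect_equal(sys$A[r, ], sys$A[twin, ])
    expect_equal(sys$b[r], sys$b[twin])
  }
  # collapse option keeps only the n(n+1)/2 unique equations
  sys_c <- suppressWarnings(build_linear_system(C, jd$D, pat, collapse = TRUE))
  expect_equal(nrow(sys_c$A), 10)
})

test_that("condition number of A is invariant under rescaling C", {
  jd <- stable_JD(5, seed = 4)
  C <- solve_lyapunov_forward(jd$J, jd$D)$C
  pat <- jacobian_pattern(lower.tri(diag(5), diag = TRUE))  # p = n(n+1)/2
  k1 <- build_linear_system(C, jd$D, pat)$kappa_A
  k2 <- build_linear_system(17.3 * C, jd$D, pat)$kappa_A
  expect_equal(k1, k2, tolerance = 1e-8)
})

test_that("pattern size warnings and errors fire", {
  pat_full <- jacobian_pattern(matrix(TRUE, 2, 2))  # p = 4 > n(n+1)/2 = 3
  expect_warning(build_linear_system(diag(2), diag(2), pat_full),
                 "no longer overdetermined")
})

test_that("condition number matches singular-value and eigenvalue oracles", {
  expect_equal(condition_number(diag(c(3, 1))), 3)
  Q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  expect_equal(condition_number(Q), 1, tolerance = 1e-12)
  set.seed(5)
  M <- matrix(rnorm(24), 8, 3)
  lam <- eigen(crossprod(M), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(condition_number(M), sqrt(max(lam) / min(lam)), tolerance = 1e-10)
  # numerically singular matrices report Inf rather than overflow
  expect_identical(condition_number(matrix(c(1, 0, 0, 0), 2, 2)), Inf)
})

test_that("Lyapunov residual is 0 for exact triples, 1 for J = 0, monotone in error", {
  jd <- stable_JD(5, seed = 6)
  C <- solve_lyapunov_forward(jd$J, jd$D)
  expect_lt(lyapunov_residual(jd$J, C, jd$D), 1e-10)
  expect_equal(lyapunov_residual(matrix(0, 5, 5), C, jd$D), 1)
  res <- vapply(c(0.01, 0.1, 0.5),
                function(e) lyapunov_residual(jd$J * (1 + e), C, jd$D), 0)
  expect_true(all(diff(res) > 0))
  # zero D returns the unnormalized residual with a flag
  r0 <- lyapunov_residual(jd$J, C, matrix(0, 5, 5))
  expect_true(isTRUE(attr(r0, "unnormalized")))
})

test_that("noiseless round trip recovers the Jacobian by OLS", {
  for (s in 1:12) {
    n <- 3 + (s %% 8)
    m <- make_random_mass_action_network(n, density = 0.35, seed = 40 + s)
    ss <- attr(m, "steady_state")
    J0 <- numerical_jacobian(m, ss$state)
    pat <- pattern_from_stoichiometry(m)
    D0 <- default_fluctuation(ss)
    sys <- build_linear_system(solve_lyapunov_forward(J0, D0), D0, pat)
    if (sys$kappa_A > 1e8) next
    x0 <- vectorize_jacobian(J0, pat)
    expect_lt(max(abs(solve_ols(sys)$x - x0)), 1e-6)
  }
})
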