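test_that("ode_rhs is stoichiometry times rate laws", {
  # linear model f(S) = M S with diagonal M
  m <- kinetic_model(c("X", "Y"), diag(2),
                     list(quote(-1 * X), quote(-2 * Y)),
                     initial_state = c(X = 1, Y = 1))
  expect_equal(unname(ode_rhs(m, c(1, 1))), c(-1, -2))

  expect_equal(unname(ode_rhs(chain_ab(k1 = 2), c(3, 0))), c(-6, 6))

  # at a converged steady state the rhs vanishes below the tolerance
  m2 <- linear2_model()
  ss <- find_steady_state(m2, tol = 1e-9)
  expect_true(ss$converged)
  expect_lte(max(abs(ode_rhs(m2, ss$state))), 1e-9)
})

test_that("ode_rhs validates input and names offending reactions", {
  m <- kinetic_model("A", matrix(-1, 1, 1), list(quote(k / A)), c(k = 1),
                     initial_state = c(A = 1))
  expect_error(ode_rhs(m, c(1, 2)), "does not match")
  expect_error(ode_rhs(m, NaN), "non-finite")
  expect_error(ode_rhs(m, 0), "v1")  # division by zero names the reaction
})

test_that("numerical_jacobian matches known derivatives", {
  # derivative of a linear map is the map itself, at any state
  M <- matrix(c(-1.5, 0.3, 2, -4), 2, 2)
  m <- kinetic_model(c("X", "Y"), diag(2),
                     list(str2lang("-1.5 * X + 2 * Y"), str2lang("0.3 * X - 4 * Y")),
                     initial_state = c(X = 1, Y = 1))
  for (s in list(c(1, 1), c(0.2, 5), c(0, 0))) {
    expect_lt(max(abs(numerical_jacobian(m, s) - M)), 1e-6 * max(abs(M)))
  }

  # f(S) = S^2 at S = 3 -> derivative 6
  sq <- kinetic_model("S", matrix(1, 1, 1), list(quote(S^2)),
                      initial_state = c(S = 3))
  expect_equal(numerical_jacobian(sq, 3)[1, 1], 6, tolerance = 1e-6)

  # mass-action chain: symbolic differentiation oracle
  k1 <- 2; k2 <- 0.7
  J <- numerical_jacobian(chain_abo(k1, k2), c(1.3, 0.4))
  expect_equal(unname(J), matrix(c(-k1, k1, 0, -k2), 2, 2), tolerance = 1e-6)
})

test_that("find_steady_state converges, solves linear systems, flags divergence", {
  # dS/dt = 1 - S -> fixed point at 1
  m <- kinetic_model("S", matrix(c(1, -1), 1, 2),
                     list(quote(1), quote(S)), initial_state = c(S = 0))
  ss <- find_steady_state(m)
  expect_true(ss$converged)
  expect_equal(unname(ss$state), 1, tolerance = 1e-6)

  # stable linear system: steady state is -M^{-1} c (linear-solve oracle)
  m2 <- linear2_model(kin = 2, k1 = 1, k2 = 0.5)
  M <- matrix(c(-1, 1, 0, -0.5), 2, 2)
  expect_equal(unname(find_steady_state(m2)$state),
               as.numeric(solve(M, -c(2, 0))), tolerance = 1e-6)

  # unstable dS/dt = +S never converges and never throws
  bad <- kinetic_model("S", matrix(1, 1, 1), list(quote(S)),
                       initial_state = c(S = 1))
  res <- find_steady_state(bad, max_time = 50)
  expect_false(res$converged)
})

test_that("sparsity pattern follows stoichiometry, reversibility and modifiers", {
  pat <- pattern_from_stoichiometry(chain_ab(reversible = FALSE))
  expect_equal(unname(pat$mask), matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
  expect_equal(pat$p, 2L)

  pat_rev <- pattern_from_stoichiometry(chain_ab(reversible = TRUE))
  expect_true(all(pat_rev$mask))
  expect_equal(pat_rev$p, 4L)

  # modifier adds a column of influence without stoichiometric participation
  m <- kinetic_model(c("A", "B", "E"), matrix(c(-1, 1, 0), 3, 1),
                     list(quote(k * A * E)), c(k = 1),
                     modifiers = list("E"), initial_state = c(1, 1, 1))
  pat_mod <- pattern_from_stoichiometry(m)
  expect_true(all(pat_mod$mask[c(1, 2), 3]))

  # species untouched by any reaction contributes no pattern entries
  m3 <- kinetic_model(c("A", "B", "Z"), matrix(c(-1, 1, 0), 3, 1),
                      list(quote(k * A)), c(k = 1), initial_state = c(1, 0, 1))
  pat3 <- pattern_from_stoichiometry(m3)
  expect_false(any(pat3$mask[3, ]))
  expect_false(any(pat3$mask[, 3]))
})

test_that("pattern index_map is row-major and round-trips with devectorize", {
  mask <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2)
  pat <- jacobian_pattern(mask)
  expect_equal(pat$index_map[, "row"], c(1L, 1L, 2L))
  expect_equal(pat$index_map[, "col"], c(1L, 2L, 2L))
  J <- matrix(c(5, 0, 7, -3), 2, 2)
  expect_equal(devectorize(vectorize_jacobian(J, pat), pat), J * (mask != 0),
               ignore_attr = TRUE)
})

test_that("stoichiometric pattern is a superset of the true Jacobian support", {
  for (s in 1:10) {
    n <- 3 + (s %% 6)
    m <- make_random_mass_action_network(n, density = 0.35, seed = s)
    ss <- attr(m, "steady_state")
    J <- numerical_jacobian(m, ss$state)
    pat <- pattern_from_stoichiometry(m)
    expect_lt(max(abs(J[!pat$mask])), 1e-8)
  }
})

test_that("stiffness ratio measures the spread of non-zero Jacobian entries", {
  J <- matrix(c(-1, 0, 2, -4), 2, 2)
  pat <- jacobian_pattern(J != 0)
  expect_equal(stiffness_ratio(J, pat), 4)
  # degenerate: all equal magnitudes
  expect_equal(stiffness_ratio(matrix(c(-2, 2, 2, -2), 2, 2)), 1)
  # invariant under non-zero rescaling
  expect_equal(stiffness_ratio(-0.037 * J, pat), 4)
  expect_error(stiffness_ratio(matrix(0, 2, 2)), "zero")
})

test_that("random mass-action networks are seeded, stable and overdetermined", {
  m1 <- make_random_mass_action_network(5, density = 0.3, seed = 1)
  m2 <- make_random_mass_action_network(5, density = 0.3, seed = 1)
  expect_identical(m1$stoichiometry, m2$stoichiometry)
  expect_identical(m1$parameters, m2$parameters)

  for (s in c(2, 5, 9)) {
    m <- make_random_mass_action_network(6, density = 0.4, seed = s)
    ss <- attr(m, "steady_state")
    expect_true(ss$converged)
    J <- numerical_jacobian(m, ss$state)
    expect_lt(max(Re(eigen(J, only.values = TRUE)$values)), 0)
    expect_lte(pattern_from_stoichiometry(m)$p, 6 * 7 / 2)
  }
})
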