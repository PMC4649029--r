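test_that("covariance subsampling: identity at fraction 1, larger drift for smaller subsets", {
  set.seed(10)
  X <- matrix(rnorm(400 * 4), 400, 4) %*% matrix(c(1, 0.5, 0, 0,
                                                   0, 1, 0.3, 0,
                                                   0, 0, 1, 0.2,
                                                   0, 0, 0, 1), 4, 4)
  ps1 <- perturb_covariance_subsample(X, fractions = 1, repeats = 3, seed = 1)
  expect_true(all(ps1$levels == 0))
  expect_identical(ps1$perturbed[[1]]$C, ps1$reference$C)

  # law of large numbers: smaller subsets wander further from C0
  ps <- perturb_covariance_subsample(X, fractions = c(0.9, 0.5), repeats = 100,
                                     seed = 2)
  expect_gt(mean(ps$levels[ps$fraction == 0.5]),
            mean(ps$levels[ps$fraction == 0.9]))

  # determinism under a fixed seed
  ps_a <- perturb_covariance_subsample(X, fractions = 0.3, repeats = 5, seed = 7)
  ps_b <- perturb_covariance_subsample(X, fractions = 0.3, repeats = 5, seed = 7)
  expect_identical(ps_a$levels, ps_b$levels)
  expect_identical(ps_a$perturbed[[3]]$C, ps_b$perturbed[[3]]$C)

  expect_error(perturb_covariance_subsample(X[1:10, ], fractions = 0.1),
               "fewer than 3")
})

test_that("fluctuation perturbation scales with sigma and fills off-diagonals", {
  D0 <- fluctuation_spec(diag(c(1, 2, 0.5)))
  p0 <- perturb_fluctuation(D0, sigma = 0, repeats = 2, seed = 1)
  expect_equal(p0$levels, c(0, 0))
  expect_equal(p0$perturbed[[1]]$D, D0$D)

  # mean delta-D grows with sigma and tracks sigma * sqrt(n)
  means <- vapply(c(0.01, 0.1, 1), function(s) {
    mean(perturb_fluctuation(D0, s, repeats = 200, seed = 3)$levels)
  }, 0)
  expect_true(all(diff(means) > 0))
  expect_equal(means, c(0.01, 0.1, 1) * sqrt(3), tolerance = 0.15)

  # sigma = 1: the matrix is effectively fully randomized, with off-diagonal
  # entries of the same order as the diagonal
  p1 <- perturb_fluctuation(D0, sigma = 1, repeats = 1, seed = 4)
  Dp <- p1$perturbed[[1]]$D
  off <- abs(Dp[row(Dp) != col(Dp)])
  expect_gt(max(off), 0.3 * max(abs(diag(Dp))))
  expect_false(p1$perturbed[[1]]$is_diagonal)
})

test_that("jacobian R^2 matches the textbook regression formula", {
  m <- make_random_mass_action_network(6, density = 0.4, seed = 13)
  ss <- attr(m, "steady_state")
  J0 <- numerical_jacobian(m, ss$state)
  pat <- pattern_from_stoichiometry(m)

  exact <- jacobian_r2(J0, J0, pat)
  expect_equal(exact$r_squared, 1)
  expect_equal(exact$slope, 1)
  expect_equal(exact$intercept, 0, tolerance = 1e-12)

  prop <- jacobian_r2(J0, 2 * J0, pat)
  expect_equal(prop$r_squared, 1)
  expect_equal(prop$slope, 2)

  # independent R^2 = 1 - SS_res / SS_tot computation
  set.seed(14)
  noise <- devectorize(rnorm(pat$p, sd = 0.1), pat)
  Je <- J0 + noise
  got <- jacobian_r2(J0, Je, pat)
  xt <- J0[pat$index_map]; xe <- Je[pat$index_map]
  beta <- cov(xt, xe) / var(xt)
  alpha <- mean(xe) - beta * mean(xt)
  ss_res <- sum((xe - alpha - beta * xt)^2)
  ss_tot <- sum((xe - mean(xe))^2)
  expect_equal(got$r_squared, 1 - ss_res / ss_tot, tolerance = 1e-12)
  expect_equal(got$slope, beta, tolerance = 1e-12)

  tiny <- jacobian_pattern(matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2))
  expect_error(jacobian_r2(diag(2), diag(2), tiny), "3")
})

test_that("Mann-Whitney comparison covers exact, degenerate and shifted cases", {
  same <- compare_methods(c(1, 1, 1), c(1, 1, 1))
  expect_true(same$degenerate)
  expect_gte(same$p_value, 0.99)

  # complete separation of two samples of 3: U = 0, exact two-sided p = 0.1
  sep <- compare_methods(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(sep$U_statistic), 0)
  expect_equal(sep$p_value, 0.1)

  # p decreases as the distribution shift grows
  set.seed(15)
  a <- rnorm(100)
  ps <- vapply(c(0.1, 0.4, 0.8), function(sh) {
    compare_methods(a, a + sh)$p_value
  }, 0)
  expect_true(all(diff(ps) < 0))
})

test_that("benchmark grid has full factorial shape, determinism and exact recovery", {
  m <- make_random_mass_action_network(5, density = 0.3, seed = 17)
  rec <- run_benchmark_grid(m, cov_fractions = 1, sigma_levels = c(0, 0.1),
                            methods = c("ols", "tsvd"), repeats = 3, seed = 5,
                            use_analytic_C0 = TRUE)
  expect_equal(nrow(rec), 1 * 2 * 2 * 3)
  expect_true(all(is.na(rec$error)))

  # noiseless cell: exact-recovery regime
  clean <- rec[rec$sigma == 0 & rec$method == "ols", ]
  expect_gte(mean(clean$r_squared), 0.999)
  expect_equal(clean$delta_C, rep(0, 3))

  rec2 <- run_benchmark_grid(m, cov_fractions = 1, sigma_levels = c(0, 0.1),
                             methods = c("ols", "tsvd"), repeats = 3, seed = 5,
                             use_analytic_C0 = TRUE)
  expect_identical(rec, rec2)
})

test_that("benchmark grid with sampled covariance records perturbation levels", {
  m <- make_random_mass_action_network(4, density = 0.4, seed = 19)
  rec <- run_benchmark_grid(m, cov_fractions = c(1, 0.2), sigma_levels = 0.01,
                            methods = "tsvd", repeats = 4, seed = 6, N = 150)
  expect_equal(nrow(rec), 2 * 1 * 1 * 4)
  expect_true(all(rec$delta_C[rec$fraction == 0.2] > 0))
  expect_true(all(rec$delta_D > 0))
  expect_true(all(rec$kappa_A >= 1))
  s <- summarize_benchmark(rec)
  expect_equal(nrow(s), 2)
  expect_true(all(s$n_records == 4))
  M <- benchmark_grid_summary(rec, "tsvd", bins = 2)
  expect_true(all(dim(M) >= 1))
})

test_that("small and moderate fluctuation perturbations barely move the median accuracy", {
  # matched perturbation scales: sigma chosen so the realized delta-D sits at
  # about 2% and 20%; a fully randomized D (sigma = 1) is the contrast case
  m <- make_random_mass_action_network(5, density = 0.3, seed = 17)
  rec <- run_benchmark_grid(m, cov_fractions = 1,
                            sigma_levels = c(0.01, 0.2 / sqrt(5), 1),
                            methods = "tsvd", repeats = 30, seed = 31, N = 800)
  s <- summarize_benchmark(rec)
  expect_equal(s$mean_delta_D[2], 0.2, tolerance = 0.15)
  expect_lt(abs(s$median_r2[1] - s$median_r2[2]), 0.05)
  expect_gt(s$median_r2[1] - s$median_r2[3], 0.2)
})
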