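# jacinv — inverse Jacobian estimation from metabolomics covariance data

Metabolomics experiments measure many metabolites over many biological
replicates. The replicate-to-replicate covariance of those concentrations is
not noise to be averaged away: for a metabolic network fluctuating around a
stable steady state, the stationary covariance `C`, the network Jacobian `J`
(the matrix of sensitivities ∂f_i/∂S_j, in units of inverse time), and the
fluctuation matrix `D` are tied together by the continuous Lyapunov equation

```
J C + C Jᵀ = −2 D
```

`jacinv` inverts this relation: given a covariance matrix estimated from
data, an assumed fluctuation matrix, and the Jacobian sparsity pattern fixed
by network stoichiometry (plus reaction reversibility and known allosteric
modifiers), it reconstructs the Jacobian by rewriting the Lyapunov equation
as an overdetermined linear system `A x = b` in the p structurally non-zero
Jacobian entries, and solving that ill-posed system with any of four
methods:

* ordinary least squares (OLS),
* truncated SVD (TSVD),
* truncated total least squares (TTLS, errors-in-variables),
* Tikhonov/ridge regularization with L-curve or cross-validation selection
  of λ.

The package is aimed at systems biologists who want to infer reaction-level
regulation directly from observational metabolomics variation, and at anyone
studying how ill-posed linear inverse problems respond to structured
perturbations. Beyond the solvers it provides the full in-silico laboratory
used to validate them: kinetic-model handling (SBML import, steady states,
numerical Jacobians, stoichiometric sparsity patterns), a seeded generator of
random stable mass-action networks, a Langevin (Euler–Maruyama) ensemble
simulator that produces covariance data consistent with the Lyapunov
relation, and a benchmarking protocol that degrades `C` (replicate
subsampling) and `D` (multiplicative Gaussian noise) and scores recovered
Jacobians by regression R² against the truth.

## Worked example

Generate a random stable 5-species mass-action network, simulate a
2000-replicate metabolomics ensemble, and recover its Jacobian:

```r
library(jacinv)

model   <- make_random_mass_action_network(5, density = 0.3, seed = 17)
steady  <- attr(model, "steady_state")
J_true  <- numerical_jacobian(model, steady$state)
pattern <- pattern_from_stoichiometry(model)
print(pattern)
#> Jacobian pattern: 5 x 5, p = 11 structural non-zeros (44% dense)
#>   overdetermined linear system: yes (p <= n(n+1)/2 = 15)

D0  <- default_fluctuation(steady)           # diagonal control-condition D
ens <- ensemble_covariance(model, D0, N = 2000, seed = 1, steady = steady)
print(ens$covariance)
#> Covariance estimate: 5 x 5, N = 2000, deltaC = 0, positive definite

fit <- jacobian_fit(ens$covariance, D0, pattern, method = "tsvd")
summary(fit)
#> Inverse Jacobian fit (TSVD): n = 5, p = 11
#>   condition number kappa_A = 20.06, stiffness ratio = 96.5
#>   residual |Ax - b| = 2.614e-05
#> Estimated Jacobian:
#>         S1       S2     S3      S4     S5
#> S1 -5.6500  0.06852  0.000  0.0000  0.000
#> S2  0.0000 -0.52410  2.009  0.0000  0.000
#> S3  0.3416  0.00000 -5.919  0.0000  1.298
#> S4  0.0000  0.00000  0.000 -1.1340  0.000
#> S5  1.7640  0.00000  0.000  0.9294 -6.612

jacobian_r2(J_true, coef(fit, "matrix"), pattern)
#> R^2 = 0.999, slope = 1.004, intercept = -0.0202
```

What the numbers mean: `kappa_A` is the condition number of the linear
system — around 20 here, so the inversion is benign; with noisy or
subsampled covariances it can reach 10^16, and that is when the choice of
solver starts to matter. The recovered entries regress on the true ones with
R² = 0.999 and slope ≈ 1 through the origin, i.e. the 11 structurally
non-zero Jacobian entries are recovered almost exactly from sampled data
alone. Off-pattern entries are exact zeros by construction. `predict(fit)`
forward-solves the fitted Jacobian back to its implied covariance, and
`plot(fit, J_true = J_true)` shows the recovery scatter.

The robustness protocol is one call:

```r
records <- run_benchmark_grid(model,
                              cov_fractions = c(1, 0.5, 0.1),
                              sigma_levels  = c(0.01, 0.1, 1),
                              repeats = 100, seed = 1, N = 2000)
summarize_benchmark(records)     # mean/SD/median R^2 per grid cell
```

A command-line interface (`inst/cli/jacinv`, or `jacinv_cli()` in R) exposes
`simulate`, `invert`, `benchmark` (YAML-configured) and `report`
subcommands; every run writes a `manifest.json` from which its outputs are
bit-reproducible.

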