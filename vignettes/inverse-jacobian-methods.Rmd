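---
title: "Inverse Jacobian estimation from metabolomics covariance: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverse Jacobian estimation from metabolomics covariance: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A metabolic reaction network with species concentrations
$S = (S_1, \dots, S_n)$ evolves as $dS/dt = f(S)$, where $f$ collects the
stoichiometry-weighted reaction rates. Around a stable steady state $S^*$ the
local regulatory structure is captured by the Jacobian
$J_{ij} = \partial f_i / \partial S_j$ (units of inverse time): which
metabolites accelerate or inhibit the net production of which others.

Biological replicates are not copies of one deterministic state: intrinsic
fluctuations jitter the system around $S^*$. Modelling those fluctuations as
Langevin noise, $dS = f(S)\,dt + B\,dW$ with diffusion strength
$B B^\top = 2D$, and linearizing around $S^*$, the stationary covariance $C$
of the observed concentrations obeys the continuous Lyapunov equation

$$ J C + C J^\top = -2D. $$

This identity is the engine of the package, in both directions:

* **forward** (`solve_lyapunov_forward()`): given $J$ and $D$, the implied
  covariance — an analytic oracle for simulated data;
* **inverse** (`jacobian_fit()`): given a measured covariance $C$ and an
  assumed fluctuation matrix $D$, recover $J$.

The inverse direction is the scientifically interesting one: $C$ is exactly
what a metabolomics experiment with many biological replicates estimates.

### Why sparsity makes the problem solvable

$C$ is symmetric, so the Lyapunov equation carries $n(n+1)/2$ independent
scalar equations, while a free $J$ has $n^2$ unknowns: underdetermined. But
most Jacobian entries are structural zeros. $J_{ij}$ can only be non-zero if
some reaction that changes species $i$ has a rate influenced by species $j$ —
$j$ is a reactant, a product of a reversible reaction, or a declared modifier
(allosteric regulation is invisible to stoichiometry and must be supplied as
`modifiers`). `pattern_from_stoichiometry()` derives this mask; with
$p \le n(n+1)/2$ free entries the system becomes overdetermined.

Vectorizing the $p$ free entries in a fixed row-major order (the single
source of truth held in the pattern's `index_map` and reused by every
downstream function, preventing silent transposition bugs),
`build_linear_system()` rewrites the Lyapunov equation as $A x = b$: equation
rows are all $n^2$ ordered pairs $(i,k)$; the coefficient of unknown
$J_{a,b}$ in row $(i,k)$ is $[a{=}i]\,C_{b,k} + [a{=}k]\,C_{i,b}$, and
$b_{(i,k)} = -2 D_{i,k}$. All $n^2$ rows are kept by default, so each
off-diagonal equation appears twice; this weights off-diagonal information
twice in least squares, which we document rather than hide (`collapse = TRUE`
keeps the $n(n+1)/2$ unique rows instead). The condition number
$\kappa_A = \sigma_1/\sigma_p$ of $A$ is the central diagnostic: large
$\kappa_A$ means small errors in $C$ or $D$ blow up in the solution.

## The four solvers

All four act on the same `lyap_system` and return the same classed
`jacobian_fit` object (with `print`, `summary`, `coef`, `residuals`,
`predict`, `plot` methods).

* **OLS** (`solve_ols`): the SVD pseudo-inverse solution of
  $\min \|Ax-b\|^2$ — numerically equivalent to the normal equations
  $(A^\top A)^{-1}A^\top b$ on well-conditioned input, but stable. Rank
  deficiency yields the minimum-norm solution with a warning.
* **TSVD** (`solve_tsvd`): discard the $t$ smallest singular triplets of $A$
  before inverting. `truncation = "auto"` counts singular values below
  `rel_threshold` (default `1e-8`, motivated by double-precision rounding)
  times $\sigma_1$.
* **Truncated TLS** (`solve_ttls`): the errors-in-variables solver. Since $A$
  is built from the *estimated* covariance, $A$ itself is noisy;
  TTLS minimizes the joint perturbation $\|[\delta A\,|\,\delta b]\|$ subject
  to $(A+\delta A)x = b+\delta b$, via the SVD of $[A\,|\,b]$ truncated to
  rank $p-t$ and the closed form $x = -V_{12}V_{22}^{+}$. In auto mode the
  truncation count deliberately ignores the $(p{+}1)$-th singular value,
  which is structurally tiny whenever $b$ is near-consistent with $A$.
* **Tikhonov/ridge** (`solve_tikhonov`): $\min \|Ax-b\|^2 +
  \lambda\|x-x_0\|_2^2$, solved through the augmented stack
  $[A;\sqrt\lambda I]$. The penalty convention is $\lambda$ (not
  $\lambda^2$) on the squared norm; the prior $x_0$ defaults to zeros.
  Shrinkage penalties (L1/elastic net) are deliberately absent: the zero
  entries of $J$ are already fixed by stoichiometry, so sparsifying further
  entries would fight the structural prior rather than help it.

### Choosing $\lambda$ and $t$

`select_lambda()` offers the two standard rules over a common log-spaced
grid of 30 candidates:

* **L-curve** (default in the benchmark): pick the $\lambda$ of maximal
  discrete curvature of (log residual norm, log solution norm) along the
  grid, with finite-difference curvature (no spline) and ties broken toward
  smaller $\lambda$ — deterministic and reproducible. As a structural
  precondition the residual norm must be non-decreasing and the solution
  distance non-increasing along the grid; violations are flagged.
* **row-fold cross-validation**: minimize the mean held-out equation
  residual over $k = 5$ seeded folds. A caveat discovered during
  development and worth stating plainly: when the dominant noise lives in
  $A$ (covariance sampling error) rather than in $b$, every fold shares the
  same corrupted $A$, and held-out prediction error keeps improving with
  shrinkage even as parameter accuracy degrades — CV then selects far too
  much regularization. It is kept because it is the standard tool and
  behaves correctly when the error is in $b$, but the L-curve is the
  default.

The default grid spans $[\min(\sigma_p^2,\ \sigma_1^2 \cdot 10^{-12}),\
\sigma_1^2]$. The lower end matters: for a *well-conditioned* $A$
(\(\kappa_A \sim 10^2\)–\(10^4\), the regime of a small mass-action network)
the optimal $\lambda$ lies far below $\sigma_p^2$, and a grid floored at
$\sigma_p^2$ forces over-regularization everywhere.

## The in-silico data generator

`ensemble_covariance()` emulates the experiment: $N$ independent
Euler–Maruyama realizations started at $S^*$, integrated for a burn-in
period, one end-point sample per realization (the analogue of $N$ biological
replicates, rather than time-averaging a single trajectory), covariance with
the unbiased $N-1$ denominator, symmetrized exactly.

Numerical choices, all config-exposed:

* **Noise scaling** $B B^\top = 2D$: the unique convention under which the
  linearized stationary covariance satisfies $JC + CJ^\top = -2D$ exactly, so
  the simulated data and the inverse machinery agree by construction.
* **Step size** `dt = 0.01 / max|Re eig J|` (capped at 0.01) resolves the
  fastest linear timescale; **burn-in** `10 / min|Re eig J|` lets the slowest
  mode equilibrate to within $e^{-10}$.
* **Non-negativity**: concentrations are clipped at zero and the clip count
  is reported; frequent clipping means the noise has left the linear-response
  regime, invalidating the Lyapunov relation, and should prompt a smaller
  fluctuation scale.
* **Control fluctuation matrix** `default_fluctuation()`: diagonal (no
  fluctuation cross-talk in the control condition) with scale
  $(\rho\tilde S)^2$, $\rho = 0.05$, $\tilde S$ the geometric mean
  steady-state concentration. The *uniform* scale is a deliberate design
  choice: because the Lyapunov relation is linear in $D$, the overall scale
  of a uniform $D_0$ cancels from the inverse problem, and multiplicative
  perturbations $(I+E)D_0$ then degrade all equations evenly. The
  alternative `type = "proportional"` ($D_{0,ii} = (\rho S_i^*)^2$) is kept
  for studying heterogeneous-fluctuation scenarios, but when steady states
  span several decades it makes the weakest equations drown in
  perturbations of the strongest, and the robustness of the inversion to
  small $D$-uncertainty — which homogeneous fluctuations exhibit — is lost.

### The synthetic network generator

`make_random_mass_action_network()` produces the ground-truth models: a
connected backbone of uni-molecular conversions plus extra random edges (a
fraction realized as bi-molecular condensations), constant influx into a
subset of species, and first-order dilution on every species. The dilution
terms exchange mass with fixed external pools and make the steady-state
Jacobian strictly diagonally dominant in the uni-molecular case, so
stability is generic; candidates are still verified (converged positive
steady state, all eigenvalues in the left half-plane, $p \le n(n+1)/2$) and
redrawn up to a budget. Rate constants are log-uniform over
$[10^{-1}, 10^{1}]$: realistic timescale separation without extreme
stiffness.

What this emulates well: sparse stable mass-action networks with a known
Jacobian, moderate stiffness (ratios of $10^2$–$10^3$ between the largest
and smallest Jacobian entries), and ensemble-sampled stationary covariance.
What it does *not* emulate: measurement error and missing values in real
metabolomics data (only sampling error is present), saturating
Michaelis–Menten kinetics (supported via SBML import but not generated
randomly), errors in the assumed sparsity pattern, and non-stationary or
oscillatory dynamics. Passing tests therefore demonstrate the correctness
and perturbation behavior of the *inversion machinery*, not that any real
dataset will yield an accurate Jacobian.

## The benchmarking protocol

`run_benchmark_grid()` degrades the data in the two ways an experimenter
actually fears and measures the damage:

* **Covariance perturbation** by subsampling: covariance from a random
  subset of the $N$ replicates, $\delta C = \|C_i - C_0\|_F / \|C_0\|_F$
  recorded per draw. Subsampled covariances are used as-is, including
  non-positive-definite ones — losing positive definiteness is exactly what
  drives $\kappa_A$ up in practice, and repairing it would mask the effect
  (a flag records it; norms are Frobenius throughout).
* **Fluctuation perturbation**: $D_i = (I+E)D_0$ with i.i.d.
  $E_{jk} \sim N(0, \sigma^2)$, a *full* matrix, so off-diagonals populate;
  the realized $\delta D \approx \sigma\sqrt{n}$ is recorded. At
  $\sigma = 1$, $D_i$ is effectively fully randomized. No symmetrization by
  default.

Accuracy is scored by `jacobian_r2()`: ordinary regression (with intercept)
of estimated on true pattern entries. The intercept is retained so a
constant offset — which would make entries trend together without being
comparable — stays visible; slope near 1 and intercept near 0 justify
reading $R^2$ as recovery quality. Method comparisons use the two-sided
Mann–Whitney U test (`compare_methods()`, exact for small untied samples).
Heat-map summaries bin the realized $\delta C$ and $\delta D$ by empirical
percentile rank within the run (raw $\delta$ distributions are heavily
skewed); the median raw $\delta$ per bin is attached so the axes remain
interpretable.

Every cell derives its RNG seed deterministically from (master seed,
fraction index, sigma index, repeat), so single records are reproducible in
isolation and the whole grid is bit-reproducible; solver failures are
recorded as failed rows, never aborting the grid.

### Study sizes

The bundled acceptance analysis (`scripts/acceptance.R`) uses: 50 random
networks with $n$ cycling over 3–12 for the noiseless exact-recovery check; a
frozen well-conditioned $n = 8$ benchmark model (chosen by its low
$\kappa_A$, the regime in which the inversion is informative, from a small
seed survey — selection by an input property of the instance, fixed before
any benchmarking); $N = 2000$ ensemble members; subsample fractions
$\{1, 0.5, 0.1, 0.03, 0.01\}$, which realize mean $\delta C$ from 0 to about
50%; noise levels $\sigma \in \{0.01, 0.1, 1\}$; 100 repeats per cell. These
sizes give standard errors well below the effects being measured while the
whole analysis completes in about a minute.

## Numerical details worth knowing

* The forward Lyapunov solve reduces $J$ to real Schur form and
  back-substitutes column-block by column-block (quasi-triangular blocks of
  size 1 and 2), followed by up to three iterative-refinement correction
  solves; the relative residual is verified against $10^{-10}$ and the
  brute-force Kronecker solve ($O(n^6)$ memory) is reserved for the test
  suite as an independent oracle.
* Unstable $J$ (any eigenvalue with non-negative real part) is an error in
  the forward direction: no stationary covariance exists.
* `condition_number()` returns `Inf` once $\sigma_{\min} <
  \sigma_1 \cdot 10^{-300}$, keeping log-scale plots finite.
* `numerical_jacobian()` uses central differences with step
  $\max(\text{rel\_step}\,|S_j|,\ \text{floor})$, `rel_step = 1e-6`,
  absolute floor `1e-8`, so zero concentrations are handled.
* Steady states come from stiff-capable `deSolve::lsoda` integration over
  geometrically growing horizons until $\max|dS/dt| \le$ `tol` (default
  `1e-9`); divergence produces a non-converged result, never an exception.
* Degenerate inputs: $D = 0$ makes the relative Lyapunov residual
  undefined, so the unnormalized residual is returned with a flag; an all
  identical Mann–Whitney comparison returns $p = 1$ with a degeneracy flag;
  a single-candidate $\lambda$ grid is returned with a warning.

## Limitations

* The Lyapunov relation holds for the *linearized* dynamics; strongly
  nonlinear fluctuations (large $\rho$, frequent zero-clipping) bias $C$
  away from the linear prediction and the inversion inherits that bias.
* The sparsity pattern is assumed correct. Missing modifier annotations
  remove true unknowns from the fit (bias); spurious ones enlarge $p$ and can
  destroy overdeterminacy, as the bundled three-species SBML example shows
  ($p = 7 > n(n+1)/2 = 6$).
* SBML support covers the arithmetic MathML subset with reaction-local
  parameters, boundary species, and compartment sizes; function definitions,
  assignment rules, events and piecewise kinetics fail loudly by design.
* Stiff models (Jacobian entries spanning many decades) degrade both the
  inversion and the meaningfulness of entry-wise $R^2$, which large entries
  dominate; the stiffness ratio is reported so this regime is recognizable.
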