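#' Fluctuation matrix specification
#'
#' Wraps the diffusion-strength matrix D of the Langevin model
#' \eqn{dS = f(S)\,dt + B\,dW} with \eqn{B B^T = 2D}, together with
#' provenance: the multiplicative-noise level sigma it was generated with
#' (0 for the unperturbed control matrix D0) and its relative Frobenius
#' distance from D0. In the control condition D is diagonal with non-negative
#' entries — no fluctuation cross-talk between metabolites.
#'
#' @param D n x n numeric matrix (or a vector, taken as the diagonal).
#' @param sigma_level noise level used to generate this D (0 for D0).
#' @param delta_D relative Frobenius change versus D0 (0 for D0).
#' @param labels optional species labels.
#' @return An object of class `fluctuation_spec`.
#' @export
fluctuation_spec <- function(D, sigma_level = 0, delta_D = 0, labels = NULL) {
  if (!is.matrix(D)) D <- diag(as.numeric(D), nrow = length(D))
  stop_if_not_square(D, "D")
  if (any(!is.finite(D))) stop("D contains non-finite entries")
  if (sigma_level == 0) {
    offdiag <- D; diag(offdiag) <- 0
    if (any(offdiag != 0) || any(diag(D) < 0)) {
      stop("the control fluctuation matrix D0 must be diagonal with non-negative diagonal")
    }
  }
  if (!is.null(labels)) dimnames(D) <- list(labels, labels)
  structure(list(D = D, is_diagonal = all(D[row(D) != col(D)] == 0),
                 sigma_level = sigma_level, delta_D = delta_D),
            class = "fluctuation_spec")
}

#' @export
print.fluctuation_spec <- function(x, ...) {
  cat(sprintf("Fluctuation matrix: %d x %d, %s, sigma = %g, deltaD = %.3g\n",
              nrow(x$D), ncol(x$D),
              if (x$is_diagonal) "diagonal" else "full", x$sigma_level, x$delta_D))
  invisible(x)
}

#' Default control-condition fluctuation matrix
#'
#' The unperturbed D0 is diagonal — metabolites fluctuate independently in
#' the control condition. Two scaling rules are offered:
#'
#' * `"uniform"` (default): \eqn{D_0 = (\rho \tilde S)^2 I} with
#'   \eqn{\tilde S} the geometric mean of the steady-state concentrations.
#'   All metabolites receive the same fluctuation strength, a fixed fraction
#'   of the typical concentration. Because the Lyapunov relation is linear in
#'   D, the overall scale of a uniform D0 cancels from the inverse problem,
#'   and multiplicative perturbations of D degrade every equation of the
#'   linear system evenly.
#' * `"proportional"`: \eqn{D_{0,ii} = (\rho S^*_i)^2}, a fixed relative
#'   fluctuation per metabolite. When steady-state concentrations span
#'   several decades this makes the fluctuation equations correspondingly
#'   heterogeneous, and small multiplicative perturbations of D then swamp
#'   the weakest equations — useful for studying that failure mode, but not
#'   a robust control condition.
#'
#' Either way \eqn{\rho} is small so the stochastic excursions stay inside
#' the linear-response regime in which the Lyapunov relation between J, C and
#' D holds.
#'
#' @param state steady-state concentrations (a numeric vector or a
#'   `steady_state` object).
#' @param rho relative fluctuation scale (default 0.05).
#' @param type `"uniform"` (default) or `"proportional"`, see above.
#' @return A [fluctuation_spec] with `sigma_level = 0`.
#' @export
default_fluctuation <- function(state, rho = 0.05,
                                type = c("uniform", "proportional")) {
  type <- match.arg(type)
  if (inherits(state, "steady_state")) state <- state$state
  s <- as.numeric(state)
  d <- if (type == "uniform") {
    rep((rho * exp(mean(log(pmax(s, .Machine$double.xmin)))))^2, length(s))
  } else {
    (rho * s)^2
  }
  fluctuation_spec(diag(d, nrow = length(s)), labels = names(state))
}

#' @noRd
as_D_matrix <- function(D) {
  if (inherits(D, "fluctuation_spec")) D$D else as.matrix(D)
}

# Core Euler-Maruyama stepper, vectorised over an ensemble: `state` is an
# N x n matrix advanced in place over n_steps. Negative excursions are clipped
# at zero (concentrations are non-negative); the clip count is returned so
# callers can detect when the linear-noise regime is being left.
#' @noRd
em_steps <- function(model, state, B, dt, n_steps, record = FALSE,
                     diverge_bound = 1e8, clip_negative = TRUE) {
  N <- nrow(state); n <- ncol(state)
  sqdt <- sqrt(dt)
  clipped <- 0L
  traj <- if (record) matrix(NA_real_, n_steps + 1L, n) else NULL
  if (record) traj[1L, ] <- state[1L, ]
  alive <- rep(TRUE, N)
  for (s in seq_len(n_steps)) {
    drift <- ode_rhs(model, state)
    noise <- matrix(stats::rnorm(N * n), N, n) %*% t(B)
    state <- state + drift * dt + noise * sqdt
    if (clip_negative) {
      neg <- state < 0
      if (any(neg)) { clipped <- clipped + sum(neg); state[neg] <- 0 }
    }
    bad <- !is.finite(state) | abs(state) > diverge_bound
    if (any(bad)) {
      rows <- unique(which(bad, arr.ind = TRUE)[, 1])
      alive[rows] <- FALSE
      state[rows, ] <- 1  # parked at a benign value; excluded by caller
      if (record && !alive[1L]) {
        stop(sprintf("SDE trajectory diverged at t = %.4g", s * dt))
      }
    }
    if (record) traj[s + 1L, ] <- state[1L, ]
  }
  list(state = state, clipped = clipped, traj = traj, alive = alive)
}

#' Simulate one Langevin trajectory of a kinetic model
#'
#' Euler-Maruyama integration of \eqn{dS = f(S)\,dt + B\,dW} with
#' \eqn{B B^T = 2D}. The 2D scaling is what makes the stationary covariance of
#' the linearized system satisfy the Lyapunov equation
#' \eqn{J C + C J^T = -2D}. Concentrations are clipped at zero; the number of
#' clipped increments is attached as an attribute (frequent clipping signals
#' that the noise is too strong for the linear approximation).
#'
#' @param model a [kinetic_model].
#' @param D a [fluctuation_spec] or symmetric PSD matrix.
#' @param start starting concentrations (default: the model's initial state).
#' @param t_end end time (> 0).
#' @param dt Euler-Maruyama step.
#' @param seed integer seed; identical calls are bit-identical.
#' @param clip_negative clip negative excursions at zero (default TRUE; set
#'   FALSE for linear toy systems whose state is not a concentration).
#' @return A (steps + 1) x n matrix of concentrations with a `time` attribute;
#'   attribute `clipped` counts zero-clipped entries.
#' @export
simulate_sde <- function(model, D, start = model$initial_state, t_end, dt,
                         seed = 1, clip_negative = TRUE) {
  stopifnot(dt > 0, t_end >= dt)
  Dm <- as_D_matrix(D)
  n <- length(model$species_ids)
  stop_if_not_square(Dm, "D")
  if (nrow(Dm) != n) stop("D dimension does not match the model")
  B <- psd_factor(2 * Dm)
  n_steps <- ceiling(t_end / dt)
  set.seed(derive_seed(seed, 7L))
  out <- em_steps(model, matrix(as.numeric(start), 1, n), B, dt, n_steps,
                  record = TRUE, clip_negative = clip_negative)
  traj <- out$traj
  colnames(traj) <- model$species_ids
  attr(traj, "time") <- seq(0, by = dt, length.out = n_steps + 1L)
  attr(traj, "clipped") <- out$clipped
  traj
}

#' Heuristic SDE step size and burn-in from the Jacobian timescales
#'
#' dt resolves the fastest linear timescale (0.01 / max |Re eig J|, capped);
#' burn-in covers ten times the slowest (10 / min |Re eig J|).
#'
#' @param J Jacobian at the steady state.
#' @param dt_cap upper bound on dt (default 0.01).
#' @return list with `dt` and `burn_in`.
#' @export
sde_timescales <- function(J, dt_cap = 0.01) {
  re <- abs(Re(eigen(as.matrix(J), only.values = TRUE)$values))
  re <- re[re > 0]
  if (length(re) == 0L) stop("Jacobian has no decaying modes")
  list(dt = min(0.01 / max(re), dt_cap), burn_in = 10 / min(re))
}

#' Ensemble estimate of the stationary metabolomics covariance
#'
#' Runs N independent Langevin realizations from the steady state for
#' `burn_in` time units and estimates the stationary covariance C0 from the N
#' end-point concentration vectors (one sample per realization, the in-silico
#' analogue of N independent biological replicates), using the unbiased N-1
#' denominator. The result is symmetrized exactly. Realizations that diverge
#' are excluded and counted; more than 10% divergence is an error.
#'
#' @param model a [kinetic_model] with a converged steady state.
#' @param D a [fluctuation_spec] or matrix.
#' @param N ensemble size (>= 2).
#' @param burn_in equilibration time; defaults via [sde_timescales()].
#' @param dt Euler-Maruyama step; defaults via [sde_timescales()].
#' @param seed integer master seed.
#' @param steady optional precomputed `steady_state` (found if missing).
#' @param clip_negative clip negative excursions at zero (default TRUE).
#' @return list with `samples` (an `ensemble_samples` object: N x n matrix
#'   plus provenance) and `covariance` (a `covariance_estimate`).
#' @export
ensemble_covariance <- function(model, D, N, burn_in = NULL, dt = NULL,
                                seed = 1, steady = NULL, clip_negative = TRUE) {
  stopifnot(N >= 2)
  if (is.null(steady)) steady <- find_steady_state(model)
  if (!steady$converged) stop("model has no converged steady state")
  if (is.null(dt) || is.null(burn_in)) {
    ts <- sde_timescales(numerical_jacobian(model, steady$state))
    if (is.null(dt)) dt <- ts$dt
    if (is.null(burn_in)) burn_in <- ts$burn_in
  }
  Dm <- as_D_matrix(D)
  n <- length(model$species_ids)
  B <- psd_factor(2 * Dm)
  n_steps <- ceiling(burn_in / dt)
  set.seed(derive_seed(seed, 11L))
  state0 <- matrix(rep(as.numeric(steady$state), each = N), N, n)
  out <- em_steps(model, state0, B, dt, n_steps, clip_negative = clip_negative)
  n_diverged <- sum(!out$alive)
  if (n_diverged > 0.1 * N) {
    stop(sprintf("%d of %d SDE realizations diverged", n_diverged, N))
  }
  samples <- out$state[out$alive, , drop = FALSE]
  colnames(samples) <- model$species_ids
  es <- structure(list(samples = samples, N = nrow(samples),
                       model_id = model$id, seed = seed,
                       burn_in_time = burn_in, dt = dt,
                       n_diverged = n_diverged, clipped = out$clipped),
                  class = "ensemble_samples")
  ce <- covariance_estimate(stats::cov(samples), N_used = nrow(samples))
  list(samples = es, covariance = ce)
}

#' @export
print.ensemble_samples <- function(x, ...) {
  cat(sprintf("Ensemble samples: N = %d end-points of %d species (burn-in %.3g, dt %.3g)\n",
              x$N, ncol(x$samples), x$burn_in_time, x$dt))
  if (x$n_diverged > 0) cat(sprintf("  %d diverged realizations excluded\n", x$n_diverged))
  invisible(x)
}

#' Covariance estimate container
#'
#' Stores a symmetric covariance matrix together with the number of samples it
#' was estimated from, its relative Frobenius distance from a reference C0
#' (0 for C0 itself), and whether it is positive definite. The matrix is
#' symmetrized exactly on construction.
#'
#' @param C n x n numeric matrix.
#' @param N_used number of samples behind the estimate (NA if analytic).
#' @param delta_C relative Frobenius change versus the reference C0.
#' @return An object of class `covariance_estimate`.
#' @export
covariance_estimate <- function(C, N_used = NA_integer_, delta_C = 0) {
  C <- symmetrize(as.matrix(C))
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  structure(list(C = C, N_used = N_used, delta_C = delta_C,
                 positive_definite = all(ev > 0)),
            class = "covariance_estimate")
}

#' @export
print.covariance_estimate <- function(x, ...) {
  cat(sprintf("Covariance estimate: %d x %d, N = %s, deltaC = %.3g, %spositive definite\n",
              nrow(x$C), ncol(x$C),
              if (is.na(x$N_used)) "analytic" else as.character(x$N_used),
              x$delta_C, if (x$positive_definite) "" else "NOT "))
  invisible(x)
}

#' @noRd
as_C_matrix <- function(C) {
  if (inherits(C, "covariance_estimate")) C$C else as.matrix(C)
}

#' Simulate method for kinetic models
#'
#' `simulate()` on a [kinetic_model] draws `nsim` independent Langevin
#' end-point samples after equilibration — the same sampling scheme as
#' [ensemble_covariance()] — and returns the sample matrix.
#'
#' @param object a [kinetic_model].
#' @param nsim number of realizations.
#' @param seed integer seed.
#' @param D fluctuation matrix; defaults to [default_fluctuation()] at the
#'   steady state.
#' @param ... passed to [ensemble_covariance()] (`burn_in`, `dt`, `steady`).
#' @return N x n matrix of sampled concentrations.
#' @export
simulate.kinetic_model <- function(object, nsim = 100, seed = 1, D = NULL, ...) {
  steady <- find_steady_state(object)
  if (is.null(D)) D <- default_fluctuation(steady)
  ensemble_covariance(object, D, N = nsim, seed = seed, steady = steady,
                      ...)$samples$samples
}
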