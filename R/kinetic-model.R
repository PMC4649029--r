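#' Construct a kinetic reaction-network model
#'
#' A `kinetic_model` bundles everything needed to evaluate the deterministic
#' dynamics of a metabolic network, \eqn{dS/dt = N \, v(S)}: the ordered
#' species list, the signed stoichiometric matrix \eqn{N} (species by
#' reactions), and one evaluable rate law per reaction. Rate laws are ordinary
#' R expressions over species identifiers, parameter names, and fixed boundary
#' species; all units are arbitrary (concentration per time).
#'
#' Species held constant by the environment (e.g. external pools, SBML
#' `boundaryCondition` species) are not part of the dynamic state: they are
#' supplied through `boundary` and visible to rate laws as fixed numbers.
#'
#' @param species_ids character vector of n dynamic species identifiers.
#' @param stoichiometry n x r numeric matrix of signed stoichiometric
#'   coefficients (rows = species in `species_ids` order, columns = reactions).
#' @param rates list of r R expressions (or strings parsed as such), one per
#'   reaction, evaluating to the reaction rate.
#' @param parameters named numeric vector of global kinetic parameters.
#' @param reversible logical vector of length r; used when deriving the
#'   Jacobian sparsity pattern (a product of a reversible reaction influences
#'   its rate).
#' @param modifiers list of length r; each element a character vector of
#'   species that regulate the reaction rate without stoichiometric
#'   participation (allosteric effectors, enzymes).
#' @param initial_state named or unnamed non-negative numeric vector of length
#'   n of starting concentrations.
#' @param boundary named numeric vector of fixed boundary-species
#'   concentrations (may be empty).
#' @param local_parameters optional list of length r of named numeric vectors;
#'   reaction-scoped parameters that shadow global ones (as in SBML kinetic
#'   laws).
#' @param compartment_sizes numeric vector of length n of compartment volumes
#'   dividing the stoichiometric flux for each species; defaults to 1.
#' @param id optional model identifier string.
#'
#' @return An object of class `kinetic_model`.
#' @seealso [ode_rhs()], [numerical_jacobian()], [find_steady_state()],
#'   [pattern_from_stoichiometry()], [make_random_mass_action_network()],
#'   [read_sbml_model()]
#' @export
#' @examples
#' # A -> B -> (out), mass action
#' m <- kinetic_model(
#'   species_ids = c("A", "B"),
#'   stoichiometry = matrix(c(-1, 1, 0, -1), 2, 2),
#'   rates = list(quote(k1 * A), quote(k2 * B)),
#'   parameters = c(k1 = 2, k2 = 1),
#'   initial_state = c(A = 3, B = 0)
#' )
#' ode_rhs(m, c(3, 0))
kinetic_model <- function(species_ids, stoichiometry, rates, parameters = numeric(),
                          reversible = NULL, modifiers = NULL,
                          initial_state = NULL, boundary = numeric(),
                          local_parameters = NULL, compartment_sizes = NULL,
                          id = NULL) {
  species_ids <- as.character(species_ids)
  n <- length(species_ids)
  stoichiometry <- as.matrix(stoichiometry)
  r <- ncol(stoichiometry)
  if (n < 1L) stop("need at least one dynamic species")
  if (r < 1L) stop("need at least one reaction")
  if (nrow(stoichiometry) != n) {
    stop(sprintf("stoichiometry has %d rows but there are %d species",
                 nrow(stoichiometry), n))
  }
  if (anyDuplicated(species_ids)) stop("duplicated species identifiers")
  rates <- lapply(rates, function(e) {
    if (is.character(e)) str2lang(e) else e
  })
  if (length(rates) != r) {
    stop(sprintf("%d rate laws supplied for %d reactions", length(rates), r))
  }
  if (is.null(reversible)) reversible <- rep(FALSE, r)
  if (is.null(modifiers)) modifiers <- rep(list(character()), r)
  if (is.null(local_parameters)) local_parameters <- rep(list(numeric()), r)
  if (length(reversible) != r || length(modifiers) != r ||
      length(local_parameters) != r) {
    stop("reversible, modifiers and local_parameters must have one entry per reaction")
  }
  if (is.null(initial_state)) initial_state <- rep(1, n)
  initial_state <- as.numeric(initial_state)
  if (length(initial_state) != n) stop("initial_state must have length n")
  if (any(!is.finite(initial_state)) || any(initial_state < 0)) {
    stop("initial_state must be finite and non-negative")
  }
  names(initial_state) <- species_ids
  if (is.null(compartment_sizes)) compartment_sizes <- rep(1, n)
  if (length(compartment_sizes) == 1L) compartment_sizes <- rep(compartment_sizes, n)
  rownames(stoichiometry) <- species_ids
  if (is.null(colnames(stoichiometry))) {
    colnames(stoichiometry) <- paste0("v", seq_len(r))
  }

  # every symbol a rate law references must resolve somewhere
  known <- c(species_ids, names(boundary), names(parameters), "pi")
  for (j in seq_len(r)) {
    vars <- all.vars(rates[[j]])
    unknown <- setdiff(vars, c(known, names(local_parameters[[j]])))
    if (length(unknown) > 0L) {
      stop(sprintf("rate law for reaction '%s' references unknown symbols: %s",
                   colnames(stoichiometry)[j], paste(unknown, collapse = ", ")))
    }
    bad_mod <- setdiff(modifiers[[j]], c(species_ids, names(boundary)))
    if (length(bad_mod) > 0L) {
      stop(sprintf("modifiers of reaction '%s' are not species: %s",
                   colnames(stoichiometry)[j], paste(bad_mod, collapse = ", ")))
    }
  }

  m <- structure(
    list(species_ids = species_ids, stoichiometry = stoichiometry,
         rates = rates, parameters = parameters, reversible = reversible,
         modifiers = modifiers, initial_state = initial_state,
         boundary = boundary, local_parameters = local_parameters,
         compartment_sizes = compartment_sizes, id = id),
    class = "kinetic_model")

  v0 <- reaction_rates(m, initial_state)
  if (any(!is.finite(v0))) {
    bad <- colnames(stoichiometry)[!is.finite(v0)]
    stop(sprintf("rate law(s) not finite at the initial state: %s",
                 paste(bad, collapse = ", ")))
  }
  m
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat(sprintf("Kinetic model%s: %d species, %d reactions\n",
              if (!is.null(x$id)) paste0(" '", x$id, "'") else "",
              length(x$species_ids), ncol(x$stoichiometry)))
  cat("  species:", paste(utils::head(x$species_ids, 8), collapse = ", "),
      if (length(x$species_ids) > 8) "..." else "", "\n")
  if (length(x$boundary) > 0) {
    cat("  fixed boundary species:", paste(names(x$boundary), collapse = ", "), "\n")
  }
  cat(sprintf("  %d parameters, %d reversible reactions\n",
              length(x$parameters) + sum(lengths(x$local_parameters)),
              sum(x$reversible)))
  invisible(x)
}

# Evaluate all reaction rates at `state`. `state` may be a plain numeric
# vector of length n, or an N x n matrix (one row per ensemble member), in
# which case each rate law is evaluated vectorised over rows and an N x r
# matrix is returned.
#' @noRd
reaction_rates <- function(model, state) {
  vec_in <- !is.matrix(state)
  if (vec_in) state <- matrix(state, nrow = 1)
  env <- new.env(parent = baseenv())
  for (nm in names(model$parameters)) assign(nm, model$parameters[[nm]], envir = env)
  for (nm in names(model$boundary)) assign(nm, model$boundary[[nm]], envir = env)
  for (j in seq_along(model$species_ids)) {
    assign(model$species_ids[j], state[, j], envir = env)
  }
  r <- length(model$rates)
  out <- matrix(NA_real_, nrow(state), r)
  for (j in seq_len(r)) {
    loc <- model$local_parameters[[j]]
    e <- if (length(loc) > 0) {
      le <- new.env(parent = env)
      for (nm in names(loc)) assign(nm, loc[[nm]], envir = le)
      le
    } else env
    v <- eval(model$rates[[j]], envir = e)
    out[, j] <- v
  }
  if (vec_in) out[1, ] else out
}

#' Evaluate the ODE right-hand side of a kinetic model
#'
#' Computes \eqn{dS/dt = N v(S) / V}, the net production rate of every dynamic
#' species: stoichiometry times the reaction-rate vector, divided by the
#' species' compartment sizes.
#'
#' @param model a [kinetic_model].
#' @param state numeric vector of n concentrations (or an N x n matrix for
#'   vectorised evaluation over an ensemble of states).
#' @return numeric vector of n time-derivatives (or an N x n matrix).
#' @export
ode_rhs <- function(model, state) {
  vec_in <- !is.matrix(state)
  sm <- if (vec_in) matrix(state, nrow = 1) else state
  if (ncol(sm) != length(model$species_ids)) {
    stop("state length does not match the number of species")
  }
  if (any(!is.finite(sm))) stop("state contains non-finite values")
  v <- reaction_rates(model, sm)
  if (any(!is.finite(v))) {
    bad <- unique(colnames(model$stoichiometry)[colSums(!is.finite(rbind(v))) > 0])
    stop(sprintf("rate evaluation not finite for reaction(s): %s",
                 paste(bad, collapse = ", ")))
  }
  d <- v %*% t(model$stoichiometry)
  d <- sweep(d, 2, model$compartment_sizes, "/")
  if (vec_in) stats::setNames(d[1, ], model$species_ids) else d
}

#' Numerical Jacobian of a kinetic model
#'
#' Central finite differences of [ode_rhs()]: entry (i, j) is
#' \eqn{\partial f_i / \partial S_j}, the sensitivity of species i's net rate
#' to species j's concentration. The Jacobian has units of inverse time and
#' encodes the local regulatory structure of the network around `state`.
#'
#' The step for coordinate j is `rel_step * max(|S_j|, floor)`, so states with
#' zero entries are handled by the absolute floor.
#'
#' @param model a [kinetic_model].
#' @param state numeric vector of n concentrations at which to differentiate.
#' @param rel_step relative finite-difference step (default 1e-6).
#' @param floor absolute lower bound on the step size (default 1e-8).
#' @return n x n numeric matrix with species labels on both dimensions.
#' @export
numerical_jacobian <- function(model, state, rel_step = 1e-6, floor = 1e-8) {
  stopifnot(rel_step > 0, floor > 0)
  state <- as.numeric(state)
  n <- length(model$species_ids)
  if (length(state) != n) stop("state length does not match the number of species")
  J <- matrix(0, n, n, dimnames = list(model$species_ids, model$species_ids))
  for (j in seq_len(n)) {
    h <- rel_step * max(abs(state[j]), floor / rel_step)
    sp <- state; sp[j] <- sp[j] + h
    sm <- state; sm[j] <- sm[j] - h
    J[, j] <- (ode_rhs(model, sp) - ode_rhs(model, sm)) / (2 * h)
  }
  J
}

#' Find a steady state by stiff ODE integration
#'
#' Integrates the model's ODEs from `initial` with a stiff-capable solver
#' (`deSolve::lsoda`) over geometrically growing time horizons until the
#' infinity norm of the right-hand side drops below `tol`, the trajectory is
#' flagged divergent, or `max_time` is exhausted. Divergence (state norm above
#' `diverge_bound`, or a non-finite state) yields a non-converged result, not
#' an error.
#'
#' @param model a [kinetic_model].
#' @param initial starting concentrations; defaults to the model's
#'   `initial_state`.
#' @param tol convergence tolerance on `max(abs(ode_rhs))` (default 1e-9).
#' @param max_time maximum integration time in model time units (default 1e4).
#' @param diverge_bound state magnitude treated as divergence (default 1e8).
#' @return An object of class `steady_state`: a list with elements `state`
#'   (named concentrations), `residual_norm`, `converged`, and `time`.
#' @export
find_steady_state <- function(model, initial = model$initial_state, tol = 1e-9,
                              max_time = 1e4, diverge_bound = 1e8) {
  stopifnot(tol > 0, max_time > 0)
  state <- as.numeric(initial)
  n <- length(model$species_ids)
  fun <- function(t, y, p) list(as.numeric(ode_rhs(model, y)))
  t_now <- 0
  horizon <- min(1, max_time)
  converged <- FALSE
  repeat {
    res <- max(abs(ode_rhs(model, state)))
    if (res <= tol) { converged <- TRUE; break }
    if (!all(is.finite(state)) || max(abs(state)) > diverge_bound) break
    if (t_now >= max_time) break
    t_next <- min(t_now + horizon, max_time)
    sol <- tryCatch(
      deSolve::lsoda(y = state, times = c(t_now, t_next), func = fun, parms = NULL,
                     rtol = 1e-10, atol = 1e-12),
      warning = function(w) NULL, error = function(e) NULL)
    if (is.null(sol) || nrow(sol) < 2L || !all(is.finite(sol[nrow(sol), -1]))) break
    state <- as.numeric(sol[nrow(sol), -1])
    t_now <- t_next
    horizon <- horizon * 4
  }
  residual <- if (all(is.finite(state))) max(abs(ode_rhs(model, state))) else Inf
  structure(list(state = stats::setNames(state, model$species_ids),
                 residual_norm = residual,
                 converged = converged && residual <= tol,
                 time = t_now),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("Steady state (%s): residual %.3g at t = %.3g\n",
              if (x$converged) "converged" else "NOT converged",
              x$residual_norm, x$time))
  print(x$state)
  invisible(x)
}
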