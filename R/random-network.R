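#' Generate a random stable sparse mass-action network
#'
#' Builds a connected mass-action reaction network with a known, Hurwitz-stable
#' Jacobian, suitable as an in-silico ground truth for the inverse-Jacobian
#' pipeline. The network consists of (i) a constant influx into a random
#' subset of species, (ii) uni-molecular conversions \eqn{A \to B} along a
#' random connected backbone plus extra random edges up to the requested
#' density, optionally a few bi-molecular condensations \eqn{A + B \to C}, and
#' (iii) first-order dilution \eqn{S_i \to \emptyset} on every species. The
#' dilution terms exchange mass with the environment and make the steady-state
#' Jacobian strictly diagonally dominant in the uni-molecular case, so
#' stability is the norm rather than the exception; candidates are
#' nevertheless verified (steady state found, all Jacobian eigenvalues with
#' negative real part, structural pattern small enough that the inverse
#' problem is overdetermined) and redrawn up to `max_tries` times.
#'
#' Rate constants are drawn log-uniformly over one decade either side of 1, so
#' realistic timescale separation is present without extreme stiffness.
#'
#' @param n number of species (>= 2).
#' @param density target fraction of the n(n-1) possible conversion edges
#'   (0 < density <= 1); values above 0.5 are capped so the inverse problem
#'   stays overdetermined.
#' @param seed integer seed; the same (n, density, seed) always yields the
#'   same model.
#' @param bimolecular_frac fraction of extra edges realised as bi-molecular
#'   condensations (default 0.2; only used when n >= 3).
#' @param max_tries redraw budget for the stability check (default 50).
#' @return A [kinetic_model] whose attributes include the verified steady
#'   state (`attr(model, "steady_state")`).
#' @export
#' @examples
#' m <- make_random_mass_action_network(5, density = 0.3, seed = 1)
#' ss <- attr(m, "steady_state")
#' max(Re(eigen(numerical_jacobian(m, ss$state))$values)) < 0
make_random_mass_action_network <- function(n, density = 0.3, seed = 1,
                                            bimolecular_frac = 0.2,
                                            max_tries = 50) {
  stopifnot(n >= 2, density > 0, density <= 1)
  p_budget <- n * (n + 1) / 2
  for (try in seq_len(max_tries)) {
    set.seed(derive_seed(seed, 104729L, try))
    cand <- random_network_candidate(n, density, bimolecular_frac, p_budget)
    ss <- find_steady_state(cand, tol = 1e-10, max_time = 1e5)
    if (!ss$converged || any(ss$state <= 0)) next
    J <- numerical_jacobian(cand, ss$state)
    if (max(Re(eigen(J, only.values = TRUE)$values)) >= -1e-10) next
    pat <- pattern_from_stoichiometry(cand)
    if (pat$p > p_budget) next
    attr(cand, "steady_state") <- ss
    attr(cand, "seed") <- seed
    return(cand)
  }
  stop(sprintf(
    "no stable network found for n = %d, density = %.2f after %d attempts",
    n, density, max_tries))
}

#' @noRd
random_network_candidate <- function(n, density, bimolecular_frac, p_budget) {
  sp <- paste0("S", seq_len(n))
  # connected conversion backbone over a random species permutation
  perm <- sample(n)
  edges <- cbind(perm[-n], perm[-1])
  n_target <- round(density * n * (n - 1))
  # cap so that p = n (dilution diagonals) + edges stays overdetermined
  n_target <- min(n_target, floor(n * (n - 1) / 2))
  extra_needed <- max(0L, n_target - nrow(edges))
  all_pairs <- which(matrix(TRUE, n, n) & !diag(n), arr.ind = TRUE)
  have <- paste(edges[, 1], edges[, 2])
  pool <- all_pairs[!(paste(all_pairs[, 1], all_pairs[, 2]) %in% have), , drop = FALSE]
  if (extra_needed > 0L && nrow(pool) > 0L) {
    take <- pool[sample(nrow(pool), min(extra_needed, nrow(pool))), , drop = FALSE]
    edges <- rbind(edges, take)
  }

  n_bi <- if (n >= 3) round(bimolecular_frac * max(0L, nrow(edges) - (n - 1L))) else 0L
  uni_edges <- edges
  bi_list <- list()
  if (n_bi > 0L) {
    bi_rows <- sample(seq_len(nrow(edges)), n_bi)
    for (k in bi_rows) {
      a <- edges[k, 1]; c_ <- edges[k, 2]
      b <- sample(setdiff(seq_len(n), c(a, c_)), 1)
      bi_list[[length(bi_list) + 1L]] <- c(a, b, c_)
    }
    uni_edges <- edges[-bi_rows, , drop = FALSE]
  }

  n_in <- max(1L, round(n / 3))
  inflow_into <- sample(n, n_in)

  r_total <- nrow(uni_edges) + length(bi_list) + n_in + n
  stoich <- matrix(0, n, r_total)
  rates <- vector("list", r_total)
  params <- numeric(0)
  rid <- character(r_total)
  j <- 0L
  logu <- function() 10^stats::runif(1, -1, 1)
  for (k in seq_len(n_in)) {
    j <- j + 1L
    i <- inflow_into[k]
    kn <- sprintf("kin%d", j)
    params[kn] <- stats::runif(1, 0.5, 2)
    stoich[i, j] <- 1
    rates[[j]] <- str2lang(kn)
    rid[j] <- sprintf("vin%d", k)
  }
  for (k in seq_len(nrow(uni_edges))) {
    j <- j + 1L
    a <- uni_edges[k, 1]; b <- uni_edges[k, 2]
    kn <- sprintf("k%d", j)
    params[kn] <- logu()
    stoich[a, j] <- -1; stoich[b, j] <- 1
    rates[[j]] <- str2lang(sprintf("%s * %s", kn, sp[a]))
    rid[j] <- sprintf("v%d", j)
  }
  for (k in seq_along(bi_list)) {
    j <- j + 1L
    a <- bi_list[[k]][1]; b <- bi_list[[k]][2]; c_ <- bi_list[[k]][3]
    kn <- sprintf("k%d", j)
    params[kn] <- logu()
    stoich[a, j] <- -1; stoich[b, j] <- -1; stoich[c_, j] <- 1
    rates[[j]] <- str2lang(sprintf("%s * %s * %s", kn, sp[a], sp[b]))
    rid[j] <- sprintf("v%d", j)
  }
  for (i in seq_len(n)) {
    j <- j + 1L
    kn <- sprintf("kd%d", i)
    params[kn] <- logu()
    stoich[i, j] <- -1
    rates[[j]] <- str2lang(sprintf("%s * %s", kn, sp[i]))
    rid[j] <- sprintf("vdeg%d", i)
  }
  colnames(stoich) <- rid
  kinetic_model(species_ids = sp, stoichiometry = stoich, rates = rates,
                parameters = params, initial_state = rep(1, n),
                id = sprintf("random-mass-action-n%d", n))
}
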