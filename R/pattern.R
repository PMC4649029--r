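#' Jacobian sparsity pattern derived from stoichiometry
#'
#' Which Jacobian entries can be non-zero is fixed by network structure: entry
#' (i, j) is structurally non-zero iff some reaction changes species i
#' (non-zero stoichiometric coefficient in row i) and has a rate influenced by
#' species j. "Influenced" means j is a reactant of the reaction, or a product
#' of a reversible reaction, or is listed among the reaction's modifiers
#' (allosteric regulation is invisible to stoichiometry, so it must be
#' declared explicitly).
#'
#' The p true positions are enumerated in row-major order; this ordering is
#' the vectorization convention used by [build_linear_system()] and
#' [devectorize()] throughout the package.
#'
#' @param model a [kinetic_model].
#' @return An object of class `jacobian_pattern`: list with `mask` (n x n
#'   logical), `p` (number of structural non-zeros), `index_map` (p x 2 matrix
#'   of (row, col) positions in row-major order), and `species_ids`.
#' @export
pattern_from_stoichiometry <- function(model) {
  n <- length(model$species_ids)
  r <- ncol(model$stoichiometry)
  S <- model$stoichiometry
  mask <- matrix(FALSE, n, n, dimnames = list(model$species_ids, model$species_ids))
  for (rx in seq_len(r)) {
    affected <- which(S[, rx] != 0)
    if (length(affected) == 0L) next
    reactants <- model$species_ids[S[, rx] < 0]
    products <- if (model$reversible[rx]) model$species_ids[S[, rx] > 0] else character()
    influencers <- union(union(reactants, products),
                         intersect(model$modifiers[[rx]], model$species_ids))
    cols <- match(influencers, model$species_ids)
    mask[affected, cols] <- TRUE
  }
  jacobian_pattern(mask, model$species_ids)
}

#' Construct a Jacobian pattern from a logical mask
#'
#' @param mask n x n logical matrix of allowed non-zero positions.
#' @param species_ids optional species labels.
#' @return A `jacobian_pattern` object; see [pattern_from_stoichiometry()].
#' @export
jacobian_pattern <- function(mask, species_ids = NULL) {
  mask <- as.matrix(mask)
  stop_if_not_square(mask, "pattern mask")
  mask <- mask != 0
  n <- nrow(mask)
  if (is.null(species_ids)) {
    species_ids <- rownames(mask)
    if (is.null(species_ids)) species_ids <- paste0("S", seq_len(n))
  }
  dimnames(mask) <- list(species_ids, species_ids)
  lin <- which(t(mask))  # row-major enumeration of TRUE positions
  index_map <- cbind(row = (lin - 1L) %/% n + 1L, col = (lin - 1L) %% n + 1L)
  structure(list(mask = mask, p = nrow(index_map), index_map = index_map,
                 species_ids = species_ids),
            class = "jacobian_pattern")
}

#' @export
print.jacobian_pattern <- function(x, ...) {
  n <- nrow(x$mask)
  cat(sprintf("Jacobian pattern: %d x %d, p = %d structural non-zeros (%.0f%% dense)\n",
              n, n, x$p, 100 * x$p / n^2))
  cat(sprintf("  overdetermined linear system: %s (p %s n(n+1)/2 = %d)\n",
              if (x$p <= n * (n + 1) / 2) "yes" else "no",
              if (x$p <= n * (n + 1) / 2) "<=" else ">", n * (n + 1) / 2))
  invisible(x)
}

#' Extract the pattern-true entries of a Jacobian as a vector
#'
#' Vectorizes J over the pattern's row-major index map; the exact inverse of
#' [devectorize()].
#'
#' @param J n x n numeric matrix.
#' @param pattern a `jacobian_pattern`.
#' @return numeric vector of length `pattern$p`.
#' @export
vectorize_jacobian <- function(J, pattern) {
  J <- as.matrix(J)
  J[pattern$index_map]
}

#' Place a solution vector back into Jacobian form
#'
#' @param x numeric vector of length `pattern$p` in the pattern's row-major
#'   order.
#' @param pattern a `jacobian_pattern`.
#' @return n x n matrix with `x` at the pattern positions and exact zeros
#'   elsewhere.
#' @export
devectorize <- function(x, pattern) {
  if (length(x) != pattern$p) {
    stop(sprintf("solution has length %d but the pattern has p = %d entries",
                 length(x), pattern$p))
  }
  n <- nrow(pattern$mask)
  J <- matrix(0, n, n, dimnames = dimnames(pattern$mask))
  J[pattern$index_map] <- x
  J
}

#' Stiffness ratio of a Jacobian
#'
#' The ratio between the maximal and minimal absolute values of the non-zero
#' Jacobian entries (restricted to the structural pattern when one is given).
#' A large spread of Jacobian magnitudes reflects widely separated reaction
#' timescales and degrades the accuracy of inverse solutions.
#'
#' @param J n x n numeric Jacobian matrix.
#' @param pattern optional `jacobian_pattern` restricting which entries count;
#'   by default all non-zero entries of J are used.
#' @return scalar ratio `max|J_ij| / min|J_ij|` over the counted entries.
#' @export
stiffness_ratio <- function(J, pattern = NULL) {
  J <- as.matrix(J)
  vals <- if (is.null(pattern)) abs(J) else abs(J[pattern$index_map])
  vals <- vals[vals > 0]
  if (length(vals) == 0L) stop("all counted Jacobian entries are zero")
  max(vals) / min(vals)
}
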