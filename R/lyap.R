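#' Forward solve of the continuous Lyapunov equation
#'
#' Computes the unique symmetric stationary covariance C satisfying
#' \deqn{J C + C J^T = -2D}
#' for a Hurwitz-stable Jacobian J and symmetric fluctuation matrix D. This is
#' the forward direction of the fluctuation-dissipation relation and serves as
#' the analytic ground truth against which sampled covariances and inverse
#' solutions are checked.
#'
#' A dense Bartels-Stewart-type algorithm is used: J is reduced to real Schur
#' form, the transformed equation is solved by block back-substitution over
#' the quasi-triangular factor (1 x 1 and 2 x 2 diagonal blocks), and the
#' solution is rotated back and symmetrized. The residual
#' \eqn{\|JC + CJ^T + 2D\|_F} is verified against `1e-10 * \|2D\|_F`.
#'
#' @param J n x n Hurwitz-stable Jacobian matrix.
#' @param D a [fluctuation_spec] or symmetric n x n matrix.
#' @return A [covariance_estimate] with `N_used = NA` (analytic).
#' @export
#' @examples
#' C <- solve_lyapunov_forward(diag(c(-1, -2)), diag(2))
#' C$C  # diag(1, 0.5)
solve_lyapunov_forward <- function(J, D) {
  J <- as.matrix(J)
  Dm <- symmetrize(as_D_matrix(D))
  stop_if_not_square(J, "J")
  if (!all(dim(J) == dim(Dm))) stop("J and D dimensions disagree")
  ev <- eigen(J, only.values = TRUE)$values
  if (max(Re(ev)) >= 0) {
    stop("J is not Hurwitz-stable (an eigenvalue has non-negative real part); no stationary covariance exists")
  }
  n <- nrow(J)
  sch <- Matrix::Schur(J)
  Q <- sch$Q
  Tm <- sch$T

  # block partition of the quasi-upper-triangular T
  starts <- integer(0)
  i <- 1L
  while (i <= n) {
    starts <- c(starts, i)
    i <- i + if (i < n && abs(Tm[i + 1L, i]) > 0) 2L else 1L
  }
  sizes <- diff(c(starts, n + 1L))
  m <- length(starts)

  # solve J Y + Y J^T = RHS through the Schur factors, column-block by
  # column-block from last to first
  schur_solve <- function(RHS) {
    G <- t(Q) %*% RHS %*% Q
    Y <- matrix(0, n, n)
    for (ell in rev(seq_len(m))) {
      cols <- starts[ell]:(starts[ell] + sizes[ell] - 1L)
      rhs <- G[, cols, drop = FALSE]
      if (ell < m) {
        later <- (starts[ell] + sizes[ell]):n
        rhs <- rhs - Y[, later, drop = FALSE] %*% t(Tm[cols, later, drop = FALSE])
      }
      Tll <- Tm[cols, cols, drop = FALSE]
      s <- length(cols)
      # small Sylvester solve: (I_s (x) T + T_ll (x) I_n) vec(Ycol) = vec(rhs)
      K <- diag(s) %x% Tm + Tll %x% diag(n)
      Y[, cols] <- matrix(solve(K, as.vector(rhs)), n, s)
    }
    Q %*% Y %*% t(Q)
  }

  C <- symmetrize(schur_solve(-2 * Dm))
  scale <- frob(2 * Dm)
  # iterative refinement: a couple of correction solves recover full accuracy
  # when the Lyapunov operator is badly separated
  for (iter in 1:3) {
    R <- J %*% C + C %*% t(J) + 2 * Dm
    if (scale == 0 || frob(R) <= 1e-12 * scale) break
    C <- symmetrize(C - schur_solve(R))
  }
  res <- frob(J %*% C + C %*% t(J) + 2 * Dm)
  if (scale > 0 && res > 1e-10 * scale) {
    if (res > 1e-6 * scale) {
      stop(sprintf("Lyapunov forward solve residual %.3g exceeds tolerance", res / scale))
    }
    warning(sprintf("Lyapunov forward solve residual %.3g above target 1e-10", res / scale))
  }
  out <- covariance_estimate(C, N_used = NA_integer_)
  dimnames(out$C) <- dimnames(J)
  out
}

#' Build the sparsity-constrained linear system A x = b
#'
#' Rewrites the Lyapunov equation \eqn{J C + C J^T = -2D} as an overdetermined
#' linear system in the p structurally non-zero Jacobian entries. Equation
#' rows are all n^2 ordered pairs (i, k) in row-major order; the coefficient
#' of unknown \eqn{J_{a,b}} in equation (i, k) is
#' \deqn{[a = i]\, C_{b,k} + [a = k]\, C_{i,b},}
#' and the right-hand side entry is \eqn{-2 D_{i,k}}. By default all n^2 rows
#' are kept, so each off-diagonal equation appears twice (the (i,k) and (k,i)
#' rows coincide for symmetric D), which weights off-diagonal information
#' twice in least squares; set `collapse = TRUE` to keep only the
#' n(n+1)/2 unique rows i <= k.
#'
#' @param C a [covariance_estimate] or symmetric n x n matrix.
#' @param D a [fluctuation_spec] or n x n matrix.
#' @param pattern a `jacobian_pattern` giving the p unknown positions.
#' @param collapse keep only rows with i <= k (default FALSE).
#' @return An object of class `lyap_system`: list with `A` (n^2 x p), `b`
#'   (length n^2), `index_map`, `row_map`, `kappa_A` (condition number of A),
#'   `n`, `p`, and `species_ids`.
#' @export
build_linear_system <- function(C, D, pattern, collapse = FALSE) {
  Cm <- as_C_matrix(C)
  Dm <- as_D_matrix(D)
  stop_if_not_square(Cm, "C")
  n <- nrow(Cm)
  if (!all(dim(Dm) == n)) stop("C and D dimensions disagree")
  if (nrow(pattern$mask) != n) stop("pattern dimension does not match C")
  p <- pattern$p
  if (p < 1L) stop("pattern has no free entries")
  if (p > n^2) stop("pattern has more entries than the Jacobian")
  if (p > n * (n + 1) / 2) {
    warning(sprintf(
      "p = %d exceeds n(n+1)/2 = %d: the system is no longer overdetermined",
      p, n * (n + 1) / 2))
  }
  if (collapse) {
    ik <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
    row_map <- cbind(i = ik[, 1], k = ik[, 2])
    row_map <- row_map[order(row_map[, 1], row_map[, 2]), , drop = FALSE]
  } else {
    row_map <- cbind(i = rep(seq_len(n), each = n), k = rep(seq_len(n), n))
  }
  n_rows <- nrow(row_map)
  A <- matrix(0, n_rows, p)
  im <- pattern$index_map
  for (q in seq_len(p)) {
    a <- im[q, 1]; b_ <- im[q, 2]
    col <- numeric(n_rows)
    hit_i <- row_map[, "i"] == a
    col[hit_i] <- col[hit_i] + Cm[b_, row_map[hit_i, "k"]]
    hit_k <- row_map[, "k"] == a
    col[hit_k] <- col[hit_k] + Cm[row_map[hit_k, "i"], b_]
    A[, q] <- col
  }
  b <- -2 * Dm[row_map]
  structure(list(A = A, b = b, index_map = im, row_map = row_map,
                 kappa_A = condition_number(A), n = n, p = p,
                 species_ids = pattern$species_ids, pattern = pattern),
            class = "lyap_system")
}

#' @export
print.lyap_system <- function(x, ...) {
  cat(sprintf("Lyapunov linear system: A is %d x %d, condition number %.3g\n",
              nrow(x$A), x$p, x$kappa_A))
  invisible(x)
}

#' Condition number of a matrix
#'
#' The ratio of the largest to the smallest singular value,
#' \eqn{\kappa = \sigma_1 / \sigma_{\min}}. Large values flag an ill-posed
#' linear system whose solution is unstable under perturbations of the
#' right-hand side. When the smallest singular value underflows relative to
#' the largest (ratio below 1e-300) `Inf` is returned.
#'
#' @param M a numeric matrix.
#' @return scalar condition number (>= 1, possibly `Inf`).
#' @export
condition_number <- function(M) {
  M <- as.matrix(M)
  if (length(M) == 0L) stop("empty matrix")
  sv <- svd(M, nu = 0, nv = 0)$d
  s1 <- sv[1]
  if (s1 == 0) return(Inf)
  smin <- sv[length(sv)]
  if (smin < s1 * 1e-300) return(Inf)
  s1 / smin
}

#' Relative Lyapunov residual of a candidate Jacobian
#'
#' Diagnoses how well a Jacobian explains a covariance/fluctuation pair:
#' \deqn{\|J C + C J^T + 2D\|_F / \|2D\|_F.}
#' A triple that satisfies the Lyapunov equation exactly gives 0; `J = 0`
#' gives 1. When D is zero the unnormalized residual is returned with
#' attribute `unnormalized = TRUE`.
#'
#' @param J n x n Jacobian matrix.
#' @param C a [covariance_estimate] or matrix.
#' @param D a [fluctuation_spec] or matrix.
#' @return scalar relative residual.
#' @export
lyapunov_residual <- function(J, C, D) {
  J <- as.matrix(J)
  Cm <- as_C_matrix(C)
  Dm <- as_D_matrix(D)
  if (!all(dim(J) == dim(Cm)) || !all(dim(J) == dim(Dm))) {
    stop("J, C and D dimensions disagree")
  }
  num <- frob(J %*% Cm + Cm %*% t(J) + 2 * Dm)
  den <- frob(2 * Dm)
  if (den == 0) {
    return(structure(num, unnormalized = TRUE))
  }
  num / den
}

#' Export a linear system as delimited files
#'
#' Writes A and b as CSV and the column-to-Jacobian-entry index map as a JSON
#' sidecar, for comparison with external solvers.
#'
#' @param sys a `lyap_system`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default "system").
#' @return invisibly, the paths written.
#' @export
write_linear_system <- function(sys, dir, prefix = "system") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pa <- file.path(dir, paste0(prefix, "_A.csv"))
  pb <- file.path(dir, paste0(prefix, "_b.csv"))
  pj <- file.path(dir, paste0(prefix, "_index.json"))
  utils::write.table(sys$A, pa, sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(sys$b, pb, sep = ",", row.names = FALSE, col.names = FALSE)
  sp <- sys$species_ids
  jsonlite::write_json(
    list(species = sp,
         columns = data.frame(row = sys$index_map[, 1], col = sys$index_map[, 2]),
         kappa_A = sys$kappa_A),
    pj, auto_unbox = TRUE, digits = NA)
  invisible(c(pa, pb, pj))
}
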