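# The four solvers for the ill-posed system A x = b. Each returns a
# `jacobian_fit` object via new_jacobian_fit(); the user-facing front end with
# formula-free fitting semantics lives in fit.R.

#' @noRd
new_jacobian_fit <- function(x, method, hyper, sys, x0 = NULL, call = NULL) {
  if (is.null(x0)) x0 <- numeric(length(x))
  J <- devectorize(x, sys$pattern)
  structure(
    list(x = x, J = J, method = method, hyper = hyper,
         residual_norm = sqrt(sum((sys$A %*% x - sys$b)^2)),
         solution_norm = sqrt(sum((x - x0)^2)),
         kappa_A = sys$kappa_A, system = sys, call = call),
    class = "jacobian_fit")
}

#' Ordinary least squares solution of the Lyapunov system
#'
#' Minimizes \eqn{\|Ax - b\|^2}. Solved through the SVD pseudo-inverse, which
#' is numerically preferable to forming the normal equations
#' \eqn{x = (A^T A)^{-1} A^T b} explicitly but agrees with them on
#' well-conditioned input. Rank-deficient A yields the minimum-norm solution
#' with a warning.
#'
#' @param sys a `lyap_system` from [build_linear_system()].
#' @return A `jacobian_fit` object.
#' @export
solve_ols <- function(sys) {
  sv <- svd(sys$A)
  d <- sv$d
  tol <- max(dim(sys$A)) * .Machine$double.eps * d[1]
  keep <- d > tol
  if (!all(keep)) {
    warning(sprintf(
      "A is numerically rank-deficient (rank %d of %d); returning the minimum-norm solution",
      sum(keep), length(d)))
  }
  x <- as.numeric(sv$v[, keep, drop = FALSE] %*%
                    ((t(sv$u[, keep, drop = FALSE]) %*% sys$b) / d[keep]))
  new_jacobian_fit(x, "OLS", list(), sys)
}

#' Truncated SVD solution
#'
#' Discards the `t` smallest singular components of A before forming the
#' pseudo-inverse solution:
#' \deqn{x = \sum_{i \le p - t} \frac{u_i^T b}{\sigma_i} v_i.}
#' Truncation trades a small bias for a large variance reduction when A is
#' ill-conditioned. With `truncation = "auto"` the truncation level is chosen
#' by [select_truncation()] with the default relative threshold.
#'
#' @param sys a `lyap_system`.
#' @param truncation integer `t` with `0 <= t < p`, or `"auto"`.
#' @param rel_threshold relative singular-value cutoff for auto mode
#'   (default 1e-8).
#' @return A `jacobian_fit` object; `$hyper$t` records the truncation used.
#' @export
solve_tsvd <- function(sys, truncation = "auto", rel_threshold = 1e-8) {
  sv <- svd(sys$A)
  p <- sys$p
  t_ <- if (identical(truncation, "auto")) {
    select_truncation(sv$d, rel_threshold)
  } else {
    as.integer(truncation)
  }
  if (t_ < 0L || t_ >= p) stop(sprintf("truncation must satisfy 0 <= t < p = %d", p))
  keep <- seq_len(p - t_)
  x <- as.numeric(sv$v[, keep, drop = FALSE] %*%
                    ((t(sv$u[, keep, drop = FALSE]) %*% sys$b) / sv$d[keep]))
  new_jacobian_fit(x, "TSVD", list(t = t_), sys)
}

#' Truncated total least squares solution
#'
#' The errors-in-variables solver: both A (built from the estimated
#' covariance) and b (built from the uncertain fluctuation matrix) are allowed
#' to be perturbed, \eqn{(A + \delta A)x = b + \delta b}, and the smallest
#' joint perturbation is sought. Computed from the SVD of the augmented matrix
#' \eqn{[A \mid b]} truncated to rank `p - t`, with the standard closed form
#' \eqn{x = -V_{12} V_{22}^+} from the partition of the right singular
#' vectors.
#'
#' @param sys a `lyap_system`.
#' @param truncation integer `t` with `0 <= t < p`, or `"auto"` (singular
#'   values of `[A | b]` below `rel_threshold` times the largest are
#'   truncated).
#' @param rel_threshold relative cutoff for auto mode (default 1e-8).
#' @return A `jacobian_fit` object; `$hyper$t` records the truncation used.
#' @export
solve_ttls <- function(sys, truncation = "auto", rel_threshold = 1e-8) {
  p <- sys$p
  Ab <- cbind(sys$A, sys$b)
  # full right singular basis: the thin SVD omits null-space columns needed
  # for the V22 block when the system has fewer rows than p + 1
  sv <- svd(Ab, nu = 0, nv = ncol(Ab))
  t_ <- if (identical(truncation, "auto")) {
    # count only among the first p singular values: the (p+1)-th is expected
    # to be tiny whenever b is (near-)consistent with A and is always discarded
    select_truncation(sv$d[seq_len(min(p, length(sv$d)))], rel_threshold)
  } else {
    as.integer(truncation)
  }
  if (t_ < 0L || t_ >= p) stop(sprintf("truncation must satisfy 0 <= t < p = %d", p))
  keep_rank <- p - t_
  # discarded right-singular-vector block, columns (p - t + 1) ... ncol(V)
  V2 <- sv$v[, (keep_rank + 1L):ncol(sv$v), drop = FALSE]
  V12 <- V2[seq_len(p), , drop = FALSE]
  V22 <- V2[p + 1L, , drop = FALSE]
  denom <- sum(V22^2)
  if (denom < .Machine$double.eps) {
    stop("TTLS V22 block is numerically singular; try a different truncation level")
  }
  x <- as.numeric(-V12 %*% t(V22) / denom)
  new_jacobian_fit(x, "TTLS", list(t = t_), sys)
}

#' Tikhonov (ridge) regularized solution
#'
#' Minimizes \eqn{\|Ax - b\|^2 + \lambda \|x - x_0\|_2^2} (penalty norm order
#' m = 2; the penalty matrix is \eqn{\lambda I}, the simplest choice). Solved
#' through the augmented least-squares stack
#' \eqn{[A; \sqrt{\lambda} I]\,x = [b; \sqrt{\lambda} x_0]}, which is the
#' numerically stable equivalent of the normal-equations form
#' \eqn{(A^T A + \lambda I)^{-1}(A^T b + \lambda x_0)}. The prior `x0`
#' defaults to the zero vector.
#'
#' Shrinkage penalties (m = 1, LASSO; 1 < m < 2, elastic net) are deliberately
#' not offered: the zero entries of the Jacobian are already fixed by
#' stoichiometry, so zeroing further entries is unwanted.
#'
#' @param sys a `lyap_system`.
#' @param lambda regularization strength (>= 0), or `"lcurve"` / `"cv"` to
#'   select it via [select_lambda()].
#' @param x0 prior solution (default zeros).
#' @param ... passed to [select_lambda()] when `lambda` is a selection rule.
#' @return A `jacobian_fit` object; `$hyper$lambda` records the value used.
#' @export
solve_tikhonov <- function(sys, lambda = 0, x0 = NULL, ...) {
  p <- sys$p
  if (is.null(x0)) x0 <- numeric(p)
  if (length(x0) != p) stop("x0 must have length p")
  if (is.character(lambda)) {
    lambda <- select_lambda(sys, x0 = x0, method = lambda, ...)
  }
  if (lambda < 0) stop("lambda must be non-negative")
  if (lambda == 0) {
    fit <- solve_ols(sys)
    fit$method <- "TIKH"
    fit$hyper <- list(lambda = 0, m = 2)
    return(fit)
  }
  Aa <- rbind(sys$A, sqrt(lambda) * diag(p))
  ba <- c(sys$b, sqrt(lambda) * x0)
  x <- qr.solve(Aa, ba)
  new_jacobian_fit(as.numeric(x), "TIKH", list(lambda = lambda, m = 2), sys,
                   x0 = x0)
}

#' Choose the TSVD/TTLS truncation level from a singular-value spectrum
#'
#' Counts the singular values falling below `rel_threshold` times the largest
#' one; that count is the number of components to truncate. The default
#' threshold 1e-8 is motivated by double-precision accumulation error.
#'
#' @param d non-increasing singular values (or an `svd()` result).
#' @param rel_threshold relative cutoff in (0, 1).
#' @return integer truncation level t.
#' @export
select_truncation <- function(d, rel_threshold = 1e-8) {
  if (is.list(d)) d <- d$d
  stopifnot(rel_threshold > 0, rel_threshold < 1)
  sum(d / d[1] < rel_threshold)
}

#' Select the Tikhonov regularization strength
#'
#' Two standard rules are offered over a common log-spaced candidate grid
#' (default: 30 points spanning \eqn{[\sigma_p^2, \sigma_1^2]}, the squared
#' extreme singular values of A):
#'
#' * `"lcurve"` — the L-curve criterion: along the grid, plot log residual
#'   norm against log solution norm and pick the lambda of maximal discrete
#'   curvature (the "corner" balancing data fit against solution size).
#'   Curvature is computed by finite differences on the log-log grid; ties
#'   break toward smaller lambda.
#' * `"cv"` — k-fold cross-validation over equation rows: pick the lambda
#'   minimizing the mean held-out residual \eqn{\|A_{test} x - b_{test}\|^2};
#'   ties break toward smaller lambda.
#'
#' @param sys a `lyap_system`.
#' @param x0 prior solution (default zeros).
#' @param method `"lcurve"` or `"cv"`.
#' @param grid increasing positive candidate lambdas; default as above.
#' @param folds number of CV folds (default 5).
#' @param seed seed for the CV fold shuffle (default 1).
#' @return the selected lambda (scalar).
#' @export
select_lambda <- function(sys, x0 = NULL, method = c("lcurve", "cv"),
                          grid = NULL, folds = 5, seed = 1) {
  method <- match.arg(method)
  p <- sys$p
  if (is.null(x0)) x0 <- numeric(p)
  if (is.null(grid)) {
    sv <- svd(sys$A, nu = 0, nv = 0)$d
    hi <- sv[1]^2
    # span down to sigma_p^2, but always at least 12 decades below sigma_1^2:
    # for well-conditioned A the useful lambda lie far below sigma_p^2
    lo <- max(min(sv[length(sv)]^2, hi * 1e-12), hi * 1e-30)
    grid <- exp(seq(log(lo), log(hi), length.out = 30))
  }
  if (any(grid <= 0) || is.unsorted(grid)) stop("grid must be positive and increasing")
  if (length(grid) == 1L) {
    warning("lambda grid has a single candidate; returning it")
    return(grid)
  }
  if (method == "lcurve") {
    rn <- sn <- numeric(length(grid))
    for (i in seq_along(grid)) {
      f <- solve_tikhonov(sys, lambda = grid[i], x0 = x0)
      rn[i] <- f$residual_norm
      sn[i] <- f$solution_norm
    }
    # Tikhonov monotonicity along the grid is a structural property of the
    # method; verify it before trusting the curvature computation.
    if (any(diff(rn) < -1e-8 * max(rn)) || any(diff(sn) > 1e-8 * max(sn))) {
      warning("L-curve monotonicity violated numerically; selection may be unreliable")
    }
    lr <- log(pmax(rn, .Machine$double.xmin))
    ls <- log(pmax(sn, .Machine$double.xmin))
    k_ <- lcurve_curvature(lr, ls)
    best <- which(k_ == max(k_, na.rm = TRUE))[1]  # ties -> smaller lambda
    return(grid[best])
  }
  # cross-validation over equation rows
  n_rows <- nrow(sys$A)
  set.seed(derive_seed(seed, 13L))
  fold_id <- sample(rep_len(seq_len(folds), n_rows))
  err <- numeric(length(grid))
  for (i in seq_along(grid)) {
    sse <- 0
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      Atr <- sys$A[tr, , drop = FALSE]
      Aa <- rbind(Atr, sqrt(grid[i]) * diag(p))
      ba <- c(sys$b[tr], sqrt(grid[i]) * x0)
      x <- tryCatch(qr.solve(Aa, ba), error = function(e) rep(NA_real_, p))
      pred <- sys$A[!tr, , drop = FALSE] %*% x
      sse <- sse + sum((pred - sys$b[!tr])^2)
    }
    err[i] <- sse / n_rows
  }
  grid[which(err == min(err))[1]]
}

# Discrete curvature of the parametric log-log L-curve by central finite
# differences; endpoints get -Inf so an interior corner is preferred.
#' @noRd
lcurve_curvature <- function(lr, ls) {
  m <- length(lr)
  k <- rep(-Inf, m)
  for (i in 2:(m - 1)) {
    d1r <- (lr[i + 1] - lr[i - 1]) / 2
    d1s <- (ls[i + 1] - ls[i - 1]) / 2
    d2r <- lr[i + 1] - 2 * lr[i] + lr[i - 1]
    d2s <- ls[i + 1] - 2 * ls[i] + ls[i - 1]
    den <- (d1r^2 + d1s^2)^1.5
    k[i] <- if (den > 0) (d1r * d2s - d1s * d2r) / den else -Inf
  }
  k
}
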