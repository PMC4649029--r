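#' Fit a Jacobian to covariance and fluctuation data
#'
#' The central fitting function of the package: given a metabolomics
#' covariance matrix C, a fluctuation matrix D, and the structural sparsity
#' pattern of the Jacobian, it rewrites the Lyapunov equation
#' \eqn{J C + C J^T = -2D} as the overdetermined linear system
#' \eqn{A x = b} in the p structurally non-zero Jacobian entries
#' ([build_linear_system()]) and solves it with the requested method:
#'
#' * `"ols"` — ordinary least squares ([solve_ols()]);
#' * `"tsvd"` — truncated SVD ([solve_tsvd()]);
#' * `"ttls"` — truncated total least squares ([solve_ttls()]);
#' * `"tikhonov"` — Tikhonov/ridge regularization ([solve_tikhonov()]).
#'
#' @param C covariance matrix (a [covariance_estimate], or a plain symmetric
#'   matrix).
#' @param D fluctuation matrix (a [fluctuation_spec], a matrix, or a vector of
#'   diagonal entries).
#' @param pattern a `jacobian_pattern`, or a [kinetic_model] (in which case
#'   the pattern is derived from its stoichiometry).
#' @param method one of `"ols"`, `"tsvd"`, `"ttls"`, `"tikhonov"`.
#' @param ... method-specific arguments: `truncation` / `rel_threshold` for
#'   tsvd and ttls; `lambda` / `x0` for tikhonov.
#' @param collapse passed to [build_linear_system()].
#' @return An object of class `jacobian_fit` with components `J` (the
#'   estimated Jacobian, exact zeros off-pattern), `x` (its vectorized
#'   pattern entries), `method`, `hyper` (selected hyperparameters),
#'   `residual_norm`, `solution_norm`, `kappa_A`, and `system`.
#' @seealso [coef.jacobian_fit()], [residuals.jacobian_fit()],
#'   [predict.jacobian_fit()], [jacobian_r2()]
#' @export
#' @examples
#' J <- matrix(c(-1, 0.5, 0, -2), 2, 2)
#' D <- diag(c(0.1, 0.2))
#' C <- solve_lyapunov_forward(J, D)
#' pat <- jacobian_pattern(J != 0)
#' fit <- jacobian_fit(C, D, pat, method = "tsvd")
#' max(abs(coef(fit, "matrix") - J))
jacobian_fit <- function(C, D, pattern, method = c("ols", "tsvd", "ttls", "tikhonov"),
                         ..., collapse = FALSE) {
  method <- match.arg(method)
  if (inherits(pattern, "kinetic_model")) {
    pattern <- pattern_from_stoichiometry(pattern)
  }
  sys <- build_linear_system(C, D, pattern, collapse = collapse)
  fit <- switch(method,
                ols = solve_ols(sys),
                tsvd = solve_tsvd(sys, ...),
                ttls = solve_ttls(sys, ...),
                tikhonov = solve_tikhonov(sys, ...))
  fit$call <- match.call()
  if (!is.null(pattern$species_ids)) {
    dimnames(fit$J) <- list(pattern$species_ids, pattern$species_ids)
  }
  fit
}

#' @export
print.jacobian_fit <- function(x, ...) {
  cat(sprintf("Inverse Jacobian fit (%s)\n", x$method))
  if (!is.null(x$call)) { cat("  call: "); print(x$call) }
  cat(sprintf("  n = %d species, p = %d free entries, condition number %.4g\n",
              x$system$n, x$system$p, x$kappa_A))
  if (length(x$hyper) > 0) {
    cat("  hyperparameters:",
        paste(names(x$hyper), vapply(x$hyper, format, ""), sep = " = ",
              collapse = ", "), "\n")
  }
  cat(sprintf("  residual norm |Ax - b| = %.4g, solution norm = %.4g\n",
              x$residual_norm, x$solution_norm))
  invisible(x)
}

#' Summary of an inverse Jacobian fit
#'
#' @param object a `jacobian_fit`.
#' @param ... unused.
#' @return An object of class `summary.jacobian_fit` (printed with the
#'   estimated Jacobian, conditioning and residual diagnostics).
#' @export
summary.jacobian_fit <- function(object, ...) {
  s <- object[c("method", "hyper", "residual_norm", "solution_norm", "kappa_A")]
  s$J <- object$J
  s$n <- object$system$n
  s$p <- object$system$p
  s$stiffness <- tryCatch(stiffness_ratio(object$J), error = function(e) NA_real_)
  class(s) <- "summary.jacobian_fit"
  s
}

#' @export
print.summary.jacobian_fit <- function(x, ...) {
  cat(sprintf("Inverse Jacobian fit (%s): n = %d, p = %d\n", x$method, x$n, x$p))
  cat(sprintf("  condition number kappa_A = %.4g, stiffness ratio = %.4g\n",
              x$kappa_A, x$stiffness))
  cat(sprintf("  residual |Ax - b| = %.4g\n", x$residual_norm))
  cat("Estimated Jacobian:\n")
  print(signif(x$J, 4))
  invisible(x)
}

#' Extract coefficients of an inverse Jacobian fit
#'
#' @param object a `jacobian_fit`.
#' @param form `"vector"` (default) for the p pattern entries named
#'   `"J[i,j]"`, or `"matrix"` for the full n x n Jacobian.
#' @param ... unused.
#' @return named numeric vector or matrix.
#' @export
coef.jacobian_fit <- function(object, form = c("vector", "matrix"), ...) {
  form <- match.arg(form)
  if (form == "matrix") return(object$J)
  im <- object$system$index_map
  stats::setNames(object$x, sprintf("J[%d,%d]", im[, 1], im[, 2]))
}

#' Residuals of an inverse Jacobian fit
#'
#' @param object a `jacobian_fit`.
#' @param type `"equation"` (default) for the n^2 linear-system residuals
#'   `A x - b`, or `"lyapunov"` for the scalar relative Lyapunov residual of
#'   the fitted Jacobian against the data it was fitted to.
#' @param ... unused.
#' @return numeric vector (equation) or scalar (lyapunov).
#' @export
residuals.jacobian_fit <- function(object, type = c("equation", "lyapunov"), ...) {
  type <- match.arg(type)
  sys <- object$system
  if (type == "equation") {
    return(as.numeric(sys$A %*% object$x - sys$b))
  }
  n <- sys$n
  # reconstruct C and D from the stored system: C columns and b entries
  D <- matrix(-sys$b / 2, n, n, byrow = TRUE)
  C <- system_covariance(sys)
  lyapunov_residual(object$J, C, D)
}

# recover the covariance the system was built from (possible because column q
# of A holds C entries at known positions)
#' @noRd
system_covariance <- function(sys) {
  n <- sys$n
  C <- matrix(NA_real_, n, n)
  im <- sys$index_map
  rm_ <- sys$row_map
  for (q in seq_len(sys$p)) {
    a <- im[q, 1]; b_ <- im[q, 2]
    hit <- which(rm_[, "i"] == a)
    other <- rm_[hit, "k"]
    dup <- other == a  # row (a, a): both indicator terms fire, coeff = 2 C[b, a]
    vals <- sys$A[hit, q]
    vals[dup] <- vals[dup] / 2
    C[b_, other] <- vals
    C[other, b_] <- vals
  }
  C
}

#' Predicted stationary covariance of a fitted Jacobian
#'
#' Forward-solves the Lyapunov equation with the estimated Jacobian and a
#' fluctuation matrix: the covariance the fitted network would show at
#' stationarity. Only defined when the estimate is Hurwitz-stable.
#'
#' @param object a `jacobian_fit`.
#' @param D fluctuation matrix; defaults to the one the fit was built from.
#' @param ... unused.
#' @return A [covariance_estimate].
#' @export
predict.jacobian_fit <- function(object, D = NULL, ...) {
  if (is.null(D)) {
    n <- object$system$n
    D <- matrix(-object$system$b / 2, n, n, byrow = TRUE)
    if (nrow(object$system$row_map) < n^2) {
      stop("cannot reconstruct D from a collapsed system; supply D explicitly")
    }
  }
  solve_lyapunov_forward(object$J, D)
}

#' Diagnostic plot of an inverse Jacobian fit
#'
#' With a reference Jacobian, plots estimated against true pattern entries
#' with the identity line (the regression underlying the R^2 accuracy metric).
#' Without one, shows the singular-value spectrum of A on a log scale — the
#' conditioning profile that decides how ill-posed the inversion is.
#'
#' @param x a `jacobian_fit`.
#' @param J_true optional reference Jacobian matrix.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.jacobian_fit <- function(x, J_true = NULL, ...) {
  if (!is.null(J_true)) {
    xt <- as.matrix(J_true)[x$system$index_map]
    graphics::plot(xt, x$x, xlab = "true Jacobian entry",
                   ylab = "estimated Jacobian entry",
                   main = sprintf("%s recovery", x$method), ...)
    graphics::abline(0, 1, lty = 2)
  } else {
    d <- svd(x$system$A, nu = 0, nv = 0)$d
    graphics::plot(seq_along(d), d, log = "y", type = "b",
                   xlab = "index", ylab = "singular value of A",
                   main = sprintf("spectrum (kappa = %.3g)", x$kappa_A), ...)
  }
  invisible(x)
}

#' Serialize a fit to JSON plus a labelled CSV of the Jacobian
#'
#' @param fit a `jacobian_fit`.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
write_jacobian_fit <- function(fit, dir, prefix = "fit") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pj <- file.path(dir, paste0(prefix, ".json"))
  pc <- file.path(dir, paste0(prefix, "_J.csv"))
  jsonlite::write_json(
    list(method = fit$method, hyper = fit$hyper,
         residual_norm = fit$residual_norm, solution_norm = fit$solution_norm,
         kappa_A = fit$kappa_A),
    pj, auto_unbox = TRUE, digits = NA)
  labels <- if (!is.null(rownames(fit$J))) rownames(fit$J) else
    paste0("S", seq_len(nrow(fit$J)))
  write_matrix(fit$J, pc, labels = labels)
  invisible(c(pj, pc))
}
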