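# Controlled degradation of the covariance and fluctuation matrices, and the
# R^2 accuracy metric for recovered Jacobians.

#' Perturb a covariance estimate by ensemble subsampling
#'
#' Emulates imperfect covariance estimation from too few biological
#' replicates: for each requested fraction and repeat, a uniform random subset
#' of the ensemble rows is drawn without replacement and its covariance
#' computed. By the law of large numbers, smaller subsets drift further from
#' the full-ensemble reference C0; the realized perturbation level is recorded
#' per matrix as \eqn{\delta C = \|C_i - C_0\|_F / \|C_0\|_F}. Subsampled
#' covariances are used as-is — no positive-definiteness repair — because loss
#' of positive definiteness is precisely what drives the condition number up
#' in practice; each matrix carries a `positive_definite` flag.
#'
#' @param samples an `ensemble_samples` object (or plain N x n matrix).
#' @param fractions subsample fractions in (0, 1]; `floor(fraction * N)` must
#'   be >= 3.
#' @param repeats subsamples per fraction.
#' @param seed integer seed (deterministic per (fraction, repeat)).
#' @return An object of class `perturbation_set`: list with `reference` (the
#'   full-N [covariance_estimate]), `perturbed` (list of covariance_estimate),
#'   `levels` (realized delta values), `fraction`, `repeat_index`, `generator`
#'   and `seed`.
#' @export
perturb_covariance_subsample <- function(samples, fractions, repeats = 1,
                                         seed = 1) {
  X <- if (inherits(samples, "ensemble_samples")) samples$samples else as.matrix(samples)
  N <- nrow(X)
  stopifnot(all(fractions > 0), all(fractions <= 1), repeats >= 1)
  sizes <- floor(fractions * N)
  if (any(sizes < 3)) {
    stop("a subsample would have fewer than 3 rows; increase N or the fraction")
  }
  C0 <- covariance_estimate(stats::cov(X), N_used = N)
  f0 <- frob(C0$C)
  perturbed <- list()
  levels <- numeric(0)
  frac_rec <- numeric(0)
  rep_rec <- integer(0)
  for (fi in seq_along(fractions)) {
    for (r in seq_len(repeats)) {
      if (fractions[fi] == 1) {
        Ci <- C0
        d <- 0
      } else {
        set.seed(derive_seed(seed, 17L, fi, r))
        rows <- sample(N, sizes[fi])
        Cm <- stats::cov(X[rows, , drop = FALSE])
        d <- frob(Cm - C0$C) / f0
        Ci <- covariance_estimate(Cm, N_used = sizes[fi], delta_C = d)
      }
      perturbed[[length(perturbed) + 1L]] <- Ci
      levels <- c(levels, d)
      frac_rec <- c(frac_rec, fractions[fi])
      rep_rec <- c(rep_rec, r)
    }
  }
  structure(list(reference = C0, perturbed = perturbed, levels = levels,
                 fraction = frac_rec, repeat_index = rep_rec,
                 generator = "subsample", seed = seed),
            class = "perturbation_set")
}

#' Perturb a fluctuation matrix with multiplicative Gaussian noise
#'
#' Emulates uncertainty in the assumed fluctuation structure:
#' \deqn{D_i = (I + E)\,D_0, \qquad E_{jk} \sim N(0, \sigma^2) \text{ i.i.d.}}
#' E is a full matrix, so off-diagonal entries of D become populated even when
#' D0 is diagonal; at sigma = 1 the perturbed matrix is effectively fully
#' randomized, with off-diagonal entries of the same magnitude as the
#' diagonal. No symmetrization is applied by default (set
#' `symmetrize_D = TRUE` to restore exact symmetry). The realized
#' \eqn{\delta D = \|D_i - D_0\|_F / \|D_0\|_F} is recorded per matrix.
#'
#' @param D0 the control [fluctuation_spec] (or a matrix).
#' @param sigma noise level (>= 0); the reference study levels are 0.01, 0.1
#'   and 1.
#' @param repeats number of perturbed matrices.
#' @param seed integer seed.
#' @param symmetrize_D symmetrize each perturbed matrix (default FALSE).
#' @return A `perturbation_set` with `fluctuation_spec` elements.
#' @export
perturb_fluctuation <- function(D0, sigma, repeats = 1, seed = 1,
                                symmetrize_D = FALSE) {
  stopifnot(sigma >= 0, repeats >= 1)
  if (!inherits(D0, "fluctuation_spec")) D0 <- fluctuation_spec(as.matrix(D0))
  n <- nrow(D0$D)
  f0 <- frob(D0$D)
  perturbed <- list()
  levels <- numeric(repeats)
  for (r in seq_len(repeats)) {
    if (sigma == 0) {
      Di <- D0$D
    } else {
      set.seed(derive_seed(seed, 19L, r))
      E <- matrix(stats::rnorm(n * n, sd = sigma), n, n)
      Di <- (diag(n) + E) %*% D0$D
      if (symmetrize_D) Di <- symmetrize(Di)
    }
    d <- frob(Di - D0$D) / f0
    levels[r] <- d
    perturbed[[r]] <- structure(
      list(D = Di, is_diagonal = all(Di[row(Di) != col(Di)] == 0),
           sigma_level = sigma, delta_D = d),
      class = "fluctuation_spec")
  }
  structure(list(reference = D0, perturbed = perturbed, levels = levels,
                 sigma = sigma, repeat_index = seq_len(repeats),
                 generator = "gaussian_multiplicative", seed = seed),
            class = "perturbation_set")
}

#' @export
print.perturbation_set <- function(x, ...) {
  cat(sprintf("Perturbation set (%s): %d matrices, delta in [%.3g, %.3g]\n",
              x$generator, length(x$perturbed),
              min(x$levels), max(x$levels)))
  invisible(x)
}

#' Accuracy of a recovered Jacobian: regression R^2 against the truth
#'
#' Ordinary linear regression (with intercept) of the p pattern-true entries
#' of the estimated Jacobian on those of the true Jacobian. R^2 near 1 with
#' slope near 1 and intercept near 0 means the recovered entries are
#' pairwise comparable to the truth; the intercept is retained so departures
#' from an origin-crossing relationship stay visible.
#'
#' @param J_true true Jacobian matrix.
#' @param J_est estimated Jacobian matrix (e.g. `coef(fit, "matrix")`).
#' @param pattern a `jacobian_pattern` selecting the compared entries.
#' @return list with `r_squared`, `slope`, `intercept`.
#' @export
jacobian_r2 <- function(J_true, J_est, pattern) {
  xt <- as.matrix(J_true)[pattern$index_map]
  xe <- as.matrix(J_est)[pattern$index_map]
  if (pattern$p < 3L) stop("regression over fewer than 3 pattern entries is meaningless")
  fit <- stats::lm(xe ~ xt)
  # R^2 from the fit residuals directly (summary.lm warns on perfect fits)
  ss_tot <- sum((xe - mean(xe))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  list(r_squared = min(max(r2, 0), 1),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}

#' Compare two sets of accuracy scores (Mann-Whitney U)
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test between two vectors of R^2
#' scores, as used to decide whether one solver outperforms another. Small
#' untied samples are tested exactly; larger or tied samples use the
#' tie-corrected normal approximation (via [stats::wilcox.test()]).
#'
#' @param r2_a,r2_b numeric vectors (length >= 2 each).
#' @param alternative passed to [stats::wilcox.test()] (default two-sided).
#' @return list with `U_statistic`, `p_value`, and `degenerate` (TRUE when
#'   every value in both samples is identical, in which case p = 1).
#' @export
compare_methods <- function(r2_a, r2_b, alternative = "two.sided") {
  stopifnot(length(r2_a) >= 2, length(r2_b) >= 2)
  if (length(unique(c(r2_a, r2_b))) == 1L) {
    return(list(U_statistic = length(r2_a) * length(r2_b) / 2, p_value = 1,
                degenerate = TRUE))
  }
  wt <- suppressWarnings(stats::wilcox.test(r2_a, r2_b, alternative = alternative,
                                            exact = NULL, correct = TRUE))
  list(U_statistic = unname(wt$statistic), p_value = wt$p.value,
       degenerate = FALSE)
}
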