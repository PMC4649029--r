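# Internal helpers shared across modules.

#' @noRd
frob <- function(M) sqrt(sum(M^2))

#' @noRd
symmetrize <- function(M) (M + t(M)) / 2

# Derive a child RNG seed from a master seed and one or more indices.
# Kept below 2^31 so it is always a valid R integer seed.
#' @noRd
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (i in idx) {
    s <- (s * 48271 + as.double(i) * 9973 + 1) %% 2147483647
  }
  as.integer(s)
}

#' @noRd
is_square <- function(M) is.matrix(M) && nrow(M) == ncol(M)

#' @noRd
stop_if_not_square <- function(M, what) {
  if (!is_square(M)) stop(sprintf("%s must be a square matrix", what), call. = FALSE)
}

# Matrix square root factor B with B %*% t(B) = M, for symmetric PSD M.
# Uses the eigendecomposition so positive semi-definite (singular) M is fine.
#' @noRd
psd_factor <- function(M, tol = 1e-12) {
  M <- symmetrize(M)
  e <- eigen(M, symmetric = TRUE)
  lam <- e$values
  if (any(lam < -tol * max(abs(lam), 1))) {
    stop("matrix is not positive semi-definite; cannot factor the diffusion term",
         call. = FALSE)
  }
  lam[lam < 0] <- 0
  e$vectors %*% (sqrt(lam) * t(e$vectors))
}
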