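#' Pseudo-inverse of a symmetric matrix with relative eigenvalue cutoff
#'
#' Eigendecomposition-based inverse used wherever a moment covariance must be
#' inverted. Eigenvalues below `tol` times the largest eigenvalue are treated
#' as zero (their inverse contribution is dropped), so rank-deficient
#' empirical covariances from short time series are handled gracefully.
#'
#' @param A symmetric matrix.
#' @param tol relative eigenvalue cutoff (default `1e-12`).
#' @return The (pseudo-)inverse, with attributes `"rank"` and
#'   `"condition_number"` (ratio of largest to smallest retained eigenvalue).
#' @export
pseudo_inverse <- function(A, tol = 1e-12) {
  A <- as.matrix(A)
  stopifnot(nrow(A) == ncol(A))
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  lmax <- max(abs(e$values))
  if (lmax == 0) {
    out <- matrix(0, nrow(A), ncol(A))
    attr(out, "rank") <- 0L
    attr(out, "condition_number") <- NA_real_
    return(out)
  }
  keep <- e$values > tol * lmax
  inv_vals <- ifelse(keep, 1 / e$values, 0)
  out <- e$vectors %*% (inv_vals * t(e$vectors))
  attr(out, "rank") <- sum(keep)
  attr(out, "condition_number") <- lmax / min(e$values[keep])
  out
}

# solve A x = b through the symmetric pseudo-inverse path
pseudo_solve <- function(A, b, tol = 1e-12) {
  pseudo_inverse(A, tol = tol) %*% b
}

#' Fisher z-transform of a Pearson correlation
#'
#' `z = atanh(r) = 0.5 * log((1 + r) / (1 - r))`, the variance-stabilising
#' map used to compare recovered-response correlations across methods.
#'
#' @param r correlation value(s), each strictly inside (-1, 1).
#' @return Transformed value(s), same length as `r`.
#' @examples
#' fisher_transform(0.5)   # ~0.5493
#' @export
fisher_transform <- function(r) {
  if (!is.numeric(r) || any(!is.finite(r))) {
    stop("`r` must be finite numeric")
  }
  if (any(abs(r) >= 1)) {
    stop("fisher_transform is defined for |r| < 1")
  }
  atanh(r)
}

# Fisher z with clipping at |r| = 1 - 1e-12 for noise-free/degenerate fits;
# returns value with attribute "clipped"
fisher_transform_clipped <- function(r) {
  clip <- abs(r) >= 1 - 1e-12
  r2 <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  z <- atanh(r2)
  attr(z, "clipped") <- clip
  z
}
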