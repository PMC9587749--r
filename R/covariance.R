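#' Shot-noise covariance of DTOF moments
#'
#' First-order (delta-method) covariance of `(M0, M1, M2)` under the model
#' that each histogram bin count is an independent Poisson variable. With
#' `N` detected photons and `mu_k` the k'th central moment of the normalised
#' DTOF, the non-zero entries are
#' \deqn{Var(M0) = 1/N, \quad Var(M1) = M2/N,}
#' \deqn{Var(M2) = (\mu_4 - M2^2)/N, \quad Cov(M1, M2) = \mu_3/N.}
#' The first-order covariances between M0 and the timing moments vanish
#' exactly: the M0 derivative with respect to every bin is the constant
#' `-1/N`, so the propagation sum telescopes to a multiple of the mean-centred
#' first moment, which is zero. Every entry scales as `1/N`.
#'
#' @param x a [dtof()] object (its shape supplies the central moments).
#' @param total_photons photon count `N` setting the noise level; defaults to
#'   the total counts in `x`.
#' @return 3x3 matrix of class `"moment_covariance"` with attribute
#'   `source = "theoretical"`.
#' @seealso [empirical_covariance()]
#' @export
shot_noise_covariance <- function(x, total_photons = NULL) {
  mv <- compute_moments(x)
  if (is.null(total_photons)) total_photons <- x$total_photons
  shot_noise_cov_from_moments(M2 = mv[["M2"]],
                              mu3 = attr(mv, "mu3"),
                              mu4 = attr(mv, "mu4"),
                              total_photons = total_photons)
}

# shot-noise 3x3 covariance from normalised-DTOF central moments
shot_noise_cov_from_moments <- function(M2, mu3, mu4, total_photons) {
  if (total_photons <= 0) stop("`total_photons` must be positive")
  Z <- matrix(0, 3, 3, dimnames = list(c("M0", "M1", "M2"),
                                       c("M0", "M1", "M2")))
  Z["M0", "M0"] <- 1 / total_photons
  Z["M1", "M1"] <- M2 / total_photons
  Z["M2", "M2"] <- max(mu4 - M2^2, 0) / total_photons
  Z["M1", "M2"] <- Z["M2", "M1"] <- mu3 / total_photons
  moment_covariance(Z, source = "theoretical")
}

#' Moment covariance matrix
#'
#' Validating constructor for the `3 Nc x 3 Nc` covariance of stacked moment
#' rows. Stacking is always moment-major: all M0 rows, then all M1 rows,
#' then all M2 rows — the package's canonical ordering for every `3 Nc`
#' object.
#'
#' @param matrix symmetric positive-semidefinite matrix, dimension a
#'   multiple of 3.
#' @param source `"theoretical"` (shot noise), `"empirical"` (from data) or
#'   `"identity"`.
#' @return The matrix with class `"moment_covariance"` and attribute
#'   `source`.
#' @export
moment_covariance <- function(matrix, source = c("theoretical", "empirical",
                                                 "identity")) {
  source <- match.arg(source)
  m <- as.matrix(matrix)
  if (nrow(m) != ncol(m) || nrow(m) %% 3 != 0) {
    stop("moment covariance must be square with dimension a multiple of 3")
  }
  scale <- max(abs(m))
  if (scale > 0 && max(abs(m - t(m))) > 1e-10 * scale) {
    stop("moment covariance must be symmetric (1e-10 relative)")
  }
  m <- (m + t(m)) / 2
  if (any(diag(m) < -1e-15 * max(scale, 1))) {
    stop("moment covariance has negative diagonal entries")
  }
  structure(m, source = source, class = c("moment_covariance", "matrix"))
}

#' @export
print.moment_covariance <- function(x, ...) {
  cat(sprintf("moment covariance (%s), %d x %d\n", attr(x, "source"),
              nrow(x), ncol(x)))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  invisible(x)
}

#' Empirical covariance of a moment time series
#'
#' Sample covariance of the stacked moment rows of the selected channels at
#' one wavelength: rows are stacked moment-major (all channels' M0, then M1,
#' then M2) and the covariance is taken across time after mean subtraction.
#'
#' @param x a [moment_time_series()].
#' @param channels integer channel indices (default: all).
#' @param wavelength_index which wavelength slice to use (default 1).
#' @return `3 Nc x 3 Nc` matrix of class `"moment_covariance"` with
#'   `source = "empirical"`. A constant (zero-variance) input gives the zero
#'   matrix and a rank warning.
#' @export
empirical_covariance <- function(x, channels = NULL, wavelength_index = 1) {
  stopifnot(inherits(x, "moment_time_series"))
  if (is.null(channels)) channels <- seq_len(dim(x$values)[1])
  nt <- dim(x$values)[4]
  if (nt < 2) stop("need at least two time samples")
  ym <- stacked_moment_rows(x, channels, wavelength_index)
  Z <- cov(t(ym))  # cov() mean-subtracts internally
  # rank check on the correlation matrix: the raw covariance mixes moment
  # scales spanning ~40 orders of magnitude, which defeats a plain qr()
  v <- diag(Z)
  if (any(v == 0) ||
      qr(Z / sqrt(v %o% v))$rank < nrow(Z)) {
    warning("empirical moment covariance is rank deficient")
  }
  moment_covariance(Z, source = "empirical")
}

# YM: rows = moment-major stacked channels (3 Nc), cols = time
stacked_moment_rows <- function(x, channels, wavelength_index = 1) {
  nt <- dim(x$values)[4]
  nc <- length(channels)
  ym <- matrix(0, 3 * nc, nt)
  for (n in 1:3) {
    for (ci in seq_along(channels)) {
      ym[(n - 1) * nc + ci, ] <- x$values[channels[ci], wavelength_index, n, ]
    }
  }
  ym
}
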