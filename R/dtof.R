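#' Distribution of times of flight (DTOF)
#'
#' A binned photon time-of-flight histogram for one channel, wavelength and
#' time sample. Bin times are stored in seconds; counts may be non-integer
#' (weighted counts from Monte Carlo are allowed) but must be non-negative.
#'
#' @param bin_times bin centre times in seconds, strictly increasing and
#'   uniformly spaced.
#' @param counts photon counts per bin (non-negative, same length as
#'   `bin_times`). At least one count must be positive.
#' @return An object of class `"dtof"` with fields `bin_times`, `counts`
#'   and `total_photons`.
#' @seealso [compute_moments()], [shot_noise_covariance()], [read_dtof()]
#' @export
dtof <- function(bin_times, counts) {
  bin_times <- as.numeric(bin_times)
  counts <- as.numeric(counts)
  if (length(bin_times) != length(counts)) {
    stop("`bin_times` and `counts` must have the same length")
  }
  if (length(bin_times) < 1) stop("empty DTOF")
  if (any(!is.finite(bin_times)) || any(!is.finite(counts))) {
    stop("DTOF fields must be finite")
  }
  if (length(bin_times) > 1) {
    d <- diff(bin_times)
    if (any(d <= 0)) stop("`bin_times` must be strictly increasing")
    if (max(d) - min(d) > 1e-9 * max(d)) {
      stop("`bin_times` must be uniformly spaced")
    }
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total <= 0) stop("DTOF has zero total counts; moments are undefined")
  structure(list(bin_times = bin_times, counts = counts,
                 total_photons = total),
            class = "dtof")
}

#' @export
print.dtof <- function(x, ...) {
  cat(sprintf("DTOF: %d bins, %.3g total photons, span %.3g-%.3g ns\n",
              length(x$bin_times), x$total_photons,
              min(x$bin_times) * 1e9, max(x$bin_times) * 1e9))
  invisible(x)
}

#' Temporal moments of a DTOF
#'
#' Computes the three moments used throughout the package:
#' `M0 = -log(sum(counts))` (the optical-density analogue of total detected
#' intensity), `M1` the mean time of flight (seconds), and `M2` the variance
#' of the time of flight (seconds squared). The third and fourth central
#' moments of the normalised DTOF are returned as attributes because the
#' shot-noise covariance model needs them.
#'
#' @param x a [dtof()] object.
#' @return Named numeric vector `c(M0, M1, M2)` of class `"moment_vector"`,
#'   with attributes `mu3`, `mu4` (central moments, s^3 and s^4) and
#'   `total_photons`.
#' @examples
#' d <- dtof(bin_times = c(1, 3) * 1e-9, counts = c(10, 10))
#' compute_moments(d)   # M1 = 2 ns, M2 = 1 ns^2
#' @export
compute_moments <- function(x) {
  stopifnot(inherits(x, "dtof"))
  p <- x$counts / x$total_photons
  m1 <- sum(p * x$bin_times)
  ct <- x$bin_times - m1
  m2 <- sum(p * ct^2)
  mv <- c(M0 = -log(x$total_photons), M1 = m1, M2 = max(m2, 0))
  attr(mv, "mu3") <- sum(p * ct^3)
  attr(mv, "mu4") <- sum(p * ct^4)
  attr(mv, "total_photons") <- x$total_photons
  class(mv) <- c("moment_vector", "numeric")
  mv
}

#' @export
print.moment_vector <- function(x, ...) {
  cat(sprintf("moments: M0 = %.6g, M1 = %.6g ns, M2 = %.6g ns^2\n",
              x[["M0"]], x[["M1"]] * 1e9, x[["M2"]] * 1e18))
  invisible(x)
}

#' Read / write a DTOF as delimited text
#'
#' Plain-text interchange format: two whitespace-delimited columns,
#' bin time in nanoseconds and counts. Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return `read_dtof` returns a [dtof()] object; `write_dtof` returns
#'   `path` invisibly.
#' @export
read_dtof <- function(path) {
  tab <- read.table(path, header = FALSE, comment.char = "#",
                    col.names = c("time_ns", "counts"))
  dtof(bin_times = tab$time_ns * 1e-9, counts = tab$counts)
}

#' @rdname read_dtof
#' @param x a [dtof()] object.
#' @export
write_dtof <- function(x, path) {
  stopifnot(inherits(x, "dtof"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# bin_time_ns counts", con)
  write.table(data.frame(t = sprintf("%.17g", x$bin_times * 1e9),
                         n = sprintf("%.17g", x$counts)),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
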