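#' Moment time series container
#'
#' Holds the three DTOF moments for a set of channels (optode pairs) at two
#' wavelengths over time, together with the channel geometry and sampling
#' rate. Channels are classified by source-detector separation:
#' short separation (SS) below 10 mm, medium (MS) 21-27 mm, long (LS)
#' 28-34 mm, very long (VLS) above 34 mm, and `"other"` in the 10-21 mm gap.
#'
#' @param values numeric array `[channel, wavelength, moment, time]` with the
#'   moment axis ordered (M0, M1, M2); M1 in seconds, M2 in seconds squared.
#' @param separations source-detector separation per channel, mm.
#' @param wavelengths the two wavelengths, nm (default `c(690, 850)`).
#' @param sample_rate sampling rate, Hz.
#' @param detectors optional integer detector id per channel (channels on the
#'   same detector share scalp physiology and can be paired for
#'   short-separation regression).
#' @return Object of class `"moment_time_series"`.
#' @export
moment_time_series <- function(values, separations,
                               wavelengths = c(690, 850),
                               sample_rate, detectors = NULL) {
  values <- as.array(values)
  if (length(dim(values)) != 4) {
    stop("`values` must be a 4-d array [channel, wavelength, moment, time]")
  }
  if (dim(values)[3] != 3) stop("moment axis must have length 3 (M0, M1, M2)")
  if (dim(values)[1] != length(separations)) {
    stop("length(separations) must match the channel dimension")
  }
  if (dim(values)[2] != length(wavelengths)) {
    stop("length(wavelengths) must match the wavelength dimension")
  }
  if (!is.null(detectors) && length(detectors) != length(separations)) {
    stop("length(detectors) must match the channel dimension")
  }
  structure(list(values = values,
                 separations = as.numeric(separations),
                 wavelengths = as.numeric(wavelengths),
                 sample_rate = as.numeric(sample_rate),
                 detectors = detectors,
                 channel_class = classify_separation(separations)),
            class = "moment_time_series")
}

#' @rdname moment_time_series
#' @param separation separation(s) in mm.
#' @export
classify_separation <- function(separation) {
  cls <- rep("other", length(separation))
  cls[separation < 10] <- "SS"
  cls[separation >= 21 & separation < 28] <- "MS"
  cls[separation >= 28 & separation <= 34] <- "LS"
  cls[separation > 34] <- "VLS"
  cls
}

#' @export
print.moment_time_series <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("moment time series: %d channels x %d wavelengths x 3 moments x %d samples @ %.3g Hz\n",
              d[1], d[2], d[4], x$sample_rate))
  cat("  channel classes:",
      paste(sprintf("%s=%d", names(table(x$channel_class)),
                    table(x$channel_class)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.moment_time_series <- function(x) dim(x$values)

# time axis in seconds
time_axis <- function(x) {
  (seq_len(dim(x$values)[4]) - 1) / x$sample_rate
}

# extract one channel/wavelength moment matrix (3 x Nt)
channel_moments <- function(x, channel, wavelength_index) {
  m <- x$values[channel, wavelength_index, , , drop = TRUE]
  matrix(m, nrow = 3)
}

#' Read / write a moment time series as JSON
#'
#' Text serialisation with full double precision: metadata plus the flattened
#' values array. Round-trips exactly.
#'
#' @param x a [moment_time_series()].
#' @param path file path.
#' @export
write_moment_series <- function(x, path) {
  stopifnot(inherits(x, "moment_time_series"))
  payload <- list(dim = dim(x$values),
                  values = as.numeric(x$values),
                  separations = x$separations,
                  wavelengths = x$wavelengths,
                  sample_rate = x$sample_rate,
                  detectors = x$detectors)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_moment_series
#' @export
read_moment_series <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  moment_time_series(values = array(p$values, dim = p$dim),
                     separations = p$separations,
                     wavelengths = p$wavelengths,
                     sample_rate = p$sample_rate,
                     detectors = p$detectors)
}
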