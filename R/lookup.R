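#' Build a moment-sensitivity lookup table
#'
#' Runs one Monte Carlo simulation per source-detector separation and, by
#' reweighting the same photon records, evaluates at every baseline
#' absorption on the grid: the per-layer sensitivities of the three moments
#' and the DTOF central moments (up to order 4, for the theoretical
#' shot-noise covariance). The default grids span separations 6-34 mm in
#' 2 mm steps and absorptions 0.009-0.03 mm^-1 in 0.001 mm^-1 steps; the
#' absorption axis is free because it is served by reweighting, so the grid
#' cost is one simulation per separation. Grid cells whose record set has
#' fewer than `min_detected` photons are flagged and excluded from
#' interpolation.
#'
#' @param model a [tissue_model()] (its `absorption` field is ignored; the
#'   grid value is applied uniformly to all layers).
#' @param separations separation grid, mm.
#' @param absorptions baseline absorption grid, mm^-1.
#' @param n_photons photons launched per separation (scalar or one value
#'   per separation; longer separations need more photons for the same
#'   detected count).
#' @param seed base RNG seed; separation i uses `seed + i - 1`.
#' @param min_detected flag threshold on detected photons per separation.
#' @param keep_records keep the raw photon records in the returned object
#'   (useful for oracle checks; not serialised).
#' @return Object of class `"sensitivity_table"`: `sens` array
#'   `[moment, layer, separation, absorption]`, `moments` array
#'   `[5, separation, absorption]` with rows
#'   (detected_fraction, M1, M2, mu3, mu4), the grids, per-separation
#'   detected counts, flags, and full provenance.
#' @export
build_lookup_table <- function(model = tissue_model(),
                               separations = seq(6, 34, by = 2),
                               absorptions = seq(0.009, 0.03, by = 0.001),
                               n_photons = 1e6, seed = 1,
                               min_detected = 50,
                               keep_records = FALSE) {
  stopifnot(inherits(model, "tissue_model"))
  ns <- length(separations)
  na <- length(absorptions)
  nl <- model$n_layers
  n_photons <- rep_len(n_photons, ns)
  sens <- array(NA_real_, c(3, nl, ns, na),
                dimnames = list(c("M0", "M1", "M2"), NULL, NULL, NULL))
  moms <- array(NA_real_, c(5, ns, na),
                dimnames = list(c("detected_fraction", "M1", "M2",
                                  "mu3", "mu4"), NULL, NULL))
  detected <- integer(ns)
  records <- if (keep_records) vector("list", ns) else NULL
  for (i in seq_len(ns)) {
    rec <- run_mc(model, separations[i], n_photons[i], seed = seed + i - 1)
    detected[i] <- rec$n_detected
    if (keep_records) records[[i]] <- rec
    for (a in seq_len(na)) {
      mua <- rep(absorptions[a], nl)
      mv <- moments_from_records(rec, mua)
      sens[, , i, a] <- sensitivities_from_records(rec, mua)
      moms[, i, a] <- c(attr(mv, "detected_fraction"), mv[["M1"]],
                        mv[["M2"]], attr(mv, "mu3"), attr(mv, "mu4"))
    }
  }
  structure(list(sens = sens, moments = moms,
                 separations = as.numeric(separations),
                 absorptions = as.numeric(absorptions),
                 n_layers = nl,
                 detected = detected,
                 flagged = detected < min_detected,
                 records = records,
                 provenance = list(n_photons = n_photons, seed = seed,
                                   min_detected = min_detected,
                                   detector = "annulus, 1 mm width",
                                   scattering = model$scattering,
                                   anisotropy = model$anisotropy,
                                   refractive_index = model$refractive_index,
                                   layer_thickness = model$layer_thickness,
                                   volume_mm = model$volume_mm)),
            class = "sensitivity_table")
}

#' @export
print.sensitivity_table <- function(x, ...) {
  cat(sprintf("sensitivity table: %d separations (%.3g-%.3g mm) x %d absorptions (%.3g-%.3g /mm), %d layers\n",
              length(x$separations), min(x$separations), max(x$separations),
              length(x$absorptions), min(x$absorptions), max(x$absorptions),
              x$n_layers))
  cat(sprintf("  detected photons per separation: %s\n",
              paste(x$detected, collapse = ", ")))
  if (any(x$flagged)) {
    cat("  flagged separations:",
        paste(x$separations[x$flagged], collapse = ", "), "mm\n")
  }
  invisible(x)
}

#' Serialise a sensitivity table as JSON
#'
#' Full-double-precision text round trip (raw photon records, if kept, are
#' not serialised).
#' @param x a [build_lookup_table()] result.
#' @param path file path.
#' @export
write_sensitivity_table <- function(x, path) {
  stopifnot(inherits(x, "sensitivity_table"))
  payload <- list(sens_dim = dim(x$sens), sens = as.numeric(x$sens),
                  moments_dim = dim(x$moments),
                  moments = as.numeric(x$moments),
                  separations = x$separations, absorptions = x$absorptions,
                  n_layers = x$n_layers, detected = x$detected,
                  flagged = x$flagged, provenance = x$provenance)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_sensitivity_table
#' @export
read_sensitivity_table <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(sens = array(p$sens, dim = p$sens_dim,
                              dimnames = list(c("M0", "M1", "M2"),
                                              NULL, NULL, NULL)),
                 moments = array(p$moments, dim = p$moments_dim,
                                 dimnames = list(c("detected_fraction",
                                                   "M1", "M2", "mu3", "mu4"),
                                                 NULL, NULL)),
                 separations = p$separations, absorptions = p$absorptions,
                 n_layers = p$n_layers, detected = p$detected,
                 flagged = p$flagged, records = NULL,
                 provenance = as.list(p$provenance)),
            class = "sensitivity_table")
}

# bilinear interpolation weights on one axis; error outside the hull
.axis_weights <- function(grid, value, what) {
  if (value < min(grid) || value > max(grid)) {
    stop(sprintf("%s = %g outside the table hull [%g, %g]; refusing to extrapolate",
                 what, value, min(grid), max(grid)))
  }
  hi <- findInterval(value, grid, rightmost.closed = TRUE)
  hi <- min(max(hi, 1), length(grid) - 1)
  lo <- hi; hi <- hi + 1
  if (grid[hi] == grid[lo]) return(list(idx = c(lo, hi), w = c(1, 0)))
  t <- (value - grid[lo]) / (grid[hi] - grid[lo])
  list(idx = c(lo, hi), w = c(1 - t, t))
}

# bilinearly interpolate a slice f[sep, mua] of the table
.interp_grid <- function(x, arr_fun, separation, absorption) {
  ws <- .axis_weights(x$separations, separation, what = "separation")
  ok <- !x$flagged[ws$idx]
  if (!all(ok)) {
    if (!any(ok)) stop("all neighbouring separations are flagged (too few detected photons)")
    ws$w <- ws$w * ok / sum(ws$w * ok)
  }
  wa <- .axis_weights(x$absorptions, absorption, what = "absorption")
  out <- 0
  for (i in 1:2) for (j in 1:2) {
    out <- out + ws$w[i] * wa$w[j] * arr_fun(ws$idx[i], wa$idx[j])
  }
  out
}

#' Two-layer (scalp/brain) sensitivities from a lookup table
#'
#' Bilinear interpolation over (separation, absorption) of the per-layer
#' sensitivities, collapsed to a two-layer head model: the scalp block is the
#' sum of sensitivities over the first `scalp_thickness` layers, the brain
#' block the sum over the remaining layers. Queries outside the grid hull
#' raise an error rather than extrapolating.
#'
#' @param x a [build_lookup_table()] result.
#' @param separation query separation, mm.
#' @param absorption query baseline absorption, mm^-1.
#' @param scalp_thickness superficial-layer thickness in integer mm
#'   (default 13, i.e. layers 1-13 are scalp).
#' @return Object of class `"two_layer_sensitivity"`: numeric vectors
#'   `scalp` and `brain`, each `c(S0, S1, S2)`.
#' @export
interp_two_layer <- function(x, separation, absorption,
                             scalp_thickness = 13) {
  stopifnot(inherits(x, "sensitivity_table"))
  if (scalp_thickness != round(scalp_thickness) ||
      scalp_thickness < 1 || scalp_thickness >= x$n_layers) {
    stop("`scalp_thickness` must be an integer number of layers below n_layers")
  }
  scalp_idx <- seq_len(scalp_thickness)
  brain_idx <- (scalp_thickness + 1):x$n_layers
  S <- .interp_grid(x, function(i, j) x$sens[, , i, j],
                    separation, absorption)
  structure(list(scalp = rowSums(S[, scalp_idx, drop = FALSE]),
                 brain = rowSums(S[, brain_idx, drop = FALSE]),
                 total = rowSums(S),
                 separation = separation, absorption = absorption,
                 scalp_thickness = scalp_thickness),
            class = "two_layer_sensitivity")
}

#' @export
print.two_layer_sensitivity <- function(x, ...) {
  cat(sprintf("two-layer sensitivities at rho = %.3g mm, mua = %.4g /mm, scalp %d mm:\n",
              x$separation, x$absorption, x$scalp_thickness))
  m <- rbind(scalp = x$scalp, brain = x$brain)
  colnames(m) <- c("S0 [mm]", "S1 [s mm]", "S2 [s^2 mm]")
  print(m)
  invisible(x)
}

#' @rdname interp_two_layer
#' @return `interp_dtof_moments`: named vector
#'   `(detected_fraction, M1, M2, mu3, mu4)` of the baseline DTOF at the
#'   query point, used to assemble theoretical shot-noise covariances.
#' @export
interp_dtof_moments <- function(x, separation, absorption) {
  stopifnot(inherits(x, "sensitivity_table"))
  out <- .interp_grid(x, function(i, j) x$moments[, i, j],
                      separation, absorption)
  names(out) <- rownames(x$moments)
  out
}

#' Theoretical shot-noise covariance for a channel from a lookup table
#'
#' Assembles the 3x3 shot-noise moment covariance for a channel at the given
#' separation and baseline absorption, using the table's stored DTOF central
#' moments and a photon budget per time sample.
#'
#' @inheritParams interp_two_layer
#' @param photons detected-photon budget per sample.
#' @return `"moment_covariance"` (3x3, theoretical).
#' @export
channel_shot_noise <- function(x, separation, absorption, photons) {
  m <- interp_dtof_moments(x, separation, absorption)
  shot_noise_cov_from_moments(M2 = m[["M2"]], mu3 = m[["mu3"]],
                              mu4 = m[["mu4"]], total_photons = photons)
}
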