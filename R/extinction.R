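# Chromophore tables shipped with the package.
#
# Hemoglobin molar extinction coefficients (base 10, cm^-1 / M) from the
# compilation by S. Prahl (Oregon Medical Laser Center, "Optical absorption
# of hemoglobin"); water absorption coefficients (mm^-1) from the
# Hale & Querry (1973) / Kou et al. compilation. Values are tabulated at
# standard fNIRS wavelengths and linearly interpolated in between.
.chromophore_table <- data.frame(
  wavelength = c(650, 690, 750, 780, 800, 830, 850, 900),
  eps_hbo    = c(368, 276, 518, 710, 816, 974, 1058, 1198),   # cm^-1/M
  eps_hbr    = c(3750.12, 2051.96, 1405.24, 1078.0, 761.72,
                 693.04, 691.32, 761.84),                     # cm^-1/M
  mua_water  = c(0.00034, 0.00050, 0.0028, 0.0024, 0.0020,
                 0.0029, 0.0043, 0.0068)                      # mm^-1
)

#' Hemoglobin extinction coefficients
#'
#' Base-10 molar extinction coefficients of oxy- and deoxy-hemoglobin,
#' linearly interpolated from the shipped compilation and converted to
#' mm^-1 per micromolar, the unit used throughout the package.
#'
#' @param wavelength wavelength in nm; must lie inside the tabulated range
#'   (650-900 nm).
#' @return Named vector `c(hbo, hbr)` in mm^-1 / uM (base 10).
#' @export
extinction_coefficients <- function(wavelength) {
  tab <- .chromophore_table
  if (any(wavelength < min(tab$wavelength)) ||
      any(wavelength > max(tab$wavelength))) {
    stop("wavelength outside the tabulated 650-900 nm range")
  }
  # cm^-1/M  ->  mm^-1/uM : /10 for cm->mm, x1e-6 for M->uM
  c(hbo = approx(tab$wavelength, tab$eps_hbo, wavelength)$y * 1e-7,
    hbr = approx(tab$wavelength, tab$eps_hbr, wavelength)$y * 1e-7)
}

#' @rdname extinction_coefficients
#' @return `water_absorption`: absorption coefficient of pure water, mm^-1.
#' @export
water_absorption <- function(wavelength) {
  tab <- .chromophore_table
  if (any(wavelength < min(tab$wavelength)) ||
      any(wavelength > max(tab$wavelength))) {
    stop("wavelength outside the tabulated 650-900 nm range")
  }
  approx(tab$wavelength, tab$mua_water, wavelength)$y
}

#' Baseline tissue absorption coefficient
#'
#' Absorption (mm^-1, base e) of a tissue modelled as a water fraction plus
#' oxy- and deoxy-hemoglobin:
#' `mua = f_water * mua_water + ln(10) * (eps_HbO * C_HbO + eps_HbR * C_HbR)`.
#' The defaults (80% water, 30 uM HbO, 20 uM HbR, i.e. 60% oxygen
#' saturation) are the composition used to pick the baseline absorption for
#' the sensitivity lookup tables.
#'
#' @param wavelength nm.
#' @param water_fraction volume fraction of water, in `[0, 1]`.
#' @param c_hbo,c_hbr chromophore concentrations, uM (non-negative).
#' @return Absorption coefficient, mm^-1.
#' @examples
#' baseline_absorption(850)   # ~0.014 mm^-1
#' @export
baseline_absorption <- function(wavelength, water_fraction = 0.8,
                                c_hbo = 30, c_hbr = 20) {
  if (c_hbo < 0 || c_hbr < 0) stop("concentrations must be non-negative")
  if (water_fraction < 0 || water_fraction > 1) {
    stop("`water_fraction` must be in [0, 1]")
  }
  eps <- extinction_coefficients(wavelength)
  water_fraction * water_absorption(wavelength) +
    log(10) * (eps[["hbo"]] * c_hbo + eps[["hbr"]] * c_hbr)
}

#' Convert hemoglobin concentration changes to absorption changes and back
#'
#' `hb_to_mua` applies the Beer-Lambert relation
#' `d_mua(lambda) = ln(10) * (eps_HbO * dHbO + eps_HbR * dHbR)`;
#' `mua_to_hb` inverts the 2x2 system given absorption changes at two
#' wavelengths.
#'
#' @param hbo,hbr concentration changes, uM (vectors over time).
#' @param wavelength nm (scalar for `hb_to_mua`).
#' @return `hb_to_mua`: absorption change in mm^-1. `mua_to_hb`: list with
#'   `hbo` and `hbr` in uM.
#' @export
hb_to_mua <- function(hbo, hbr, wavelength) {
  eps <- extinction_coefficients(wavelength)
  log(10) * (eps[["hbo"]] * hbo + eps[["hbr"]] * hbr)
}

#' @rdname hb_to_mua
#' @param mua1,mua2 absorption changes (mm^-1) at `wavelengths[1]` and
#'   `wavelengths[2]`.
#' @param wavelengths the two wavelengths, nm.
#' @export
mua_to_hb <- function(mua1, mua2, wavelengths) {
  e1 <- extinction_coefficients(wavelengths[1])
  e2 <- extinction_coefficients(wavelengths[2])
  E <- log(10) * rbind(e1, e2)
  det_e <- E[1, 1] * E[2, 2] - E[1, 2] * E[2, 1]
  if (abs(det_e) < 1e-12 * max(abs(E))^2) {
    stop("extinction matrix is singular for these wavelengths")
  }
  hbo <- (E[2, 2] * mua1 - E[1, 2] * mua2) / det_e
  hbr <- (-E[2, 1] * mua1 + E[1, 1] * mua2) / det_e
  list(hbo = hbo, hbr = hbr)
}
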