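# run expr with a private RNG stream; global .Random.seed is untouched
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Canonical synthetic hemodynamic response function
#'
#' Double-gamma HRF rescaled so that, at `scale = 1`, the HbO curve peaks at
#' 0.6 uM and the HbR curve at -0.2 uM (HbR is the HbO shape scaled by
#' -1/3). The shape is `Gamma(6, 1) - Gamma(12, 1) / 6`: peak around 5 s, a
#' small undershoot with minimum near 11 s, and return to under 5% of peak
#' by 18 s. Both curves are identically zero at and before onset.
#'
#' @param scale non-negative amplitude multiplier (0.2, 0.5, 1 and 3 are the
#'   benchmark settings).
#' @param sample_rate sampling rate of the returned time base, Hz.
#' @param t_range time range relative to onset, seconds (default -2 to 18).
#' @return Object of class `"canonical_hrf"`: `time` (s), `hbo`, `hbr` (uM),
#'   `scale`.
#' @examples
#' h <- make_hrf(1)
#' max(h$hbo)   # 0.6
#' min(h$hbr)   # -0.2
#' @export
make_hrf <- function(scale = 1, sample_rate = 7, t_range = c(-2, 18)) {
  if (!is.numeric(scale) || scale < 0) stop("`scale` must be non-negative")
  tt <- seq(t_range[1], t_range[2], by = 1 / sample_rate)
  shape <- ifelse(tt > 0,
                  dgamma(tt, shape = 6, rate = 1) -
                    dgamma(tt, shape = 12, rate = 1) / 6,
                  0)
  peak <- max(shape)
  hbo <- 0.6 * scale * shape / peak
  structure(list(time = tt, hbo = hbo, hbr = -hbo / 3, scale = scale,
                 sample_rate = sample_rate),
            class = "canonical_hrf")
}

#' @export
print.canonical_hrf <- function(x, ...) {
  cat(sprintf("canonical HRF (scale %.3g): HbO peak %.3g uM, HbR trough %.3g uM, %g-%g s\n",
              x$scale, max(x$hbo), min(x$hbr), min(x$time), max(x$time)))
  invisible(x)
}

#' @export
plot.canonical_hrf <- function(x, ...) {
  plot(x$time, x$hbo, type = "l", col = "red3",
       xlab = "time since onset [s]", ylab = "concentration change [uM]",
       ylim = range(c(x$hbo, x$hbr)), ...)
  lines(x$time, x$hbr, col = "blue3")
  abline(h = 0, lty = 3)
  legend("topright", c("HbO", "HbR"), col = c("red3", "blue3"), lty = 1,
         bty = "n")
  invisible(x)
}

#' Random stimulus train
#'
#' Onset times for repeated stimulus presentations: the first onset is
#' uniform in `[5, mean_isi]` seconds (avoids edge epochs) and successive
#' inter-stimulus intervals are drawn from a normal distribution truncated
#' at zero. At the defaults (mean 21 s, sd 3 s) a 300 s recording receives
#' about 14 repetitions.
#'
#' @param duration recording length, seconds (must exceed `mean_isi`).
#' @param mean_isi mean inter-stimulus interval, seconds.
#' @param sd_isi standard deviation of the interval, seconds (0 gives
#'   exactly uniform spacing).
#' @param seed integer seed; the train is fully determined by
#'   `(seed, parameters)`.
#' @return Object of class `"stimulus_train"` with strictly increasing
#'   `onsets` inside `[0, duration)`.
#' @export
make_stimulus_train <- function(duration, mean_isi = 21, sd_isi = 3, seed) {
  if (sd_isi < 0) stop("`sd_isi` must be non-negative")
  if (duration <= mean_isi) stop("`duration` must exceed `mean_isi`")
  with_seed(seed, {
    onsets <- runif(1, min(5, mean_isi), mean_isi)
    repeat {
      isi <- rnorm(1, mean_isi, sd_isi)
      while (isi <= 0) isi <- rnorm(1, mean_isi, sd_isi)
      nxt <- onsets[length(onsets)] + isi
      if (nxt >= duration) break
      onsets <- c(onsets, nxt)
    }
    structure(list(onsets = onsets, duration = duration,
                   mean_isi = mean_isi, sd_isi = sd_isi, seed = seed),
              class = "stimulus_train")
  })
}

#' @rdname make_stimulus_train
#' @param onsets explicit onset times, seconds (strictly increasing, inside
#'   `[0, duration)`); for deterministic designs.
#' @export
stimulus_train <- function(onsets, duration) {
  onsets <- as.numeric(onsets)
  if (any(diff(onsets) <= 0)) stop("`onsets` must be strictly increasing")
  if (any(onsets < 0) || any(onsets >= duration)) {
    stop("`onsets` must lie inside [0, duration)")
  }
  structure(list(onsets = onsets, duration = duration,
                 mean_isi = if (length(onsets) > 1) mean(diff(onsets))
                            else NA_real_,
                 sd_isi = if (length(onsets) > 2) sd(diff(onsets))
                          else NA_real_,
                 seed = NA_integer_),
            class = "stimulus_train")
}

#' @export
print.stimulus_train <- function(x, ...) {
  cat(sprintf("stimulus train: %d onsets in %g s (mean ISI %.3g s, sd %.3g s, seed %d)\n",
              length(x$onsets), x$duration, x$mean_isi, x$sd_isi, x$seed))
  invisible(x)
}

#' Probe geometry for synthetic sessions
#'
#' Each synthetic "detector" carries one short-separation channel and one
#' long-separation channel which share the same patch of scalp (so
#' short-separation regression is informative).
#'
#' @param n_detectors number of detectors.
#' @param ss_separation short channel separation, mm (default 8).
#' @param ls_separation long channel separation, mm (default 30).
#' @return data.frame with columns `detector`, `separation`, `role`.
#' @export
flow_geometry <- function(n_detectors, ss_separation = 8,
                          ls_separation = 30) {
  data.frame(detector = rep(seq_len(n_detectors), each = 2),
             separation = rep(c(ss_separation, ls_separation), n_detectors),
             role = rep(c("SS", "LS"), n_detectors))
}

#' Noise and physiology configuration for the resting generator
#'
#' Amplitudes of the scalp-dominant physiological processes (as HbO
#' concentration oscillations in the scalp layer, uM), the HbR coupling
#' ratio, the relative size of brain-layer background fluctuations, the
#' fraction of scalp variance that is local to a channel rather than shared
#' across the detector, and the detected-photon budget per sample that sets
#' the shot-noise level.
#'
#' @param cardiac_hbo,respiratory_hbo,lowfreq_hbo oscillation amplitudes,
#'   uM, at 1.1, 0.25 and 0.1 Hz.
#' @param drift_sd random-walk drift increment sd, uM per sample.
#' @param hbr_ratio scalp HbR = `hbr_ratio` x scalp HbO.
#' @param brain_frac brain-layer background amplitude relative to scalp.
#' @param local_frac fraction of scalp-process variance private to each
#'   channel (models scalp heterogeneity across the head; 0 makes SS
#'   regression perfect).
#' @param photons_ss,photons_ls detected photons per sample for SS and
#'   non-SS channels (`Inf` disables shot noise).
#' @return list of class `"resting_noise"`.
#' @export
resting_noise <- function(cardiac_hbo = 0.8, respiratory_hbo = 0.5,
                          lowfreq_hbo = 1.0, drift_sd = 0.03,
                          hbr_ratio = -0.3, brain_frac = 0.15,
                          local_frac = 0.3,
                          photons_ss = 1e6, photons_ls = 1e5) {
  structure(list(cardiac_hbo = cardiac_hbo,
                 respiratory_hbo = respiratory_hbo,
                 lowfreq_hbo = lowfreq_hbo, drift_sd = drift_sd,
                 hbr_ratio = hbr_ratio, brain_frac = brain_frac,
                 local_frac = local_frac,
                 photons_ss = photons_ss, photons_ls = photons_ls),
            class = "resting_noise")
}

# one scalp-physiology HbO trace (uM) on time grid tt
.physio_trace <- function(tt, cfg, nt) {
  cfg$cardiac_hbo * sin(2 * pi * 1.1 * tt + runif(1, 0, 2 * pi)) +
    cfg$respiratory_hbo * sin(2 * pi * 0.25 * tt + runif(1, 0, 2 * pi)) +
    cfg$lowfreq_hbo * sin(2 * pi * 0.1 * tt + runif(1, 0, 2 * pi)) +
    cumsum(rnorm(nt, 0, cfg$drift_sd))
}

#' Simulate a resting moment time series
#'
#' Emulates the statistical structure of resting TD-fNIRS moment
#' recordings: scalp-layer hemodynamic fluctuations (cardiac ~1.1 Hz,
#' respiratory ~0.25 Hz, low-frequency ~0.1 Hz, random-walk drift) shared
#' between the channels of a detector plus a smaller local component,
#' smaller independent brain-layer background fluctuations, all
#' forward-projected onto the three moments of every channel and wavelength
#' through the two-layer sensitivities of the lookup table, plus additive
#' per-sample measurement noise drawn from the theoretical shot-noise
#' covariance at the configured photon budget.
#'
#' @param geometry a [flow_geometry()] data.frame.
#' @param table a [build_lookup_table()] covering all separations at the
#'   baseline absorptions of both wavelengths.
#' @param duration seconds (default 300).
#' @param sample_rate Hz (default 7; a warning is issued below 2.2 Hz where
#'   the cardiac line aliases).
#' @param noise a [resting_noise()] configuration.
#' @param seed integer seed; output is fully determined by seed + params.
#' @param wavelengths nm (default `c(690, 850)`).
#' @param scalp_thickness superficial-layer thickness, mm (default 13).
#' @return A [moment_time_series()] with attribute `"forward"` holding the
#'   per-channel two-layer sensitivities, baseline absorptions, shot-noise
#'   covariances, photon budgets and the generator configuration.
#' @export
simulate_resting <- function(geometry, table, duration = 300,
                             sample_rate = 7, noise = resting_noise(),
                             seed = 1, wavelengths = c(690, 850),
                             scalp_thickness = 13) {
  if (sample_rate <= 2 * 1.1) {
    warning("sample rate below twice the cardiac frequency; cardiac physiology will alias")
  }
  nt <- round(duration * sample_rate)
  tt <- (seq_len(nt) - 1) / sample_rate
  nch <- nrow(geometry)
  nw <- length(wavelengths)
  mua0 <- vapply(wavelengths, baseline_absorption, numeric(1))

  # per-channel/wavelength two-layer sensitivities and shot-noise covariances
  sens <- array(NA_real_, c(nch, nw, 3, 2),
                dimnames = list(NULL, NULL, c("M0", "M1", "M2"),
                                c("scalp", "brain")))
  zt <- array(NA_real_, c(nch, nw, 3, 3))
  photons <- ifelse(classify_separation(geometry$separation) == "SS",
                    noise$photons_ss, noise$photons_ls)
  for (ch in seq_len(nch)) {
    for (wi in seq_len(nw)) {
      tl <- interp_two_layer(table, geometry$separation[ch], mua0[wi],
                             scalp_thickness)
      sens[ch, wi, , 1] <- tl$scalp
      sens[ch, wi, , 2] <- tl$brain
      if (is.finite(photons[ch])) {
        zt[ch, wi, , ] <- channel_shot_noise(table, geometry$separation[ch],
                                             mua0[wi], photons[ch])
      } else {
        zt[ch, wi, , ] <- 0
      }
    }
  }

  values <- array(0, c(nch, nw, 3, nt))
  with_seed(seed, {
    for (d in unique(geometry$detector)) {
      chs <- which(geometry$detector == d)
      shared <- .physio_trace(tt, noise, nt)
      brain_cfg <- noise
      brain_cfg$cardiac_hbo <- noise$cardiac_hbo * noise$brain_frac
      brain_cfg$respiratory_hbo <- noise$respiratory_hbo * noise$brain_frac
      brain_cfg$lowfreq_hbo <- noise$lowfreq_hbo * noise$brain_frac
      brain_cfg$drift_sd <- noise$drift_sd * noise$brain_frac
      brain_hbo <- .physio_trace(tt, brain_cfg, nt)
      for (ch in chs) {
        local <- .physio_trace(tt, noise, nt)
        scalp_hbo <- sqrt(1 - noise$local_frac) * shared +
          sqrt(noise$local_frac) * local
        scalp_hbr <- noise$hbr_ratio * scalp_hbo
        brain_hbr <- noise$hbr_ratio * brain_hbo
        for (wi in seq_len(nw)) {
          dmua_s <- hb_to_mua(scalp_hbo, scalp_hbr, wavelengths[wi])
          dmua_b <- hb_to_mua(brain_hbo, brain_hbr, wavelengths[wi])
          for (n in 1:3) {
            values[ch, wi, n, ] <- sens[ch, wi, n, 1] * dmua_s +
              sens[ch, wi, n, 2] * dmua_b
          }
          if (is.finite(photons[ch])) {
            cholz <- chol(zt[ch, wi, , ] +
                            diag(1e-300, 3))  # guard exact zeros
            eps <- t(cholz) %*% matrix(rnorm(3 * nt), 3, nt)
            for (n in 1:3) {
              values[ch, wi, n, ] <- values[ch, wi, n, ] + eps[n, ]
            }
          }
        }
      }
    }
  })

  out <- moment_time_series(values, separations = geometry$separation,
                            wavelengths = wavelengths,
                            sample_rate = sample_rate,
                            detectors = geometry$detector)
  attr(out, "forward") <- list(sens = sens, zt = zt, mua0 = mua0,
                               photons = photons, geometry = geometry,
                               noise = noise, seed = seed,
                               scalp_thickness = scalp_thickness)
  out
}

#' Augment a resting series with a known synthetic HRF
#'
#' Converts the HRF concentration curves to brain-layer absorption changes
#' by the Beer-Lambert relation, convolves them with the stimulus onset
#' train, forward-projects through each augmented channel's brain-layer
#' moment sensitivities, and adds the result to the mean-subtracted resting
#' series. By default every channel with separation under
#' `max_separation` (34 mm) is augmented — including the short-separation
#' channels, whose brain sensitivity is small but not zero.
#'
#' @param resting a [simulate_resting()] output (mean subtraction is applied
#'   here).
#' @param hrf a [make_hrf()] object.
#' @param train a [make_stimulus_train()] object.
#' @param augment_ss also inject the HRF into SS channels (default TRUE;
#'   set FALSE for a short-separation regressor guaranteed clean of
#'   response).
#' @param max_separation only channels below this separation (mm) receive
#'   the HRF.
#' @return Object of class `"synthetic_session"`: `resting` (mean
#'   subtracted), `augmented`, `truth` (HRF, train, injected concentration
#'   time courses and the exact added moment perturbation array), and the
#'   generator parameters.
#' @export
augment <- function(resting, hrf, train, augment_ss = TRUE,
                    max_separation = 34) {
  stopifnot(inherits(resting, "moment_time_series"),
            inherits(hrf, "canonical_hrf"),
            inherits(train, "stimulus_train"))
  fwd <- attr(resting, "forward")
  if (is.null(fwd)) {
    stop("`resting` must carry forward-model sensitivities (use simulate_resting)")
  }
  nt <- dim(resting$values)[4]
  fs <- resting$sample_rate
  tt <- (seq_len(nt) - 1) / fs

  # mean-subtract the resting series
  base <- resting
  mean_arr <- apply(resting$values, c(1, 2, 3), mean)
  base$values <- sweep(resting$values, c(1, 2, 3), mean_arr)

  # HRF resampled onto the session grid (t >= 0 part) and convolved with
  # the onset impulse train
  hgrid <- seq(0, max(hrf$time), by = 1 / fs)
  h_hbo <- approx(hrf$time, hrf$hbo, xout = hgrid, yleft = 0, yright = 0)$y
  h_hbr <- approx(hrf$time, hrf$hbr, xout = hgrid, yleft = 0, yright = 0)$y
  impulse <- numeric(nt)
  idx <- round(train$onsets * fs) + 1
  idx <- idx[idx >= 1 & idx <= nt]
  for (i in idx) impulse[i] <- impulse[i] + 1
  conv_trunc <- function(h) {
    full <- convolve(impulse, rev(h), type = "open")
    full[seq_len(nt)]
  }
  resp_hbo <- conv_trunc(h_hbo)
  resp_hbr <- conv_trunc(h_hbr)

  cls <- resting$channel_class
  aug_ch <- which(resting$separations < max_separation &
                    (augment_ss | cls != "SS"))

  added <- array(0, dim(resting$values))
  nw <- dim(resting$values)[2]
  for (wi in seq_len(nw)) {
    dmua_b <- hb_to_mua(resp_hbo, resp_hbr, resting$wavelengths[wi])
    for (ch in aug_ch) {
      for (n in 1:3) {
        added[ch, wi, n, ] <- fwd$sens[ch, wi, n, 2] * dmua_b
      }
    }
  }
  augmented <- base
  augmented$values <- base$values + added
  attr(augmented, "forward") <- fwd

  structure(list(resting = base, augmented = augmented,
                 truth = list(hrf = hrf, train = train,
                              response_hbo = resp_hbo,
                              response_hbr = resp_hbr,
                              added = added,
                              augmented_channels = aug_ch),
                 params = list(augment_ss = augment_ss,
                               max_separation = max_separation,
                               scale = hrf$scale,
                               scalp_thickness = fwd$scalp_thickness,
                               seed_resting = fwd$seed,
                               seed_train = train$seed)),
            class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  d <- dim(x$augmented$values)
  cat(sprintf("synthetic session: %d channels, %d samples @ %.3g Hz, HRF scale %.3g, %d onsets\n",
              d[1], d[4], x$augmented$sample_rate, x$truth$hrf$scale,
              length(x$truth$train$onsets)))
  cat(sprintf("  augmented channels: %s\n",
              paste(x$truth$augmented_channels, collapse = ", ")))
  invisible(x)
}
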