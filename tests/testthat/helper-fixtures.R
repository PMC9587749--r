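# shared fixtures, built once per test session and cached

.fixtures <- new.env(parent = emptyenv())

# desk-scale lookup table at the two geometry separations (8 and 30 mm),
# absorption grid covering the baseline absorptions at 690 and 850 nm;
# photon counts chosen for ~5e3 (SS) / ~1e3 (LS) detected photons
desk_table <- function() {
  if (is.null(.fixtures$table)) {
    .fixtures$table <- build_lookup_table(
      tissue_model(), separations = c(8, 30),
      absorptions = seq(0.009, 0.03, by = 0.003),
      n_photons = c(3e5, 1.5e6), seed = 101, keep_records = TRUE)
  }
  .fixtures$table
}

# noise configuration that silences every stochastic component
silent_noise <- function() {
  resting_noise(cardiac_hbo = 0, respiratory_hbo = 0, lowfreq_hbo = 0,
                drift_sd = 0, brain_frac = 0, local_frac = 0,
                photons_ss = Inf, photons_ls = Inf)
}

# noise-free session with on-grid, exactly periodic onsets (7 Hz grid)
noise_free_session <- function(n_detectors = 1, duration = 300, scale = 1,
                               augment_ss = TRUE) {
  geom <- flow_geometry(n_detectors)
  resting <- simulate_resting(geom, desk_table(), duration = duration,
                              noise = silent_noise(), seed = 1)
  train <- stimulus_train(onsets = seq(7, duration - 19, by = 21), duration)
  augment(resting, make_hrf(scale), train, augment_ss = augment_ss)
}

# default-physiology session (the benchmark conditions)
default_session <- function(n_detectors = 2, duration = 300, scale = 1,
                            seed = 11) {
  geom <- flow_geometry(n_detectors)
  resting <- simulate_resting(geom, desk_table(), duration = duration,
                              seed = seed)
  train <- make_stimulus_train(duration, seed = seed + 1)
  augment(resting, make_hrf(scale), train)
}

# simple DTOF shapes for covariance checks (bin times in seconds)
dtof_shapes <- function(n_bins = 120, total = 1e6) {
  tt <- seq(50e-12, by = 25e-12, length.out = n_bins)
  shape <- list(
    exponential = exp(-tt / 0.5e-9),
    bimodal = exp(-((tt - 0.6e-9) / 0.15e-9)^2) +
      0.6 * exp(-((tt - 1.8e-9) / 0.3e-9)^2),
    narrow = exp(-((tt - 1e-9) / 0.05e-9)^2)
  )
  lapply(shape, function(s) dtof(tt, total * s / sum(s)))
}

# diffusion-approximation time-resolved reflectance for a semi-infinite
# medium (extrapolated-boundary dipole); independent oracle for the MC
diffusion_tpsf <- function(t, rho, mua, musp, n_tissue = 1.4) {
  v <- 2.99792458e11 / n_tissue       # mm/s
  D <- 1 / (3 * musp)
  z0 <- 1 / musp
  rd <- -1.44 / n_tissue^2 + 0.71 / n_tissue + 0.668 + 0.0636 * n_tissue
  A <- (1 + rd) / (1 - rd)
  zb <- 2 * A * D
  t^(-5 / 2) * exp(-mua * v * t - rho^2 / (4 * D * v * t)) *
    (z0 * exp(-z0^2 / (4 * D * v * t)) +
       (z0 + 2 * zb) * exp(-(z0 + 2 * zb)^2 / (4 * D * v * t)))
}
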