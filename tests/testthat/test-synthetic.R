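test_that("canonical HRF amplitudes scale from the 0.6/-0.2 uM reference", {
  h1 <- make_hrf(1)
  expect_equal(max(h1$hbo), 0.6)
  expect_equal(min(h1$hbr), -0.2)
  expect_true(all(h1$hbo[h1$time <= 0] == 0))
  expect_true(all(h1$hbr[h1$time <= 0] == 0))
  expect_equal(h1$hbr, -h1$hbo / 3)
  # returned to under 5% of peak by the end of the epoch
  expect_lt(abs(h1$hbo[length(h1$hbo)]) / max(h1$hbo), 0.05)

  h3 <- make_hrf(3)
  expect_equal(max(h3$hbo), 1.8)
  expect_equal(h3$hbo, 3 * h1$hbo)

  h0 <- make_hrf(0)
  expect_true(all(h0$hbo == 0) && all(h0$hbr == 0))
  expect_error(make_hrf(-1), "non-negative")
})

test_that("stimulus trains have the configured interval statistics", {
  # zero interval spread: exactly uniform spacing
  tr0 <- make_stimulus_train(300, sd_isi = 0, seed = 3)
  expect_equal(diff(tr0$onsets), rep(21, length(tr0$onsets) - 1))

  tr <- make_stimulus_train(300, seed = 4)
  expect_true(all(diff(tr$onsets) > 0))
  expect_true(all(tr$onsets >= 0 & tr$onsets < 300))
  expect_identical(tr$onsets, make_stimulus_train(300, seed = 4)$onsets)

  # law of large numbers on the interval mean: one long train
  trL <- make_stimulus_train(21 * 10500, seed = 5)
  isi <- diff(trL$onsets)
  expect_gt(length(isi), 1e4)
  expect_equal(mean(isi), 21, tolerance = 0.01)

  # a 5-minute recording at the defaults typically holds 14 repetitions
  counts <- vapply(1:200,
                   function(s) length(make_stimulus_train(300,
                                                          seed = s)$onsets),
                   numeric(1))
  expect_true(all(abs(counts - 14) <= 2))
  expect_equal(round(mean(counts)), 14)

  expect_error(make_stimulus_train(300, sd_isi = -1), "non-negative")
  expect_error(make_stimulus_train(10, mean_isi = 21), "exceed")
})

test_that("resting generator is deterministic and silences cleanly", {
  geom <- flow_geometry(1)
  a <- simulate_resting(geom, desk_table(), duration = 30, seed = 8)
  b <- simulate_resting(geom, desk_table(), duration = 30, seed = 8)
  expect_identical(a$values, b$values)

  z <- simulate_resting(geom, desk_table(), duration = 30,
                        noise = silent_noise(), seed = 8)
  expect_true(all(z$values == 0))

  expect_warning(simulate_resting(geom, desk_table(), duration = 10,
                                  sample_rate = 2, seed = 8), "alias")
})

test_that("short and long channels of a detector share scalp physiology", {
  geom <- flow_geometry(2)
  mts <- simulate_resting(geom, desk_table(), duration = 300, seed = 21)
  # M0 of the SS and LS channel on detector 1 (850 nm)
  ss <- mts$values[1, 2, 1, ]
  ls <- mts$values[2, 2, 1, ]
  expect_gt(cor(ss, ls), 0.7)
  # channels on different detectors are far less correlated
  ls_other <- mts$values[4, 2, 1, ]
  expect_lt(abs(cor(ls, ls_other)), 0.5)
})

test_that("shot-noise-only simulation reproduces the configured covariance", {
  geom <- flow_geometry(1)
  nn <- silent_noise()
  nn$photons_ss <- 1e6
  nn$photons_ls <- 1e5
  mts <- simulate_resting(geom, desk_table(), duration = 300, noise = nn,
                          seed = 31)
  fwd <- attr(mts, "forward")
  for (ch in 1:2) {
    Ze <- suppressWarnings(empirical_covariance(mts, channels = ch,
                                                wavelength_index = 2))
    Zt <- fwd$zt[ch, 2, , ]
    for (n in 1:3) {
      expect_equal(Ze[n, n], Zt[n, n], tolerance = 0.10)
    }
  }
})

test_that("augmentation adds exactly the stored ground-truth perturbation", {
  session <- default_session(n_detectors = 1, seed = 41)
  expect_equal(session$augmented$values - session$resting$values,
               session$truth$added)
  # resting series is mean subtracted
  expect_lt(max(abs(apply(session$resting$values, c(1, 2, 3), mean))), 1e-12)
  # zero HRF: augmented equals resting
  geom <- flow_geometry(1)
  resting <- simulate_resting(geom, desk_table(), duration = 60, seed = 42)
  s0 <- augment(resting, make_hrf(0), make_stimulus_train(60, seed = 1))
  expect_equal(s0$augmented$values, s0$resting$values)
})

test_that("augmentation respects channel eligibility", {
  # a channel outside the table hull is refused outright
  geom_bad <- data.frame(detector = 1, separation = 40, role = "VLS")
  expect_error(simulate_resting(geom_bad, desk_table(), duration = 60,
                                seed = 2), "hull")
  geom <- flow_geometry(1)
  resting <- simulate_resting(geom, desk_table(), duration = 60,
                              noise = silent_noise(), seed = 2)
  tr <- stimulus_train(c(7, 28), 60)
  s_all <- augment(resting, make_hrf(1), tr, augment_ss = TRUE)
  s_ls <- augment(resting, make_hrf(1), tr, augment_ss = FALSE)
  expect_equal(s_all$truth$augmented_channels, 1:2)
  expect_equal(s_ls$truth$augmented_channels, 2L)
  expect_true(all(s_ls$truth$added[1, , , ] == 0))
  expect_true(any(s_all$truth$added[1, , , ] != 0))
  # the SS channel receives far less response than the LS channel
  expect_lt(max(abs(s_all$truth$added[1, 2, 1, ])),
            0.1 * max(abs(s_all$truth$added[2, 2, 1, ])))
})

test_that("overlapping responses superpose linearly", {
  geom <- flow_geometry(1)
  resting <- simulate_resting(geom, desk_table(), duration = 60,
                              noise = silent_noise(), seed = 2)
  h <- make_hrf(1)
  s_both <- augment(resting, h, stimulus_train(c(10, 15), 60))
  s_a <- augment(resting, h, stimulus_train(10, 60))
  s_b <- augment(resting, h, stimulus_train(15, 60))
  expect_equal(s_both$truth$added, s_a$truth$added + s_b$truth$added)
})

test_that("response contrast grows with moment order on long channels", {
  session <- default_session(n_detectors = 2, seed = 51)
  ls <- 2  # LS channel of detector 1
  contrast <- vapply(1:3, function(n) {
    sd(session$truth$added[ls, 2, n, ]) /
      sd(session$resting$values[ls, 2, n, ])
  }, numeric(1))
  expect_lt(contrast[1], contrast[2])
  expect_lt(contrast[2], contrast[3])
})

test_that("moment series round-trips through JSON", {
  geom <- flow_geometry(1)
  mts <- simulate_resting(geom, desk_table(), duration = 20, seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  write_moment_series(mts, path)
  m2 <- read_moment_series(path)
  expect_equal(m2$values, mts$values)
  expect_equal(m2$separations, mts$separations)
  expect_equal(m2$sample_rate, mts$sample_rate)
  expect_equal(m2$channel_class, mts$channel_class)
})
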