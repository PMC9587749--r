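test_that("Monte Carlo runs are reproducible and conserve weight", {
  tm <- tissue_model()
  a <- run_mc(tm, 8, 2e4, seed = 99)
  b <- run_mc(tm, 8, 2e4, seed = 99)
  expect_identical(a$pathlengths, b$pathlengths)
  expect_identical(a$tof, b$tof)
  expect_gt(a$n_detected, 0)

  # zero absorption: all survival weights are exactly 1
  w0 <- tdmoments:::record_weights(a, rep(0, 20), include_roulette = FALSE)
  expect_true(all(w0 == 1))
  # detected weight cannot exceed photons launched
  expect_lte(sum(tdmoments:::record_weights(a, rep(0.01, 20))), a$n_launched)

  # per-photon pathlength bookkeeping is consistent with time of flight
  v <- 2.99792458e11 / tm$refractive_index
  expect_equal(rowSums(a$pathlengths), a$tof * v, tolerance = 1e-9)

  # raising any layer's absorption strictly decreases detected weight
  base_w <- sum(tdmoments:::record_weights(a, rep(0.01, 20)))
  for (j in c(1, 3, 6)) {
    mua <- rep(0.01, 20)
    mua[j] <- 0.02
    expect_lt(sum(tdmoments:::record_weights(a, mua)), base_w)
  }

  expect_error(run_mc(tm, 32, 10, seed = 1), "no photons detected")
  expect_error(run_mc(tm, 60, 100, seed = 1), "fit inside")
})

test_that("homogeneous-medium mean time of flight matches diffusion theory", {
  tab <- desk_table()
  rec <- tab$records[[which(tab$separations == 30)]]
  mua <- rep(0.01, 20)
  mv <- moments_from_records(rec, mua)
  tt <- seq(1e-12, 5e-9, by = 1e-12)
  w <- diffusion_tpsf(tt, rho = 30, mua = 0.01, musp = 1)
  m1_theory <- sum(tt * w) / sum(w)
  expect_equal(mv[["M1"]], m1_theory, tolerance = 0.10)
})

test_that("record moments agree with binned DTOF moments", {
  tab <- desk_table()
  rec <- tab$records[[which(tab$separations == 8)]]
  mua <- rep(0.012, 20)
  mv <- moments_from_records(rec, mua)
  # bin the weighted records at 5 ps and recompute through compute_moments
  w <- tdmoments:::record_weights(rec, mua)
  breaks <- seq(0, 5e-9, by = 5e-12)
  bin <- findInterval(rec$tof, breaks, rightmost.closed = TRUE)
  counts <- vapply(seq_len(length(breaks) - 1),
                   function(i) sum(w[bin == i]), numeric(1))
  keep <- counts > 0
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  # uniform-grid DTOF (zeros allowed on empty interior bins)
  d <- dtof(centers[seq_len(max(which(keep)))],
            counts[seq_len(max(which(keep)))])
  mb <- compute_moments(d)
  expect_equal(mb[["M1"]], mv[["M1"]], tolerance = 0.01)
  expect_equal(mb[["M2"]], mv[["M2"]], tolerance = 0.01)
})

test_that("analytic sensitivities match the finite-difference oracle", {
  tab <- desk_table()
  for (sep in c(8, 30)) {
    rec <- tab$records[[which(tab$separations == sep)]]
    mua <- rep(0.011, 20)
    S <- sensitivities_from_records(rec, mua)
    delta <- 1e-4
    for (j in c(1, 4, 9, 14)) {
      mp <- mua; mp[j] <- mp[j] + delta
      mm <- mua; mm[j] <- mm[j] - delta
      fd <- (as.numeric(moments_from_records(rec, mp))[1:3] -
               as.numeric(moments_from_records(rec, mm))[1:3]) / (2 * delta)
      expect_equal(S[, j], fd, tolerance = 0.01, ignore_attr = TRUE)
    }
    # sign pattern: positive M0 pathlengths, negative M1 sensitivity
    visited <- colSums(rec$pathlengths) > 0
    expect_true(all(S[1, visited] > 0))
    expect_true(all(S[2, which(visited)[1:10]] < 0))
    # unvisited layers have exactly zero sensitivity
    if (any(!visited)) expect_true(all(S[, !visited] == 0))
  }
})

test_that("sensitivity formulas agree with a hand-computed record set", {
  # two photons, two layers; weighted expectations done by hand
  rec <- structure(list(
    pathlengths = rbind(c(10, 0), c(6, 4)),
    tof = c(10, 10) / (2.99792458e11 / 1.4),   # both 10 mm total path
    roulette_weight = c(1, 1),
    n_launched = 100, n_detected = 2L
  ), class = "photon_records")
  mua <- c(0.01, 0.02)
  w <- as.numeric(exp(-rec$pathlengths %*% mua))
  p <- w / sum(w)
  S <- sensitivities_from_records(rec, mua)
  expect_equal(S[1, ], as.numeric(p %*% rec$pathlengths),
               ignore_attr = TRUE)
  # equal times of flight: timing moments cannot respond to absorption
  expect_equal(S[2, ], c(0, 0), ignore_attr = TRUE)
  expect_equal(S[3, ], c(0, 0), ignore_attr = TRUE)
})

test_that("lookup table interpolation is exact on nodes and linear between", {
  tab <- desk_table()
  mua_grid <- tab$absorptions
  tl_node <- interp_two_layer(tab, 30, mua_grid[2], scalp_thickness = 13)
  S <- tab$sens[, , which(tab$separations == 30), 2]
  expect_equal(tl_node$scalp, rowSums(S[, 1:13]))
  expect_equal(tl_node$brain, rowSums(S[, 14:20]))
  # scalp + brain equals the total over all layers exactly
  expect_equal(tl_node$scalp + tl_node$brain, rowSums(S))

  # midpoint of two absorption nodes: arithmetic mean of the node values
  mid <- (mua_grid[2] + mua_grid[3]) / 2
  tl_mid <- interp_two_layer(tab, 30, mid, 13)
  tl_a <- interp_two_layer(tab, 30, mua_grid[2], 13)
  tl_b <- interp_two_layer(tab, 30, mua_grid[3], 13)
  expect_equal(tl_mid$brain, (tl_a$brain + tl_b$brain) / 2)

  expect_error(interp_two_layer(tab, 40, 0.012, 13), "hull")
  expect_error(interp_two_layer(tab, 30, 0.05, 13), "hull")
  expect_error(interp_two_layer(tab, 30, 0.012, 25), "scalp_thickness")
})

test_that("a small grid builds, serialises and reloads exactly", {
  tab <- build_lookup_table(tissue_model(),
                            separations = c(6, 10, 14),
                            absorptions = seq(0.009, 0.03, by = 0.007),
                            n_photons = 2e4, seed = 5)
  expect_s3_class(tab, "sensitivity_table")
  expect_true(all(is.finite(tab$sens[, , !tab$flagged, ])))
  path <- withr::local_tempfile(fileext = ".json")
  write_sensitivity_table(tab, path)
  tab2 <- read_sensitivity_table(path)
  expect_equal(tab2$sens, tab$sens)
  expect_equal(tab2$moments, tab$moments)
  expect_equal(tab2$separations, tab$separations)
  expect_equal(tab2$provenance$n_photons, rep(2e4, 3))
})

test_that("baseline absorption reproduces the stated tissue composition", {
  expect_equal(baseline_absorption(850, water_fraction = 0, c_hbo = 0,
                                   c_hbr = 0), 0)
  # hand summation at 850 nm from the shipped extinction values:
  # 0.8 * 0.0043 + ln(10) * (1058e-7 * 30 + 691.32e-7 * 20)
  hand <- 0.8 * 0.0043 + log(10) * (1058e-7 * 30 + 691.32e-7 * 20)
  expect_equal(baseline_absorption(850), hand)
  # the 80% water / 30 uM HbO / 20 uM HbR composition lands inside the
  # simulated absorption grid at both wavelengths
  for (wl in c(690, 850)) {
    mua <- baseline_absorption(wl)
    expect_gte(mua, 0.009)
    expect_lte(mua, 0.03)
  }
  expect_error(baseline_absorption(500), "range")
})

test_that("brain sensitivity share grows with moment order at 30 mm", {
  tl <- interp_two_layer(desk_table(), 30, baseline_absorption(850), 13)
  share <- abs(tl$brain) / (abs(tl$brain) + abs(tl$scalp))
  expect_lt(share[1], share[2])
  expect_lt(share[2], share[3])
})
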