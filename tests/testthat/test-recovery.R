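random_pd <- function(n, seed = 1, scale = 1) {
  set.seed(seed)
  A <- matrix(rnorm(n * n), n)
  scale * (crossprod(A) + diag(n))
}

test_that("scaled WLS estimator equals the textbook estimator", {
  set.seed(10)
  X <- matrix(rnorm(12), 6, 2)
  Z <- random_pd(6, seed = 2)
  # identity scaling: straight comparison with (X'Z^-1X)^-1 X'Z^-1
  ref <- solve(t(X) %*% solve(Z) %*% X) %*% t(X) %*% solve(Z)
  est <- scaled_wls_estimator(X, Z, k = rep(1, 6))
  expect_equal(unclass(est), ref, tolerance = 1e-10, ignore_attr = TRUE)

  # arbitrary positive diagonal scaling leaves the estimator unchanged
  for (s in 1:5) {
    k <- 10^runif(6, -3, 3)
    estk <- scaled_wls_estimator(X, Z, k = k)
    expect_equal(unclass(estk), ref, tolerance = 1e-8, ignore_attr = TRUE)
  }

  # the default scaling handles moments at their natural magnitudes,
  # where the unscaled normal equations are numerically hopeless
  D <- diag(rep(c(1, 1e-12, 1e-24), each = 2))
  Xm <- D %*% X
  Zm <- D %*% Z %*% D
  estm <- scaled_wls_estimator(Xm, Zm)
  expect_equal(unclass(estm %*% Xm), diag(2), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("two-layer inversion recovers its own forward data exactly", {
  tab <- desk_table()
  mua0 <- baseline_absorption(850)
  X <- rbind(
    do.call(rbind, lapply(1:3, function(n) {
      tl8 <- interp_two_layer(tab, 8, mua0, 13)
      tl30 <- interp_two_layer(tab, 30, mua0, 13)
      rbind(c(tl8$scalp[n], tl8$brain[n]),
            c(tl30$scalp[n], tl30$brain[n]))
    })))
  set.seed(3)
  nt <- 50
  truth <- rbind(scalp = rnorm(nt, 0, 1e-4), brain = rnorm(nt, 0, 1e-4))
  Y <- X %*% truth
  # covariances at physical moment scales: Var(Mn) ~ (1, 1e-12, 1e-24)^2
  D <- diag(rep(c(1, 1e-12, 1e-24), each = 2))
  for (Z in list(D %*% D, D %*% random_pd(6, seed = 4) %*% D)) {
    rec <- td_moment_inversion(Y, X, Z)
    expect_equal(unclass(rec), unclass(truth), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  # single-distance variant: 3 equations, 2 unknowns
  X1 <- X[c(2, 4, 6), ]
  rec1 <- td_moment_inversion(X1 %*% truth, X1,
                              diag(c(1, 1e-24, 1e-48)))
  expect_equal(unclass(rec1), unclass(truth), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("block averaging recovers periodic templates and shrinks noise", {
  fs <- 7
  tau <- seq(-2, 18, by = 1 / fs)
  template <- pmax(0, sin(pi * pmax(tau, 0) / 10))
  # exactly periodic signal, onsets on the sample grid
  onsets <- seq(7, 280, by = 21)
  nt <- 300 * fs
  x <- numeric(nt)
  tt <- (seq_len(nt) - 1) / fs
  for (o in onsets) {
    idx <- round((o + tau) * fs) + 1
    x[idx] <- x[idx] + approx(tau, template, xout = tau)$y
  }
  ba <- block_average(x, onsets, fs)
  tmpl_adj <- template - mean(template[tau <= 0])
  expect_equal(ba$mean, tmpl_adj, tolerance = 1e-12)
  expect_equal(ba$n_epochs, length(onsets))

  # single epoch: the epoch itself minus its baseline
  ba1 <- block_average(x, onsets[3], fs)
  expect_equal(ba1$n_epochs, 1)
  expect_equal(ba1$mean, tmpl_adj, tolerance = 1e-12)

  expect_error(block_average(x, 299, fs), "no complete epoch")

  # white noise: epoch-mean variance shrinks about 1/n_epochs
  set.seed(6)
  reps <- vapply(1:40, function(i) {
    z <- rnorm(nt)
    sd(block_average(z, onsets, fs)$mean)
  }, numeric(1))
  expect_equal(mean(reps), 1 / sqrt(length(onsets)), tolerance = 0.2)
})

test_that("noise-free session round-trips through the moment inversion", {
  session <- noise_free_session()
  truth <- session$truth$hrf
  for (m in c("td_ls_ss", "td_ls")) {
    rec <- recover_hrf(session, 1, method = m, covariance = "identity")
    expect_equal(rec$time, truth$time)
    expect_equal(rec$hbo, truth$hbo, tolerance = 1e-9)
    expect_equal(rec$hbr, truth$hbr, tolerance = 1e-9)
  }
  # TD-SS inverts the same forward model from the short channel alone
  rec_ss <- recover_hrf(session, 1, method = "td_ss",
                        covariance = "identity")
  expect_equal(rec_ss$hbo, truth$hbo, tolerance = 1e-6)
})

test_that("CW block average recovers data generated under its own model", {
  session <- noise_free_session()
  series <- session$augmented
  fs <- series$sample_rate
  # rebuild the M0 rows as a uniform absorption change seen through the
  # full mean pathlength (the CW forward model)
  for (wi in 1:2) {
    dmua <- hb_to_mua(session$truth$response_hbo,
                      session$truth$response_hbr,
                      series$wavelengths[wi])
    for (ch in 1:2) {
      L <- tdmoments:::cw_pathlength(series, ch, wi)
      series$values[ch, wi, 1, ] <- L * dmua
    }
  }
  session$augmented <- series
  rec <- tdmoments:::recover_cw_block_average(session, 1, "ls",
                                              lowpass = NULL)
  truth <- session$truth$hrf
  expect_equal(rec$hbo, truth$hbo, tolerance = 1e-9)
  expect_equal(rec$hbr, truth$hbr, tolerance = 1e-9)
  rec_ss <- tdmoments:::recover_cw_block_average(session, 1, "ss",
                                                 lowpass = NULL)
  expect_equal(rec_ss$hbo, truth$hbo, tolerance = 1e-9)
})

test_that("low-pass filtering attenuates above the 0.7 Hz cutoff", {
  fs <- 7
  tt <- seq(0, 60, by = 1 / fs)
  slow <- sin(2 * pi * 0.1 * tt)
  fast <- sin(2 * pi * 2 * tt)
  expect_gt(sd(tdmoments:::lowpass_filter(slow, fs)) / sd(slow), 0.95)
  expect_lt(sd(tdmoments:::lowpass_filter(fast, fs)) / sd(fast), 0.05)
})

test_that("CW GLM recovers exact basis coefficients with SS regression", {
  session <- noise_free_session()
  series <- session$augmented
  fs <- series$sample_rate
  nt <- dim(series$values)[4]
  tt <- (seq_len(nt) - 1) / fs
  onsets <- session$truth$train$onsets
  R <- tdmoments:::convolved_bases(tt, onsets)
  set.seed(12)
  beta_true <- rnorm(ncol(R), 0, 0.01)
  bss <- 1.7
  scalp <- sin(2 * pi * 0.1 * tt) * 0.02
  for (wi in 1:2) {
    series$values[1, wi, 1, ] <- scalp
    series$values[2, wi, 1, ] <- R %*% beta_true + bss * scalp
  }
  session$augmented <- series
  rec <- tdmoments:::recover_cw_glm(session, 1)
  for (wi in 1:2) {
    expect_equal(unname(rec$info$beta[[wi]]),
                 c(beta_true, bss), tolerance = 1e-9)
  }
})

test_that("Kronecker-structured GLS equals the dense solve on a toy problem", {
  set.seed(13)
  nt <- 20; nb <- 5; p <- 2 + 2 * nb
  U_blocks <- lapply(1:6, function(i) matrix(rnorm(nt * p), nt, p))
  beta_true <- rnorm(p)
  Z <- random_pd(6, seed = 14)
  Y_blocks <- lapply(U_blocks, function(U) as.numeric(U %*% beta_true))

  # dense oracle: materialise C = Z (x) I and solve the full GLS
  U <- do.call(rbind, U_blocks)
  Y <- unlist(Y_blocks)
  Cinv <- solve(kronecker(Z, diag(nt)))
  beta_dense <- solve(t(U) %*% Cinv %*% U, t(U) %*% Cinv %*% Y)
  beta_kron <- wls_kron_solve(U_blocks, Y_blocks, Z)
  expect_equal(as.numeric(beta_kron), as.numeric(beta_dense),
               tolerance = 1e-8)
  # and both recover the generating coefficients exactly (noise free)
  expect_equal(as.numeric(beta_kron), beta_true, tolerance = 1e-9)

  # noisy observations: still matches the dense solve
  Yn <- lapply(Y_blocks, function(y) y + rnorm(nt, 0, 0.1))
  beta_dense2 <- solve(t(U) %*% Cinv %*% U,
                       t(U) %*% Cinv %*% unlist(Yn))
  expect_equal(as.numeric(wls_kron_solve(U_blocks, Yn, Z)),
               as.numeric(beta_dense2), tolerance = 1e-8)
})

test_that("moment GLM recovers a noise-free session to high fidelity", {
  # the SS channel is kept clean of response here: with zero noise a
  # response-bearing SS regressor is exactly collinear with the temporal
  # bases and the split between them is indeterminate
  session <- noise_free_session(augment_ss = FALSE)
  rec <- td_glm(session, 1, covariance = "identity")
  truth <- session$truth$hrf
  # the double-gamma response is not inside the Gaussian basis span, so
  # recovery is near-exact rather than machine-exact
  expect_gt(cor(rec$hbo, truth$hbo), 0.999)
  expect_gt(cor(rec$hbr, truth$hbr), 0.999)
  expect_equal(max(rec$hbo), 0.6, tolerance = 0.05)
  # coefficient layout: two SS couplings then interleaved HbO/HbR
  expect_length(rec$info$beta, 2 + 2 * 21)
})

test_that("long-channel selection picks the usable channel closest to 30 mm", {
  mk <- function(seps) {
    vals <- array(0, c(length(seps), 2, 3, 10))
    moment_time_series(vals, separations = seps, sample_rate = 7,
                       detectors = rep(1, length(seps)))
  }
  expect_equal(tdmoments:::select_ls_channel(mk(c(8, 29, 31)), 1), 2L)
  expect_equal(tdmoments:::select_ls_channel(mk(c(8, 33, 28)), 1), 3L)
  # ties break toward the smaller separation
  expect_equal(tdmoments:::select_ls_channel(mk(c(8, 32, 28)), 1), 3L)
  # channels at or beyond 34 mm are never eligible
  expect_error(tdmoments:::select_ls_channel(mk(c(8, 35)), 1), "usable")
  expect_error(tdmoments:::select_ss_channel(mk(c(30, 31)), 1), "short")
})
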