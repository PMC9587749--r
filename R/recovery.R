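#' Scaled weighted-least-squares estimator
#'
#' Computes the WLS estimator matrix in its numerically stabilised form
#' \deqn{X^* = ((kX)^T (kZk)^{-1} kX)^{-1} (kX)^T (kZk)^{-1} k,}
#' which is algebraically identical to the textbook
#' `(X' Z^-1 X)^-1 X' Z^-1` but conditions the inversions by first putting
#' all moments on a comparable scale. The default diagonal scaling is 1 for
#' M0 rows, 1e12 for M1 and 1e24 for M2, matching the natural magnitudes of
#' moment changes (O(1), O(1e-12 s), O(1e-24 s^2)).
#'
#' @param X forward matrix (`3 Nc` x p), moment-major row order.
#' @param Z moment covariance (`3 Nc` x `3 Nc`).
#' @param k diagonal scaling as a vector of length `3 Nc`, or NULL for the
#'   default per-moment scales.
#' @param tol relative eigenvalue cutoff for the pseudo-inversions.
#' @return Estimator matrix (p x `3 Nc`) with attribute
#'   `"condition_numbers"` for the two inversions.
#' @export
scaled_wls_estimator <- function(X, Z, k = NULL, tol = 1e-12) {
  X <- as.matrix(X)
  Z <- as.matrix(Z)
  m <- nrow(X)
  if (nrow(Z) != m || ncol(Z) != m) stop("dim(Z) must match nrow(X)")
  if (is.null(k)) {
    if (m %% 3 != 0) stop("default scaling needs nrow(X) divisible by 3")
    k <- rep(c(1, 1e12, 1e24), each = m / 3)
  }
  if (any(k <= 0)) stop("`k` must be positive")
  kX <- k * X
  kZk <- (k %o% k) * Z
  Zinv <- pseudo_inverse(kZk, tol = tol)
  A <- t(kX) %*% Zinv %*% kX
  Ainv <- pseudo_inverse(A, tol = tol)
  if (attr(Ainv, "rank") < ncol(X)) {
    stop(sprintf("normal-equation matrix is rank deficient (rank %d < %d); condition number %.3g",
                 attr(Ainv, "rank"), ncol(X),
                 attr(Ainv, "condition_number")))
  }
  est <- Ainv %*% t(kX) %*% Zinv * rep(k, each = ncol(X))
  attr(est, "condition_numbers") <- c(Z = attr(Zinv, "condition_number"),
                                      normal = attr(Ainv, "condition_number"))
  est
}

#' Multidistance two-layer moment inversion
#'
#' Covariance-weighted least-squares separation of scalp- and brain-layer
#' absorption changes from stacked moment time courses:
#' `d_mua(t) = X* ' Y(t)` with the estimator of [scaled_wls_estimator()].
#' Rows of `Y` and `X` are stacked moment-major (all channels' M0, then M1,
#' then M2). With a single channel the same system is solved with `Nc = 1`
#' (3 equations, 2 unknowns).
#'
#' @param Y `3 Nc` x `Nt` matrix of moment changes.
#' @param X `3 Nc` x 2 sensitivity matrix, columns (scalp, brain).
#' @param Z `3 Nc` x `3 Nc` moment covariance.
#' @param k optional scaling vector (see [scaled_wls_estimator()]).
#' @return 2 x `Nt` matrix with rows `scalp` and `brain` (absorption
#'   change, mm^-1).
#' @export
td_moment_inversion <- function(Y, X, Z, k = NULL) {
  est <- scaled_wls_estimator(X, Z, k = k)
  out <- est %*% Y
  rownames(out) <- c("scalp", "brain")
  attr(out, "condition_numbers") <- attr(est, "condition_numbers")
  out
}

#' Block average around stimulus onsets
#'
#' Averages epochs of a single time course around each onset on a common
#' epoch time base (linear interpolation onto `onset + epoch grid`), then
#' subtracts the mean of the `[-2, 0]` s baseline window. Only epochs fully
#' inside the recording are used.
#'
#' @param x numeric time course.
#' @param onsets onset times, seconds.
#' @param sample_rate Hz.
#' @param epoch epoch window relative to onset, seconds (default
#'   `c(-2, 18)`).
#' @param baseline baseline window for the subtraction (default `c(-2, 0)`).
#' @return list with `time` (epoch grid), `mean` (baseline-adjusted epoch
#'   mean) and `n_epochs`.
#' @export
block_average <- function(x, onsets, sample_rate, epoch = c(-2, 18),
                          baseline = c(-2, 0)) {
  nt <- length(x)
  tt <- (seq_len(nt) - 1) / sample_rate
  tau <- seq(epoch[1], epoch[2], by = 1 / sample_rate)
  ok <- onsets + epoch[1] >= 0 & onsets + epoch[2] <= tt[nt]
  if (!any(ok)) stop("no complete epoch inside the recording")
  eps <- vapply(onsets[ok],
                function(o) approx(tt, x, xout = o + tau)$y,
                numeric(length(tau)))
  avg <- rowMeans(eps)
  avg <- avg - mean(avg[tau >= baseline[1] & tau <= baseline[2]])
  list(time = tau, mean = avg, n_epochs = sum(ok))
}

# zero-phase 4th-order Butterworth low pass (NULL cutoff = no filtering)
lowpass_filter <- function(x, sample_rate, cutoff = 0.7) {
  if (is.null(cutoff)) return(x)
  bf <- signal::butter(4, cutoff / (sample_rate / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

# recovered HRF object ------------------------------------------------------

recovered_hrf <- function(time, hbo, hbr, method, covariance_source,
                          detector, info = list()) {
  bl <- time >= -2 & time <= 0
  if (any(bl)) {
    hbo <- hbo - mean(hbo[bl])
    hbr <- hbr - mean(hbr[bl])
  }
  structure(list(time = time, hbo = hbo, hbr = hbr, method = method,
                 covariance_source = covariance_source,
                 detector = detector, info = info),
            class = "recovered_hrf")
}

#' @export
print.recovered_hrf <- function(x, ...) {
  cat(sprintf("recovered HRF (%s, covariance %s, detector %s): HbO peak %.3g uM, HbR extreme %.3g uM\n",
              x$method, x$covariance_source,
              as.character(x$detector), max(x$hbo), min(x$hbr)))
  invisible(x)
}

#' @export
plot.recovered_hrf <- function(x, truth = NULL, ...) {
  yl <- range(c(x$hbo, x$hbr, if (!is.null(truth)) c(truth$hbo, truth$hbr)))
  plot(x$time, x$hbo, type = "l", col = "red3", ylim = yl,
       xlab = "time since onset [s]", ylab = "concentration change [uM]",
       main = x$method, ...)
  lines(x$time, x$hbr, col = "blue3")
  if (!is.null(truth)) {
    lines(truth$time, truth$hbo, col = "orange", lty = 2)
    lines(truth$time, truth$hbr, col = "purple", lty = 2)
  }
  abline(h = 0, lty = 3)
  invisible(x)
}

# channel selection ---------------------------------------------------------

# usable long channel: separation < 34 mm, not SS, closest to 30 mm;
# ties broken toward the smaller separation
select_ls_channel <- function(series, detector) {
  geom_det <- which(series$detectors == detector)
  cand <- geom_det[series$separations[geom_det] < 34 &
                     series$channel_class[geom_det] != "SS"]
  if (!length(cand)) stop("detector has no usable long channel")
  sep <- series$separations[cand]
  d <- abs(sep - 30)
  best <- cand[order(d, sep)][1]
  best
}

select_ss_channel <- function(series, detector) {
  geom_det <- which(series$detectors == detector)
  cand <- geom_det[series$channel_class[geom_det] == "SS"]
  if (!length(cand)) stop("detector has no short-separation channel")
  cand[1]
}

# covariance assembly -------------------------------------------------------

# 3Nc x 3Nc covariance for a channel subset at one wavelength
assemble_covariance <- function(series, channels, wavelength_index,
                                source = c("ze", "zt", "identity")) {
  source <- match.arg(source)
  nc <- length(channels)
  if (source == "ze") {
    return(empirical_covariance(series, channels, wavelength_index))
  }
  Z <- matrix(0, 3 * nc, 3 * nc)
  if (source == "zt") {
    fwd <- attr(series, "forward")
    if (is.null(fwd)) stop("series carries no theoretical shot-noise model")
    for (ci in seq_len(nc)) {
      z3 <- fwd$zt[channels[ci], wavelength_index, , ]
      for (n in 1:3) for (m in 1:3) {
        Z[(n - 1) * nc + ci, (m - 1) * nc + ci] <- z3[n, m]
      }
    }
  } else {
    # "identity" weights the moment-scaled data equally: unit variance per
    # scaled moment, i.e. (1, 1e-24, 1e-48) at natural units. A literal
    # identity at natural units would put all weight on M0 alone.
    diag(Z) <- rep(c(1, 1e-24, 1e-48), each = nc)
  }
  moment_covariance(Z, source = if (source == "zt") "theoretical" else "identity")
}

# sensitivity stack X (3Nc x 2) for a channel subset at one wavelength
assemble_sensitivity <- function(series, channels, wavelength_index) {
  fwd <- attr(series, "forward")
  if (is.null(fwd)) stop("series carries no forward-model sensitivities")
  nc <- length(channels)
  X <- matrix(0, 3 * nc, 2)
  for (ci in seq_len(nc)) {
    for (n in 1:3) {
      X[(n - 1) * nc + ci, ] <- fwd$sens[channels[ci], wavelength_index, n, ]
    }
  }
  colnames(X) <- c("scalp", "brain")
  X
}

# method implementations ----------------------------------------------------

# multidistance (or single-distance) TD moment recovery for one detector
recover_td_moments <- function(session, detector,
                               channels = c("ls", "ss"),
                               covariance = c("ze", "zt", "identity"),
                               epoch = c(-2, 18)) {
  covariance <- match.arg(covariance)
  series <- session$augmented
  chs <- vapply(channels, function(role) {
    if (role == "ls") select_ls_channel(series, detector)
    else select_ss_channel(series, detector)
  }, integer(1))
  fs <- series$sample_rate
  onsets <- session$truth$train$onsets
  nw <- length(series$wavelengths)
  ba <- vector("list", nw)
  conds <- NULL
  for (wi in seq_len(nw)) {
    Y <- stacked_moment_rows(series, chs, wi)
    X <- assemble_sensitivity(series, chs, wi)
    Z <- assemble_covariance(series, chs, wi, covariance)
    mu <- td_moment_inversion(Y, X, Z)
    conds <- rbind(conds, attr(mu, "condition_numbers"))
    ba[[wi]] <- block_average(mu["brain", ], onsets, fs, epoch)
  }
  hb <- mua_to_hb(ba[[1]]$mean, ba[[2]]$mean, series$wavelengths)
  method <- paste0("TD-", paste(toupper(channels), collapse = "+"))
  recovered_hrf(ba[[1]]$time, hb$hbo, hb$hbr, method = method,
                covariance_source = covariance, detector = detector,
                info = list(channels = chs, condition_numbers = conds,
                            n_epochs = ba[[1]]$n_epochs))
}

# effective pathlength for CW conversions: total mean partial pathlength,
# i.e. the M0 sensitivity summed over all layers (mm)
cw_pathlength <- function(series, channel, wavelength_index) {
  fwd <- attr(series, "forward")
  if (is.null(fwd)) stop("series carries no forward-model sensitivities")
  sum(fwd$sens[channel, wavelength_index, 1, ])
}

# CW block average of one channel's M0 (optical density analogue)
recover_cw_block_average <- function(session, detector, channel_role = "ls",
                                     lowpass = 0.7, epoch = c(-2, 18)) {
  series <- session$augmented
  ch <- if (channel_role == "ls") select_ls_channel(series, detector)
        else select_ss_channel(series, detector)
  fs <- series$sample_rate
  onsets <- session$truth$train$onsets
  nw <- length(series$wavelengths)
  ba <- vector("list", nw)
  for (wi in seq_len(nw)) {
    od <- series$values[ch, wi, 1, ]
    od <- lowpass_filter(od, fs, lowpass)
    mua_eq <- od / cw_pathlength(series, ch, wi)
    ba[[wi]] <- block_average(mua_eq, onsets, fs, epoch)
  }
  hb <- mua_to_hb(ba[[1]]$mean, ba[[2]]$mean, series$wavelengths)
  method <- if (channel_role == "ls") "CW-BA" else "CW-SS"
  recovered_hrf(ba[[1]]$time, hb$hbo, hb$hbr, method = method,
                covariance_source = "none", detector = detector,
                info = list(channel = ch, lowpass = lowpass,
                            n_epochs = ba[[1]]$n_epochs))
}

# Gaussian temporal bases on the epoch grid: spacing and sd both 1 s
gaussian_bases <- function(tau, spacing = 1, sd = 1, epoch = c(-2, 18)) {
  centers <- seq(epoch[1], epoch[2], by = spacing)
  G <- outer(tau, centers, function(t, c) exp(-(t - c)^2 / (2 * sd^2)))
  G
}

# onset-convolved regressors: R[, k](t) = sum_onsets g_k(t - onset)
convolved_bases <- function(tt, onsets, spacing = 1, sd = 1,
                            epoch = c(-2, 18)) {
  centers <- seq(epoch[1], epoch[2], by = spacing)
  R <- matrix(0, length(tt), length(centers))
  for (o in onsets) {
    R <- R + outer(tt - o, centers,
                   function(t, c) exp(-(t - c)^2 / (2 * sd^2)))
  }
  R
}

# CW GLM with short-separation regression, fitted per wavelength
recover_cw_glm <- function(session, detector, epoch = c(-2, 18),
                           spacing = 1, sd = 1) {
  series <- session$augmented
  ls <- select_ls_channel(series, detector)
  ss <- select_ss_channel(series, detector)
  fs <- series$sample_rate
  nt <- dim(series$values)[4]
  tt <- (seq_len(nt) - 1) / fs
  onsets <- session$truth$train$onsets
  tau <- seq(epoch[1], epoch[2], by = 1 / fs)
  G_epoch <- gaussian_bases(tau, spacing, sd, epoch)
  R <- convolved_bases(tt, onsets, spacing, sd, epoch)
  nw <- length(series$wavelengths)
  mua_epoch <- vector("list", nw)
  betas <- vector("list", nw)
  for (wi in seq_len(nw)) {
    y <- series$values[ls, wi, 1, ]
    D <- cbind(R, series$values[ss, wi, 1, ])
    qrD <- qr(D)
    if (qrD$rank < ncol(D)) {
      bad <- setdiff(seq_len(ncol(D)), qrD$pivot[seq_len(qrD$rank)])
      stop(sprintf("CW GLM design is rank deficient (offending columns: %s)",
                   paste(bad, collapse = ", ")))
    }
    beta <- qr.coef(qrD, y)
    betas[[wi]] <- beta
    od_hrf <- G_epoch %*% beta[seq_len(ncol(R))]
    mua_epoch[[wi]] <- as.numeric(od_hrf) / cw_pathlength(series, ls, wi)
  }
  hb <- mua_to_hb(mua_epoch[[1]], mua_epoch[[2]], series$wavelengths)
  recovered_hrf(tau, hb$hbo, hb$hbr, method = "CW-GLM",
                covariance_source = "none", detector = detector,
                info = list(ls = ls, ss = ss, beta = betas))
}

#' Generalised least squares with Kronecker-structured covariance
#'
#' Solves `beta = (U' C^-1 U)^-1 U' C^-1 Y` where the covariance of the
#' stacked observation vector is `C = Z (x) I(Nt)` (block-constant across
#' time). The `6 Nt x 6 Nt` matrix is never materialised: with `U_a` the
#' a'th row block of the design and `Y_a` the a'th observation block, the
#' normal equations reduce to
#' `sum_ab Zinv[a,b] U_a' U_b` and `sum_ab Zinv[a,b] U_a' Y_b`.
#'
#' @param U_blocks list of design-matrix row blocks (each `Nt x p`).
#' @param Y_blocks list of observation blocks (each length `Nt`).
#' @param Z block covariance (`length(U_blocks)` square).
#' @param tol pseudo-inverse relative cutoff.
#' @return coefficient vector (length p) with attribute
#'   `"condition_numbers"`.
#' @export
wls_kron_solve <- function(U_blocks, Y_blocks, Z, tol = 1e-12) {
  nb <- length(U_blocks)
  stopifnot(length(Y_blocks) == nb, nrow(Z) == nb, ncol(Z) == nb)
  Zinv <- pseudo_inverse(as.matrix(Z), tol = tol)
  p <- ncol(U_blocks[[1]])
  A <- matrix(0, p, p)
  rhs <- numeric(p)
  for (a in seq_len(nb)) {
    for (b in seq_len(nb)) {
      if (Zinv[a, b] == 0) next
      A <- A + Zinv[a, b] * crossprod(U_blocks[[a]], U_blocks[[b]])
      rhs <- rhs + Zinv[a, b] * as.numeric(crossprod(U_blocks[[a]],
                                                     Y_blocks[[b]]))
    }
  }
  Ainv <- pseudo_inverse(A, tol = tol)
  beta <- as.numeric(Ainv %*% rhs)
  attr(beta, "condition_numbers") <- c(Z = attr(Zinv, "condition_number"),
                                       normal = attr(Ainv, "condition_number"))
  beta
}

#' General linear model on TD moments with short-separation regression
#'
#' Jointly fits, for one detector, the three moments of the long channel at
#' both wavelengths to (i) a scalp regressor derived from the
#' short-separation channel's M0 — scaled per moment and wavelength by the
#' sensitivity ratio `Sn_scalp(lambda, rho_LS) / S0_scalp(lambda, rho_SS)` —
#' and (ii) onset-convolved Gaussian temporal bases scaled by
#' `Sn_brain(lambda, rho_LS) * eps_HbX(lambda)`, yielding HbO and HbR
#' response coefficients simultaneously from all six moment/wavelength
#' series. The generalised least-squares covariance is block-constant over
#' time (`C = Z (x) I`), solved through [wls_kron_solve()] without forming
#' `C`; moment scaling (1, 1e12, 1e24) is applied throughout for
#' conditioning. Coefficient layout:
#' `[beta_SS(l1), beta_SS(l2), beta_1^HbO, beta_1^HbR, beta_2^HbO, ...]`.
#'
#' @param session a [augment()] synthetic session.
#' @param detector detector id.
#' @param covariance `"ze"` (empirical, from the fitted series, white-noise
#'   assumption in time), `"zt"` (theoretical shot noise) or `"identity"`.
#' @param epoch epoch window, seconds.
#' @param spacing,sd Gaussian basis spacing and width, seconds.
#' @return `"recovered_hrf"` with the full coefficient vector in
#'   `info$beta`.
#' @export
td_glm <- function(session, detector, covariance = c("ze", "zt", "identity"),
                   epoch = c(-2, 18), spacing = 1, sd = 1) {
  covariance <- match.arg(covariance)
  series <- session$augmented
  ls <- select_ls_channel(series, detector)
  ss <- select_ss_channel(series, detector)
  fwd <- attr(series, "forward")
  fs <- series$sample_rate
  nt <- dim(series$values)[4]
  tt <- (seq_len(nt) - 1) / fs
  onsets <- session$truth$train$onsets
  R <- convolved_bases(tt, onsets, spacing, sd, epoch)
  nb <- ncol(R)
  p <- 2 + 2 * nb
  wl <- series$wavelengths

  # row blocks ordered (n, lambda): (0,1), (0,2), (1,1), (1,2), (2,1), (2,2)
  kscale <- c(1, 1, 1e12, 1e12, 1e24, 1e24)
  U_blocks <- vector("list", 6)
  Y_blocks <- vector("list", 6)
  Y6 <- matrix(0, nt, 6)
  blk <- 0
  for (n in 1:3) {
    for (wi in 1:2) {
      blk <- blk + 1
      eps <- extinction_coefficients(wl[wi])
      scalp_reg <- fwd$sens[ls, wi, n, 1] *
        series$values[ss, wi, 1, ] / fwd$sens[ss, wi, 1, 1]
      U <- matrix(0, nt, p)
      U[, wi] <- scalp_reg
      sb <- fwd$sens[ls, wi, n, 2]
      hbo_cols <- 2 + seq(1, 2 * nb, by = 2)
      hbr_cols <- hbo_cols + 1
      U[, hbo_cols] <- sb * log(10) * eps[["hbo"]] * R
      U[, hbr_cols] <- sb * log(10) * eps[["hbr"]] * R
      U_blocks[[blk]] <- U * kscale[blk]
      y <- series$values[ls, wi, n, ]
      Y_blocks[[blk]] <- y * kscale[blk]
      Y6[, blk] <- y
    }
  }

  Zk <- switch(covariance,
    ze = {
      Z <- cov(Y6)
      (kscale %o% kscale) * Z
    },
    zt = {
      Z <- matrix(0, 6, 6)
      for (wi in 1:2) {
        z3 <- fwd$zt[ls, wi, , ]
        for (n in 1:3) for (m in 1:3) {
          Z[(n - 1) * 2 + wi, (m - 1) * 2 + wi] <- z3[n, m]
        }
      }
      (kscale %o% kscale) * Z
    },
    identity = diag(6)
  )

  beta <- wls_kron_solve(U_blocks, Y_blocks, Zk)
  tau <- seq(epoch[1], epoch[2], by = 1 / fs)
  G_epoch <- gaussian_bases(tau, spacing, sd, epoch)
  hbo_cols <- 2 + seq(1, 2 * nb, by = 2)
  hbo <- as.numeric(G_epoch %*% beta[hbo_cols])
  hbr <- as.numeric(G_epoch %*% beta[hbo_cols + 1])
  recovered_hrf(tau, hbo, hbr, method = "TD-GLM",
                covariance_source = covariance, detector = detector,
                info = list(ls = ls, ss = ss, beta = beta,
                            condition_numbers = attr(beta,
                                                     "condition_numbers")))
}

#' Recover the HRF for one detector with a chosen method
#'
#' Front end dispatching to the individual recovery implementations. All
#' methods return a baseline-adjusted `"recovered_hrf"` on the `[-2, 18]` s
#' epoch grid in concentration units (uM).
#'
#' Methods: `"cw_ba"` (CW block average of the long channel), `"cw_ss"`
#' (CW block average of the short channel), `"cw_glm"` (CW GLM with SS
#' regression), `"td_ss"`, `"td_ls"`, `"td_ls_ss"` (single/multidistance
#' covariance-weighted moment inversion plus block averaging) and
#' `"td_glm"` (the moment GLM).
#'
#' @param session a [augment()] synthetic session.
#' @param detector detector id.
#' @param method one of the methods above.
#' @param covariance covariance source for the TD methods: `"ze"`
#'   (empirical), `"zt"` (theoretical shot noise) or `"identity"` (equal
#'   weight per moment-scaled observation).
#' @param epoch epoch window, seconds.
#' @return `"recovered_hrf"`.
#' @export
recover_hrf <- function(session, detector,
                        method = c("td_ls_ss", "td_ls", "td_ss", "td_glm",
                                   "cw_ba", "cw_ss", "cw_glm"),
                        covariance = c("ze", "zt", "identity"),
                        epoch = c(-2, 18)) {
  method <- match.arg(method)
  covariance <- match.arg(covariance)
  switch(method,
         td_ls_ss = recover_td_moments(session, detector, c("ls", "ss"),
                                       covariance, epoch),
         td_ls = recover_td_moments(session, detector, "ls", covariance,
                                    epoch),
         td_ss = recover_td_moments(session, detector, "ss", covariance,
                                    epoch),
         td_glm = td_glm(session, detector, covariance, epoch),
         cw_ba = recover_cw_block_average(session, detector, "ls",
                                          epoch = epoch),
         cw_ss = recover_cw_block_average(session, detector, "ss",
                                          epoch = epoch),
         cw_glm = recover_cw_glm(session, detector, epoch))
}
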