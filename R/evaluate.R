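#' Score a recovered HRF against the ground truth
#'
#' Resamples the truth onto the recovered time base, baseline-adjusts both
#' curves on `[-2, 0]` s, and reports the RMSE (uM) and the Fisher
#' z-transformed Pearson correlation per chromophore. A zero-variance
#' recovered curve has an undefined correlation and is flagged; a
#' correlation at machine `|r| = 1` (noise-free recovery) is clipped at
#' `atanh(1 - 1e-12)` and flagged.
#'
#' @param recovered a `"recovered_hrf"`.
#' @param truth a [make_hrf()] object (the session ground truth).
#' @param scale HRF scale annotation for the record (default from truth).
#' @return data.frame with one row per chromophore: `detector`, `method`,
#'   `covariance_source`, `chromophore`, `rmse`, `r`, `fisher_z`, `scale`,
#'   `flagged`.
#' @export
evaluate_recovery <- function(recovered, truth, scale = truth$scale) {
  stopifnot(inherits(recovered, "recovered_hrf"),
            inherits(truth, "canonical_hrf"))
  tau <- recovered$time
  bl <- tau >= -2 & tau <= 0
  score_one <- function(rec_curve, truth_curve) {
    tr <- approx(truth$time, truth_curve, xout = tau, yleft = 0,
                 yright = 0)$y
    tr <- tr - mean(tr[bl])
    rc <- rec_curve - mean(rec_curve[bl])
    rmse <- sqrt(mean((rc - tr)^2))
    if (sd(rc) == 0 || sd(tr) == 0) {
      return(c(rmse = rmse, r = NA_real_, z = NA_real_, flagged = 1))
    }
    r <- cor(rc, tr)
    z <- fisher_transform_clipped(r)
    c(rmse = rmse, r = r, z = as.numeric(z),
      flagged = as.numeric(attr(z, "clipped")))
  }
  s_hbo <- score_one(recovered$hbo, truth$hbo)
  s_hbr <- score_one(recovered$hbr, truth$hbr)
  data.frame(detector = recovered$detector,
             method = recovered$method,
             covariance_source = recovered$covariance_source,
             chromophore = c("HbO", "HbR"),
             rmse = c(s_hbo[["rmse"]], s_hbr[["rmse"]]),
             r = c(s_hbo[["r"]], s_hbr[["r"]]),
             fisher_z = c(s_hbo[["z"]], s_hbr[["z"]]),
             scale = scale,
             flagged = c(s_hbo[["flagged"]], s_hbr[["flagged"]]) > 0)
}

#' Paired comparison of two evaluation sets
#'
#' Two-sided paired Student t-test on per-channel metric differences between
#' two methods, matched on detector and chromophore.
#'
#' @param a,b evaluation data.frames from [evaluate_recovery()] /
#'   [run_method_suite()] (one method each), or plain numeric vectors
#'   already paired.
#' @param metric `"fisher_z"` or `"rmse"` (ignored for numeric input).
#' @param chromophore restrict to `"HbO"` or `"HbR"` (default: both pooled).
#' @return One-row data.frame of class `"comparison_result"`: methods,
#'   metric, `mean_difference` (a minus b), `t`, `p`, `n`.
#' @export
paired_compare <- function(a, b, metric = c("fisher_z", "rmse"),
                           chromophore = NULL) {
  metric <- match.arg(metric)
  if (is.numeric(a) && is.numeric(b)) {
    xa <- a; xb <- b
    la <- "a"; lb <- "b"
  } else {
    if (!is.null(chromophore)) {
      a <- a[a$chromophore == chromophore, ]
      b <- b[b$chromophore == chromophore, ]
    }
    m <- merge(a, b, by = c("detector", "chromophore"),
               suffixes = c(".a", ".b"))
    xa <- m[[paste0(metric, ".a")]]
    xb <- m[[paste0(metric, ".b")]]
    la <- a$method[1]; lb <- b$method[1]
  }
  if (length(xa) != length(xb)) stop("paired design requires matched sets")
  keep <- is.finite(xa) & is.finite(xb)
  xa <- xa[keep]; xb <- xb[keep]
  if (length(xa) < 2) stop("need at least two matched pairs")
  d <- xa - xb
  if (sd(d) == 0) stop("zero-variance differences; paired t-test degenerate")
  tt <- t.test(xa, xb, paired = TRUE)
  structure(data.frame(method_a = la, method_b = lb, metric = metric,
                       mean_difference = mean(d),
                       t = unname(tt$statistic),
                       p = tt$p.value, n = length(d)),
            class = c("comparison_result", "data.frame"))
}

#' Percent improvement between mean metrics
#'
#' For correlation-type metrics, `100 * (a - b) / |b|` (larger is better).
#' For RMSE-type metrics, the reported number is the percent decrease,
#' `100 * (b - a) / |b|` (a smaller RMSE in `a` is a positive decrease).
#'
#' @param a,b mean metric values (the improvement of `a` over `b`).
#' @param type `"correlation"` or `"rmse"`.
#' @return percent, scalar.
#' @export
percent_improvement <- function(a, b, type = c("correlation", "rmse")) {
  type <- match.arg(type)
  if (b == 0) stop("reference metric is zero; percent change undefined")
  if (type == "correlation") 100 * (a - b) / abs(b)
  else 100 * (b - a) / abs(b)
}

#' Apply a set of recovery methods to every detector of a session
#'
#' Per-method failures are isolated: a failing detector/method pair is
#' recorded in the failure manifest and the remaining work proceeds.
#'
#' @param session a [augment()] synthetic session.
#' @param methods character vector of method names (see [recover_hrf()]).
#' @param covariance covariance source for the TD methods.
#' @param detectors detector ids (default: all in the session geometry).
#' @return list with `recovered` (nested list method -> detector),
#'   `records` (combined evaluation data.frame) and `failures`.
#' @export
run_method_suite <- function(session, methods = c("cw_ba", "cw_ss", "cw_glm",
                                                  "td_ss", "td_ls",
                                                  "td_ls_ss", "td_glm"),
                             covariance = "ze", detectors = NULL) {
  stopifnot(inherits(session, "synthetic_session"))
  if (is.null(detectors)) {
    detectors <- unique(session$augmented$detectors)
  }
  recovered <- list()
  records <- list()
  failures <- list()
  for (m in methods) {
    recovered[[m]] <- list()
    for (d in detectors) {
      res <- tryCatch(recover_hrf(session, d, method = m,
                                  covariance = covariance),
                      error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1]] <-
          data.frame(method = m, detector = d,
                     message = conditionMessage(res))
      } else {
        recovered[[m]][[as.character(d)]] <- res
        records[[length(records) + 1]] <-
          evaluate_recovery(res, session$truth$hrf)
      }
    }
  }
  list(recovered = recovered,
       records = if (length(records)) do.call(rbind, records) else NULL,
       failures = if (length(failures)) do.call(rbind, failures) else NULL)
}
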