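#' Run the full synthetic benchmark
#'
#' End-to-end protocol: for each synthetic "subject" (an independent seed
#' group sharing the physiology configuration) a resting session is
#' simulated, augmented with the canonical HRF at each requested scale, all
#' requested recovery methods are applied to every detector under every
#' covariance source, and the recoveries are scored against ground truth.
#' The result is deterministic given `seed`.
#'
#' @param table a [build_lookup_table()] covering the geometry.
#' @param n_subjects number of independent seed groups (default 6).
#' @param n_detectors detectors per subject (default 20).
#' @param duration recording length, seconds (default 300).
#' @param sample_rate Hz (default 7).
#' @param scales HRF amplitude scales to test (default 1).
#' @param methods recovery methods (see [recover_hrf()]).
#' @param covariance_sources covariance sources applied to the TD methods
#'   (CW methods are covariance-free and run once).
#' @param noise a [resting_noise()] configuration.
#' @param seed master seed; subject s uses derived seeds
#'   `seed * 1000 + s` (resting) and `seed * 1000 + 500 + s` (train).
#' @return Object of class `"tdm_benchmark"`: `records` (one row per
#'   detector/method/chromophore), `summary` (mean RMSE and mean Fisher z
#'   per method/covariance/chromophore/scale), `comparisons` (paired
#'   t-tests between method pairs sharing a covariance source, plain plus
#'   Bonferroni-adjusted columns), `failures`, and the full parameter
#'   record.
#' @export
run_benchmark <- function(table, n_subjects = 6, n_detectors = 20,
                          duration = 300, sample_rate = 7, scales = 1,
                          methods = c("cw_ba", "cw_ss", "cw_glm", "td_ss",
                                      "td_ls", "td_ls_ss", "td_glm"),
                          covariance_sources = "ze",
                          noise = resting_noise(), seed = 1) {
  geometry <- flow_geometry(n_detectors)
  cw <- intersect(methods, c("cw_ba", "cw_ss", "cw_glm"))
  td <- setdiff(methods, cw)
  all_records <- list()
  failures <- list()
  for (s in seq_len(n_subjects)) {
    resting <- simulate_resting(geometry, table, duration = duration,
                                sample_rate = sample_rate, noise = noise,
                                seed = seed * 1000 + s)
    train <- make_stimulus_train(duration, seed = seed * 1000 + 500 + s)
    for (sc in scales) {
      session <- augment(resting, make_hrf(sc, sample_rate), train)
      run_one <- function(mets, cov_src) {
        if (!length(mets)) return()
        suite <- run_method_suite(session, mets, covariance = cov_src)
        if (!is.null(suite$records)) {
          rec <- suite$records
          rec$subject <- s
          all_records[[length(all_records) + 1]] <<- rec
        }
        if (!is.null(suite$failures)) {
          failures[[length(failures) + 1]] <<- suite$failures
        }
      }
      run_one(cw, "ze")
      for (cv in covariance_sources) run_one(td, cv)
    }
  }
  records <- do.call(rbind, all_records)
  summary <- stats::aggregate(cbind(rmse, fisher_z) ~
                                method + covariance_source + chromophore +
                                scale,
                              data = records, FUN = mean, na.rm = TRUE)
  comparisons <- benchmark_comparisons(records)
  structure(list(records = records, summary = summary,
                 comparisons = comparisons,
                 failures = if (length(failures)) do.call(rbind, failures)
                            else NULL,
                 params = list(n_subjects = n_subjects,
                               n_detectors = n_detectors,
                               duration = duration,
                               sample_rate = sample_rate, scales = scales,
                               methods = methods,
                               covariance_sources = covariance_sources,
                               noise = unclass(noise), seed = seed)),
            class = "tdm_benchmark")
}

# all pairwise paired t-tests between methods within a covariance source,
# per chromophore and metric; Bonferroni columns are an extension over the
# plain alpha = 0.05 tests
benchmark_comparisons <- function(records) {
  out <- list()
  key <- unique(records[, c("method", "covariance_source")])
  for (chrom in unique(records$chromophore)) {
    for (metric in c("fisher_z", "rmse")) {
      for (i in seq_len(nrow(key))) {
        for (j in seq_len(nrow(key))) {
          if (j <= i) next
          a <- records[records$method == key$method[i] &
                         records$covariance_source ==
                           key$covariance_source[i] &
                         records$chromophore == chrom, ]
          b <- records[records$method == key$method[j] &
                         records$covariance_source ==
                           key$covariance_source[j] &
                         records$chromophore == chrom, ]
          a$detector <- paste(a$subject, a$detector, a$scale)
          b$detector <- paste(b$subject, b$detector, b$scale)
          cmp <- tryCatch(paired_compare(a, b, metric),
                          error = function(e) NULL)
          if (is.null(cmp)) next
          cmp$chromophore <- chrom
          cmp$covariance_a <- key$covariance_source[i]
          cmp$covariance_b <- key$covariance_source[j]
          out[[length(out) + 1]] <- cmp
        }
      }
    }
  }
  if (!length(out)) return(NULL)
  cmp <- do.call(rbind, out)
  cmp$p_bonferroni <- pmin(1, cmp$p * nrow(cmp))
  cmp
}

#' @export
print.tdm_benchmark <- function(x, ...) {
  cat(sprintf("moment-recovery benchmark: %d subjects x %d detectors, %g s @ %g Hz, scales %s\n",
              x$params$n_subjects, x$params$n_detectors, x$params$duration,
              x$params$sample_rate,
              paste(x$params$scales, collapse = ", ")))
  cat("\nmean metrics by method:\n")
  print(x$summary, digits = 3)
  if (!is.null(x$failures)) {
    cat(sprintf("\n%d detector/method failures (see $failures)\n",
                nrow(x$failures)))
  }
  invisible(x)
}

#' @export
plot.tdm_benchmark <- function(x, chromophore = "HbO",
                               metric = "fisher_z", ...) {
  rec <- x$records[x$records$chromophore == chromophore, ]
  lab <- paste(rec$method, rec$covariance_source, sep = "/")
  boxplot(rec[[metric]] ~ lab, las = 2, xlab = "",
          ylab = sprintf("%s (%s)", metric, chromophore), ...)
  invisible(x)
}
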