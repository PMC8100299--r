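log_line <- function(verbose, stage, msg) {
  if (verbose) message(sprintf("[%s] %s", stage, msg))
  invisible(NULL)
}

#' Run the full processing and analysis pipeline
#'
#' Calibrates thresholds from the empty-room recording, processes every
#' subject recording into per-minute activity scores, assembles group curves,
#' and runs the four functional tests (activity GPF and F-max, velocity GPF
#' and F-max). Optionally writes the results bundle: per-subject scores CSV,
#' totals CSV, per-time-point summary CSV, results JSON, and a run log.
#'
#' @param config a [pipeline_config()].
#' @param recordings list of `radar_recording` objects (or a directory of
#'   recording containers).
#' @param labels data.frame `subject_id, group`.
#' @param empty empty-room `radar_recording` for calibration.
#' @param out_dir optional output directory; if NULL nothing is written.
#' @param verbose log progress (default FALSE).
#' @return list with `thresholds`, `series` (per-subject `qar_series`),
#'   `curves`, `velocity_curves`, `tests` (4 `fanova_result`s),
#'   `pointwise` (distribution summary at minutes 3, 7, 9, 11, 22) and
#'   `totals`.
#' @export
run_pipeline <- function(config, recordings, labels, empty, out_dir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(recordings)) {
    dirs <- list.dirs(recordings, recursive = FALSE)
    recordings <- lapply(dirs, read_recording)
  }
  t0 <- proc.time()["elapsed"]
  log_line(verbose, "calibrate", sprintf("empty room, %d frames", empty$n_frames))
  thresholds <- calibrate_threshold(empty, alpha = config$alpha,
                                    multiplier = config$threshold_multiplier,
                                    burn_in = config$burn_in)
  series <- lapply(recordings, function(rec) {
    res <- tryCatch(
      process_recording(rec, thresholds, alpha = config$alpha,
                        aggregate = config$aggregate),
      error = function(e) {
        stop_qar(sprintf("stage 'process', subject %s: %s",
                         rec$subject_id, conditionMessage(e)),
                 "qar_pipeline_error")
      })
    log_line(verbose, "process",
             sprintf("subject %s: total %.1f (%.1fs elapsed)", rec$subject_id,
                     res$total, proc.time()["elapsed"] - t0))
    res
  })
  names(series) <- vapply(series, `[[`, "", "subject_id")

  scores <- do.call(rbind, lapply(series, `[[`, "minute_scores"))
  rownames(scores) <- names(series)
  curves <- build_curves(scores, labels, dense_n = config$dense_n)
  vel <- velocity(curves)
  seeds <- split_seed(config$seed, 2L)
  log_line(verbose, "analyze", sprintf("B = %d permutations", config$n_resamples))
  move_tests <- fanova_tests(curves, config$n_resamples, seed = seeds[1])
  vel_tests <- fanova_tests(vel, config$n_resamples, seed = seeds[2])
  tests <- list(movement_gpf = move_tests$gpf, movement_fmax = move_tests$fmax,
                velocity_gpf = vel_tests$gpf, velocity_fmax = vel_tests$fmax)
  pw_times <- c(3, 7, 9, 11, 22)
  pw_times <- pw_times[pw_times >= min(curves$knots) &
                         pw_times <= max(curves$knots)]
  if (length(pw_times) == 0) pw_times <- max(curves$knots)
  pw <- pointwise_distribution(curves, times = pw_times)
  totals <- vapply(series, `[[`, 0, "total")

  bundle <- list(thresholds = thresholds, series = series, curves = curves,
                 velocity_curves = vel, tests = tests, pointwise = pw,
                 totals = totals, config = config)
  if (!is.null(out_dir)) write_results_bundle(bundle, labels, out_dir, verbose)
  bundle
}

write_results_bundle <- function(bundle, labels, out_dir, verbose = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_qar_csv(bundle$series, file.path(out_dir, "qar_scores.csv"))
  write_totals_csv(bundle$series, file.path(out_dir, "qar_totals.csv"))
  write.csv(bundle$pointwise$means,
            file.path(out_dir, "pointwise_means.csv"), row.names = FALSE,
            quote = FALSE)
  results <- lapply(bundle$tests, function(tst) {
    list(method = tst$method, curve_type = tst$curve_type,
         statistic = tst$statistic, p_value = tst$p_value,
         n_resamples = tst$n_resamples)
  })
  jsonlite::write_json(list(tests = results, seed = bundle$config$seed,
                            config = unclass(bundle$config)),
                       file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_lines <- c(
    sprintf("qaradar %s", as.character(utils::packageVersion("qaradar"))),
    sprintf("run at %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    sprintf("config: %s", jsonlite::toJSON(unclass(bundle$config),
                                           auto_unbox = TRUE)),
    sprintf("subjects: %s", paste(names(bundle$series), collapse = ", ")))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  log_line(verbose, "write", sprintf("results written to %s", out_dir))
  invisible(out_dir)
}
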