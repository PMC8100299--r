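RECORDING_FORMAT_VERSION <- "1.0"

#' Write / read a radar recording container
#'
#' A recording is stored as a directory holding a JSON sidecar
#' (`recording.json`: subject id, sensor ids, fps, shape, duration, format
#' version) plus one raw little-endian float32 matrix per sensor
#' (`<sensor_id>.f32`, row-major `n_frames x n_bins`). The format is
#' deliberately transparent: any tool that can read raw floats can read it.
#'
#' @param recording a `radar_recording`.
#' @param path directory to create/use.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns the `radar_recording` (bit-identical frames to what was written).
#' @export
write_recording <- function(recording, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(format_version = RECORDING_FORMAT_VERSION,
               subject_id = recording$subject_id,
               sensor_ids = recording$sensor_ids,
               fps = recording$fps,
               n_frames = recording$n_frames,
               n_bins = recording$n_bins,
               duration_minutes = recording$duration_minutes)
  jsonlite::write_json(meta, file.path(path, "recording.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (i in seq_along(recording$frames)) {
    con <- file(file.path(path, paste0(recording$sensor_ids[i], ".f32")), "wb")
    on.exit(close(con), add = TRUE)
    writeBin(as.vector(t(recording$frames[[i]])), con, size = 4L,
             endian = "little")
    close(con)
    on.exit()                       # already closed
  }
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  sidecar <- file.path(path, "recording.json")
  if (!file.exists(sidecar))
    stop_qar(sprintf("missing sidecar %s", sidecar), "qar_format_error")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (f in c("format_version", "subject_id", "sensor_ids", "fps", "n_frames",
              "n_bins", "duration_minutes")) {
    if (is.null(meta[[f]]))
      stop_qar(sprintf("sidecar missing field '%s'", f), "qar_format_error")
  }
  frames <- vector("list", length(meta$sensor_ids))
  expected <- 4 * meta$n_frames * meta$n_bins
  for (i in seq_along(meta$sensor_ids)) {
    bin <- file.path(path, paste0(meta$sensor_ids[i], ".f32"))
    if (!file.exists(bin))
      stop_qar(sprintf("missing sensor file %s", bin), "qar_format_error")
    if (file.size(bin) != expected)
      stop_qar(sprintf(
        "corrupt file %s: %d bytes but sidecar n_frames x n_bins implies %d",
        bin, file.size(bin), expected), "qar_corrupt_error")
    con <- file(bin, "rb")
    v <- readBin(con, "numeric", n = meta$n_frames * meta$n_bins, size = 4L,
                 endian = "little")
    close(con)
    frames[[i]] <- matrix(v, meta$n_frames, meta$n_bins, byrow = TRUE)
  }
  new_radar_recording(frames, meta$fps, meta$sensor_ids, meta$subject_id,
                      meta$duration_minutes)
}

#' Pipeline configuration
#'
#' Tunables of the processing and analysis stages, with validation and
#' lossless JSON round-tripping.
#'
#' @param alpha clutter forgetting factor in (0, 1\].
#' @param threshold_multiplier SD multiplier for empty-room calibration.
#' @param burn_in calibration burn-in frames.
#' @param aggregate per-minute aggregation, `"mean"` or `"median"`.
#' @param n_resamples permutation replicates for the functional tests.
#' @param seed master seed.
#' @param dense_n dense-grid size for curve smoothing.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(alpha = 0.97, threshold_multiplier = 3,
                            burn_in = 100L, aggregate = "mean",
                            n_resamples = 1000L, seed = 1L, dense_n = 221L) {
  if (alpha <= 0 || alpha > 1)
    stop_qar("alpha must lie in (0, 1]", "qar_config_error")
  if (threshold_multiplier < 0 || burn_in < 0 || n_resamples < 1 || dense_n < 2)
    stop_qar("nonnegative threshold_multiplier/burn_in and positive n_resamples/dense_n required",
             "qar_config_error")
  if (!aggregate %in% c("mean", "median"))
    stop_qar("aggregate must be 'mean' or 'median'", "qar_config_error")
  structure(list(alpha = alpha, threshold_multiplier = threshold_multiplier,
                 burn_in = as.integer(burn_in), aggregate = aggregate,
                 n_resamples = as.integer(n_resamples), seed = as.integer(seed),
                 dense_n = as.integer(dense_n)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    stop_qar(sprintf("config file %s not found", path), "qar_config_error")
  do.call(pipeline_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Write / read per-subject activity score tables
#'
#' Long CSV with columns `subject_id, minute, qar_score` (minutes 1-based),
#' plus a totals CSV `subject_id, total`.
#'
#' @param series_list list of `qar_series`.
#' @param path CSV file path.
#' @return the path, invisibly (writers); a data.frame (reader).
#' @export
write_qar_csv <- function(series_list, path) {
  rows <- do.call(rbind, lapply(series_list, function(s) {
    data.frame(subject_id = s$subject_id,
               minute = seq_along(s$minute_scores),
               qar_score = s$minute_scores, stringsAsFactors = FALSE)
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_qar_csv
#' @export
write_totals_csv <- function(series_list, path) {
  rows <- data.frame(
    subject_id = vapply(series_list, `[[`, "", "subject_id"),
    total = vapply(series_list, `[[`, 0, "total"), stringsAsFactors = FALSE)
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_qar_csv
#' @export
read_qar_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "minute", "qar_score")
  if (!all(need %in% names(df)))
    stop_qar("curves CSV must have columns subject_id, minute, qar_score",
             "qar_format_error")
  df
}

#' Read a subject-to-group labels CSV (`subject_id, group`)
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_labels_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "group") %in% names(df)))
    stop_qar("labels CSV must have columns subject_id, group",
             "qar_format_error")
  df
}
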