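#' Adaptive clutter (background) state
#'
#' State of the exponential loopback filter that tracks the static background
#' return. With forgetting factor `alpha` close to 1 the clutter estimate
#' adapts slowly, so sustained motion is not absorbed into the background.
#'
#' @param clutter initial clutter estimate (numeric vector over bins).
#' @param alpha forgetting factor in \[0, 1\]. The pipeline requires
#'   `alpha > 0`: at exactly 0 the clutter estimate equals the current frame
#'   and the residual is identically zero.
#' @return an object of class `clutter_state`.
#' @export
clutter_state <- function(clutter, alpha = 0.97) {
  if (alpha < 0 || alpha > 1)
    stop_qar("alpha must lie in [0, 1]", "qar_parameter_error")
  if (any(!is.finite(clutter)))
    stop_qar("clutter must be finite", "qar_parameter_error")
  structure(list(alpha = alpha, clutter = as.numeric(clutter)),
            class = "clutter_state")
}

#' Remove static clutter from one frame
#'
#' Updates the background estimate first, then subtracts it:
#' `C_n = alpha * C_{n-1} + (1 - alpha) * x_n`, followed by
#' `y_n = x_n - C_n`. The update-then-subtract order is deliberate; its
#' degenerate consequence at `alpha = 0` (`y` identically zero) is part of the
#' contract.
#'
#' @param frame received frame `x_n` (numeric vector over bins).
#' @param state a [clutter_state()] carrying `C_{n-1}`.
#' @return list with `residual` (`y_n`) and `state` (carrying `C_n`).
#' @export
subtract_background <- function(frame, state) {
  if (length(frame) != length(state$clutter))
    stop_qar("frame and clutter lengths differ", "qar_shape_error")
  C_n <- state$alpha * state$clutter + (1 - state$alpha) * frame
  list(residual = frame - C_n, state = clutter_state(C_n, state$alpha))
}

# Whole-recording clutter removal: the same recursion applied down the frame
# axis, vectorized with the linear recursive filter
# C_n = alpha*C_{n-1} + (1-alpha)*x_n per bin. C_0 = first frame, so the
# filter starts converged to the static background.
subtract_background_matrix <- function(frames, alpha) {
  if (alpha <= 0 || alpha > 1)
    stop_qar("pipeline requires alpha in (0, 1]", "qar_parameter_error")
  n <- nrow(frames)
  C0 <- frames[1, ]
  if (alpha == 1) {
    C <- matrix(C0, n, ncol(frames), byrow = TRUE)
  } else {
    C <- sapply(seq_len(ncol(frames)), function(k) {
      as.numeric(stats::filter((1 - alpha) * frames[, k], alpha,
                               method = "recursive", init = C0[k]))
    })
  }
  frames - C
}

# Analytic-signal weights for length-n DFT: keep DC (and Nyquist for even n),
# double the positive frequencies, zero the negative ones.
analytic_weights <- function(n) {
  w <- numeric(n)
  if (n %% 2 == 0) {
    w[1] <- 1; w[n / 2 + 1] <- 1
    w[2:(n / 2)] <- 2
  } else {
    w[1] <- 1
    w[2:((n + 1) / 2)] <- 2
  }
  w
}

#' Hilbert envelope of a residual frame
#'
#' Magnitude of the analytic signal `y + i*H(y)`, computed via the FFT
#' (negative frequencies zeroed, positive frequencies doubled). The envelope
#' demodulates the carrier so that frame-to-frame amplitude changes reflect
#' movement rather than carrier phase.
#'
#' @param y real numeric vector (one clutter-removed frame), or a matrix
#'   (frames in rows) for the vectorized whole-recording form.
#' @return nonnegative envelope of the same shape.
#' @export
hilbert_envelope <- function(y) {
  if (any(!is.finite(y)))
    stop_qar("input to hilbert_envelope must be finite", "qar_numeric_error")
  if (is.matrix(y)) {
    n <- ncol(y)
    w <- analytic_weights(n)
    Z <- mvfft(t(y)) * w
    return(t(Mod(mvfft(Z, inverse = TRUE)) / n))
  }
  n <- length(y)
  z <- fft(fft(y) * analytic_weights(n), inverse = TRUE) / n
  Mod(z)
}

#' Calibrate per-sensor movement thresholds from an empty room
#'
#' Runs clutter removal and envelope extraction over an empty-room recording,
#' pools the absolute consecutive-frame envelope differences over all frames
#' (after a burn-in for clutter convergence) and bins, and sets
#' `T_i = mean + multiplier * SD` per sensor. With nobody present these
#' differences are pure receiver noise, so the threshold separates noise from
#' movement.
#'
#' @param empty a `radar_recording` of the empty room.
#' @param alpha clutter forgetting factor (must match the processing run).
#' @param multiplier SD multiplier (default 3).
#' @param burn_in frames discarded at the start (default 100; at least 1 frame
#'   must remain after it to form a difference).
#' @return an object of class `threshold_set`: per-sensor thresholds plus
#'   calibration metadata.
#' @export
calibrate_threshold <- function(empty, alpha = 0.97, multiplier = 3,
                                burn_in = 100L) {
  n_frames <- empty$n_frames
  if (n_frames - burn_in < 2)
    stop_qar("too few frames after burn-in to calibrate", "qar_calibration_error")
  thresholds <- vapply(empty$frames, function(fr) {
    y <- subtract_background_matrix(fr, alpha)
    A <- hilbert_envelope(y)
    d <- abs(diff(A[(burn_in + 1):n_frames, , drop = FALSE]))
    m <- mean(d)
    s <- sd(as.vector(d))
    max(0, m + multiplier * s)
  }, numeric(1))
  structure(list(thresholds = thresholds, n_frames = n_frames,
                 burn_in = as.integer(burn_in), multiplier = multiplier,
                 alpha = alpha, rule = "mean + multiplier * SD of pooled |dA|"),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("<threshold_set> %d sensor(s), rule '%s' (x%g), %d frames (burn-in %d)\n",
              length(x$thresholds), x$rule, x$multiplier, x$n_frames, x$burn_in))
  print(signif(x$thresholds, 4))
  invisible(x)
}

#' Detect per-bin movement between consecutive envelopes
#'
#' `g[k] = 1` iff `|A_n[k] - A_prev[k]| >= T` (the boundary counts as
#' movement).
#'
#' @param A_n,A_prev envelope rows of equal length.
#' @param threshold nonnegative scalar threshold.
#' @return integer 0/1 vector.
#' @export
detect_movement <- function(A_n, A_prev, threshold) {
  if (length(A_n) != length(A_prev))
    stop_qar("envelope rows differ in length", "qar_shape_error")
  if (threshold < 0)
    stop_qar("threshold must be >= 0", "qar_parameter_error")
  as.integer(abs(A_n - A_prev) >= threshold)
}

#' Count active bins in a movement mask row
#'
#' @param g binary (0/1) vector.
#' @return integer count of ones.
#' @export
frame_activity <- function(g) {
  if (!all(g %in% c(0, 1)))
    stop_qar("movement mask must be binary", "qar_contract_error")
  as.integer(sum(g))
}

#' Fuse per-sensor activity counts into one per-frame value
#'
#' Sample median across sensors (for an even number of sensors, the midpoint
#' of the two middle values); permutation-invariant in the sensor order. The
#' median, rather than the mean, downweights a sensor whose view of the
#' subject is blocked or whose radar cross-section differs.
#'
#' @param q numeric vector of per-sensor counts for one frame, or a matrix
#'   `n_sensors x n_frames` for the vectorized form (fused per column).
#' @return scalar median, or vector of per-frame medians.
#' @export
fuse_sensors <- function(q) {
  if (is.matrix(q)) {
    if (nrow(q) < 1) stop_qar("need >= 1 sensor", "qar_parameter_error")
    return(apply(q, 2L, median))
  }
  if (length(q) < 1) stop_qar("need >= 1 sensor", "qar_parameter_error")
  median(q)
}

#' Aggregate per-frame activity into per-minute scores
#'
#' Non-overlapping 60-second blocks of `fps * 60` frames; the score is the
#' block mean (or median, see `method`) of the per-frame values. A trailing
#' partial block is kept if it covers at least 30 seconds and dropped
#' otherwise, so a 22-minute recording (whose difference series is one frame
#' short of 22 full blocks) still yields exactly 22 scores.
#'
#' @param qar_per_frame per-frame fused activity values.
#' @param fps frames per second.
#' @param method `"mean"` (default) or `"median"` within each minute.
#' @return numeric vector of per-minute scores.
#' @export
aggregate_minutes <- function(qar_per_frame, fps, method = c("mean", "median")) {
  method <- match.arg(method)
  block <- round(fps * 60)
  n <- length(qar_per_frame)
  if (n < block / 2)
    stop_qar("series shorter than half a minute-block", "qar_aggregation_error")
  idx <- (seq_len(n) - 1L) %/% block
  sizes <- tabulate(idx + 1L)
  keep <- sizes >= block / 2            # partial trailing block: >= 30 s kept
  fun <- if (method == "mean") mean else median
  scores <- vapply(which(keep) - 1L,
                   function(b) fun(qar_per_frame[idx == b]), numeric(1))
  unname(scores)
}

#' Total activity over the session
#'
#' @param minute_scores per-minute scores.
#' @return their sum.
#' @export
total_activity <- function(minute_scores) {
  if (length(minute_scores) < 1)
    stop_qar("no minute scores", "qar_contract_error")
  sum(minute_scores)
}

#' Process one recording into an activity (QAR) series
#'
#' Full per-sensor chain -- adaptive clutter removal, Hilbert envelope,
#' thresholded consecutive-frame change detection, per-frame active-bin count
#' -- followed by median fusion across sensors and per-minute aggregation.
#' Deterministic for fixed inputs.
#'
#' @param recording a `radar_recording`.
#' @param thresholds a [calibrate_threshold()] result for the same sensor
#'   layout.
#' @param alpha clutter forgetting factor in (0, 1\] (default: the value the
#'   thresholds were calibrated with).
#' @param aggregate `"mean"` (default) or `"median"` within each minute.
#' @return an object of class `qar_series` with `per_sensor_counts`
#'   (`n_sensors x n_frames-1`), `qar_per_frame`, `minute_scores`, `total`,
#'   `fps` and `subject_id`.
#' @export
process_recording <- function(recording, thresholds, alpha = thresholds$alpha,
                              aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  S <- length(recording$frames)
  if (length(thresholds$thresholds) != S)
    stop_qar("sensor count differs between recording and thresholds",
             "qar_config_error")
  counts <- matrix(NA_integer_, S, recording$n_frames - 1L)
  for (i in seq_len(S)) {
    y <- subtract_background_matrix(recording$frames[[i]], alpha)
    A <- hilbert_envelope(y)
    d <- abs(diff(A))
    counts[i, ] <- as.integer(rowSums(d >= thresholds$thresholds[i]))
  }
  qar <- fuse_sensors(counts)
  minutes <- aggregate_minutes(qar, recording$fps, method = aggregate)
  structure(list(per_sensor_counts = counts, qar_per_frame = qar,
                 minute_scores = minutes, total = total_activity(minutes),
                 fps = recording$fps, subject_id = recording$subject_id),
            class = "qar_series")
}

#' @export
print.qar_series <- function(x, ...) {
  cat(sprintf("<qar_series> subject %s: %d per-frame values, %d minute scores, total %.2f\n",
              x$subject_id, length(x$qar_per_frame), length(x$minute_scores),
              x$total))
  invisible(x)
}
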