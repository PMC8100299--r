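#' Radar front-end configuration
#'
#' Describes the simulated impulse-radar front end: number of radially mounted
#' sensors, frame rate, number of range (delay) bins per frame, the shape of
#' the emitted pulse template and the receiver noise level.
#'
#' @param n_sensors number of sensors observing the subject (default 4, one in
#'   each ceiling corner).
#' @param fps frames per second delivered by each sensor (default 20).
#' @param n_bins number of range bins per frame; the maximum observable
#'   distance in delay units (default 128).
#' @param pulse_center_freq carrier of the pulse template, in normalized
#'   cycles per bin (default 0.25, i.e. four bins per carrier cycle).
#' @param pulse_width_bins Gaussian half-width of the pulse envelope, in bins
#'   (default 3).
#' @param noise_sigma standard deviation of the additive per-bin Gaussian
#'   receiver noise, in template-amplitude units (default 0.05).
#' @return an object of class `radar_config`.
#' @export
radar_config <- function(n_sensors = 4L, fps = 20, n_bins = 128L,
                         pulse_center_freq = 0.25, pulse_width_bins = 3,
                         noise_sigma = 0.05) {
  if (n_sensors < 1) stop_qar("n_sensors must be >= 1", "qar_parameter_error")
  if (fps <= 0) stop_qar("fps must be > 0", "qar_parameter_error")
  if (n_bins < 8) stop_qar("n_bins must be >= 8", "qar_parameter_error")
  if (noise_sigma < 0) stop_qar("noise_sigma must be >= 0", "qar_parameter_error")
  structure(list(n_sensors = as.integer(n_sensors), fps = fps,
                 n_bins = as.integer(n_bins),
                 pulse_center_freq = pulse_center_freq,
                 pulse_width_bins = pulse_width_bins,
                 noise_sigma = noise_sigma),
            class = "radar_config")
}

#' Gaussian-modulated cosine pulse template
#'
#' The emitted impulse is modelled as a cosine at the configured carrier
#' frequency under a Gaussian envelope, sampled at bin resolution. RF-level
#' specifics (GHz carrier, GS/s sampling) are deliberately abstracted away:
#' downstream activity scores depend on frame-to-frame differences, not on
#' absolute RF fidelity, so only a band-limited template of realistic shape
#' matters.
#'
#' @param radar a [radar_config()].
#' @return numeric vector of odd length `6 * pulse_width_bins + 1` (clipped
#'   Gaussian support), zero-mean oscillatory, peak magnitude 1.
#' @export
make_pulse_template <- function(radar) {
  w <- radar$pulse_width_bins
  if (w < 1) stop_qar("pulse_width_bins must be >= 1", "qar_parameter_error")
  half <- ceiling(3 * w)
  k <- seq(-half, half)
  s <- exp(-k^2 / (2 * w^2)) * cos(2 * pi * radar$pulse_center_freq * k)
  s <- s - mean(s)              # zero-mean (AC-coupled receiver)
  s / max(abs(s))
}

#' Static scene: clutter plus reflecting target paths
#'
#' @param clutter_profile per-sensor list (or single vector recycled) of
#'   static background returns over bins: walls, furniture.
#' @param target_paths per-sensor list of paths; each path is a list with
#'   `amplitude` (reflection scale) and `delay_bin` (centre delay of the
#'   target for that sensor, 0-based bin index).
#' @param n_bins number of range bins (validates delays).
#' @return an object of class `scene_model`.
#' @export
scene_model <- function(clutter_profile, target_paths, n_bins) {
  if (!is.list(clutter_profile)) clutter_profile <- list(clutter_profile)
  for (cl in clutter_profile) {
    if (length(cl) != n_bins || any(!is.finite(cl)))
      stop_qar("clutter profiles must be finite vectors of length n_bins",
               "qar_parameter_error")
  }
  for (sensor_paths in target_paths) {
    for (p in sensor_paths) {
      if (!is.finite(p$amplitude))
        stop_qar("path amplitudes must be finite", "qar_parameter_error")
      if (p$delay_bin < 0 || p$delay_bin >= n_bins)
        stop_qar("path delay bins must lie in [0, n_bins)", "qar_parameter_error")
    }
  }
  structure(list(clutter_profile = clutter_profile,
                 target_paths = target_paths, n_bins = as.integer(n_bins)),
            class = "scene_model")
}

#' Default scene for a given radar geometry
#'
#' One smooth pseudo-random clutter profile and one target path per sensor,
#' with per-sensor distinct geometry (different delays and amplitudes), as for
#' four radially mounted sensors viewing the same subject from different
#' directions.
#'
#' @param radar a [radar_config()].
#' @param seed integer seed controlling the clutter draw.
#' @param target_amplitude reflection amplitude of the subject (default 1).
#' @return a [scene_model()].
#' @export
default_scene <- function(radar, seed = 1L, target_amplitude = 1) {
  nb <- radar$n_bins
  seeds <- split_seed(seed, radar$n_sensors)
  clutter <- vector("list", radar$n_sensors)
  paths <- vector("list", radar$n_sensors)
  for (i in seq_len(radar$n_sensors)) {
    clutter[[i]] <- withr::with_seed(seeds[i], {
      raw <- rnorm(nb, 0, 1)
      as.numeric(stats::filter(raw, rep(1 / 7, 7), sides = 2, circular = TRUE))
    })
    # target sits at a sensor-specific range, away from the edges
    delay <- round(nb * (0.3 + 0.4 * (i - 1) / max(1, radar$n_sensors - 1)))
    paths[[i]] <- list(list(amplitude = target_amplitude * (0.8 + 0.1 * i),
                            delay_bin = delay))
  }
  scene_model(clutter, paths, nb)
}

#' Group movement-intensity profile
#'
#' Piecewise-linear mean intensity over the session: constant at
#' `baseline_intensity` before `changepoint_minute`, then rising at
#' `trend_per_minute`; noise dispersion is inflated by `dispersion_scale`
#' after the changepoint. The default control profile is flat; the default
#' case profile rises after minute 7 with inflated dispersion, emulating a
#' group whose movement slowly increases with high dispersion late in a
#' 22-minute attention task.
#'
#' @param group label, e.g. `"HC"` or `"ADHD"`.
#' @param baseline_intensity mean movement intensity before the changepoint
#'   (arbitrary movement-scale units; at curve level these are activity-score
#'   units).
#' @param trend_per_minute slope of the mean after the changepoint, in
#'   intensity units per minute.
#' @param changepoint_minute minute at which the trend starts (default 7).
#' @param dispersion_scale multiplier applied to both between- and
#'   within-subject noise after the changepoint (default 1).
#' @param duration_minutes session length in minutes (default 22).
#' @param noise_sd within-subject noise SD before the changepoint.
#' @param sd_between between-subject SD of the baseline level.
#' @param sd_slope between-subject SD of the post-changepoint slope.
#' @return an object of class `trajectory_profile`.
#' @export
trajectory_profile <- function(group = "HC", baseline_intensity = 1,
                               trend_per_minute = 0, changepoint_minute = 7,
                               dispersion_scale = 1, duration_minutes = 22,
                               noise_sd = 0, sd_between = 0, sd_slope = 0) {
  if (duration_minutes <= 0)
    stop_qar("duration_minutes must be > 0", "qar_parameter_error")
  if (changepoint_minute < 0 || changepoint_minute > duration_minutes)
    stop_qar("changepoint_minute must lie in [0, duration_minutes]",
             "qar_parameter_error")
  if (baseline_intensity < 0 || dispersion_scale < 0 || noise_sd < 0 ||
      sd_between < 0 || sd_slope < 0)
    stop_qar("scale parameters must be nonnegative", "qar_parameter_error")
  structure(list(group = group, baseline_intensity = baseline_intensity,
                 trend_per_minute = trend_per_minute,
                 changepoint_minute = changepoint_minute,
                 dispersion_scale = dispersion_scale,
                 duration_minutes = duration_minutes,
                 noise_sd = noise_sd, sd_between = sd_between,
                 sd_slope = sd_slope),
            class = "trajectory_profile")
}

# Piecewise-linear mean intensity at time t (minutes).
trajectory_mean <- function(profile, t_min) {
  profile$baseline_intensity +
    profile$trend_per_minute * pmax(0, t_min - profile$changepoint_minute)
}

#' Simulate a per-frame movement-intensity series
#'
#' Mean follows the profile's piecewise-linear model; Gaussian within-subject
#' noise is added per frame, with its SD multiplied by `dispersion_scale`
#' after the changepoint. Intensities are clipped at zero.
#'
#' @param profile a [trajectory_profile()].
#' @param fps frames per second.
#' @param seed integer seed; the same seed reproduces the series exactly.
#' @return numeric vector of length `round(fps * 60 * duration_minutes)`.
#' @export
simulate_trajectory <- function(profile, fps, seed = 1L) {
  n <- round(fps * 60 * profile$duration_minutes)
  t_min <- (seq_len(n) - 0.5) / (fps * 60)
  mu <- trajectory_mean(profile, t_min)
  disp <- ifelse(t_min > profile$changepoint_minute, profile$dispersion_scale, 1)
  noise <- withr::with_seed(as.integer(seed), rnorm(n, 0, 1))
  pmax(0, mu + profile$noise_sd * disp * noise)
}

new_radar_recording <- function(frames, fps, sensor_ids, subject_id,
                                duration_minutes) {
  nf <- unique(vapply(frames, nrow, 1L))
  nb <- unique(vapply(frames, ncol, 1L))
  if (length(nf) != 1 || length(nb) != 1)
    stop_qar("all sensors must share n_frames and n_bins", "qar_shape_error")
  structure(list(frames = frames, fps = fps, sensor_ids = sensor_ids,
                 subject_id = subject_id, duration_minutes = duration_minutes,
                 n_frames = nf, n_bins = nb),
            class = "radar_recording")
}

#' @export
print.radar_recording <- function(x, ...) {
  cat(sprintf("<radar_recording> subject %s: %d sensor(s), %d frames x %d bins @ %g fps (%.2f min)\n",
              x$subject_id, length(x$frames), x$n_frames, x$n_bins, x$fps,
              x$duration_minutes))
  invisible(x)
}

# Place amplitude*template at integer delay (0-based centre bin) into a
# length-nb zero vector; out-of-range template samples are dropped.
place_pulse <- function(template, delay_bin, amplitude, nb) {
  half <- (length(template) - 1L) %/% 2L
  idx <- (delay_bin - half):(delay_bin + half) + 1L  # 1-based
  keep <- idx >= 1L & idx <= nb
  out <- numeric(nb)
  out[idx[keep]] <- amplitude * template[keep]
  out
}

#' Simulate one multi-sensor recording of a moving subject
#'
#' Each frame is the superposition of the sensor's static clutter profile, one
#' reflected pulse per target path, and i.i.d. Gaussian receiver noise.
#' Movement is encoded as frame-to-frame jitter of each target's delay bin:
#' the jitter SD (in bins) is `jitter_gain` times the trajectory intensity at
#' that frame, mirroring the physical picture that when the target moves, the
#' electromagnetic path length -- hence the delay of the received pulse --
#' changes. All sensors share the trajectory but have distinct geometry.
#'
#' @param scene a [scene_model()].
#' @param trajectory per-frame intensity series (see [simulate_trajectory()]).
#' @param radar a [radar_config()].
#' @param seed integer seed (split into per-sensor substreams).
#' @param subject_id label stored in the recording.
#' @param jitter_gain delay-jitter SD per unit intensity, bins (default 1).
#' @return a `radar_recording` (frames quantized to the container's float32
#'   precision).
#' @export
simulate_recording <- function(scene, trajectory, radar, seed = 1L,
                               subject_id = "subj", jitter_gain = 1) {
  nb <- radar$n_bins
  if (scene$n_bins != nb)
    stop_qar("scene and radar disagree on n_bins", "qar_shape_error")
  n_frames <- length(trajectory)
  template <- make_pulse_template(radar)
  seeds <- split_seed(seed, radar$n_sensors)
  clutters <- rep_len(scene$clutter_profile, radar$n_sensors)
  frames <- vector("list", radar$n_sensors)
  clipped <- 0L
  for (i in seq_len(radar$n_sensors)) {
    paths <- scene$target_paths[[min(i, length(scene$target_paths))]]
    frames[[i]] <- withr::with_seed(seeds[i], {
      mat <- matrix(rnorm(n_frames * nb, 0, radar$noise_sigma), n_frames, nb)
      mat <- sweep(mat, 2L, clutters[[i]], `+`)
      for (p in paths) {
        jit <- round(rnorm(n_frames, 0, jitter_gain * trajectory))
        delay <- p$delay_bin + jit
        out_of_range <- delay < 0 | delay > nb - 1
        clipped <- clipped + sum(out_of_range)
        delay <- pmin(pmax(delay, 0), nb - 1)
        for (n in seq_len(n_frames)) {
          mat[n, ] <- mat[n, ] + place_pulse(template, delay[n], p$amplitude, nb)
        }
      }
      mat
    })
    frames[[i]] <- quantize_float32(frames[[i]])
  }
  if (clipped > 0)
    warning(sprintf("%d target delays fell outside [0, n_bins) and were clipped",
                    clipped))
  new_radar_recording(frames, radar$fps,
                      sensor_ids = paste0("s", seq_len(radar$n_sensors)),
                      subject_id = subject_id,
                      duration_minutes = n_frames / (radar$fps * 60))
}

#' Simulate an empty-room recording (clutter and noise only)
#'
#' Used to calibrate the movement-detection threshold: with nobody in the
#' room, consecutive-frame envelope differences reflect receiver noise alone.
#'
#' @param radar a [radar_config()].
#' @param n_frames number of frames (>= 2).
#' @param seed integer seed.
#' @param scene optional [scene_model()] supplying the clutter; by default the
#'   clutter of [default_scene()] with the same seed.
#' @return a `radar_recording` with `subject_id = "empty"`.
#' @export
simulate_empty_room <- function(radar, n_frames, seed = 1L, scene = NULL) {
  if (n_frames < 2) stop_qar("n_frames must be >= 2", "qar_parameter_error")
  if (is.null(scene)) scene <- default_scene(radar, seed = seed)
  nb <- radar$n_bins
  seeds <- split_seed(seed, radar$n_sensors)
  clutters <- rep_len(scene$clutter_profile, radar$n_sensors)
  frames <- vector("list", radar$n_sensors)
  for (i in seq_len(radar$n_sensors)) {
    frames[[i]] <- withr::with_seed(seeds[i], {
      mat <- matrix(rnorm(n_frames * nb, 0, radar$noise_sigma), n_frames, nb)
      sweep(mat, 2L, clutters[[i]], `+`)
    })
    frames[[i]] <- quantize_float32(frames[[i]])
  }
  new_radar_recording(frames, radar$fps,
                      sensor_ids = paste0("s", seq_len(radar$n_sensors)),
                      subject_id = "empty",
                      duration_minutes = n_frames / (radar$fps * 60))
}
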