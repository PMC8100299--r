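# Independent oracles used across the suite. Each re-derives a quantity by a
# route deliberately different from the package implementation: direct O(n^2)
# DFT instead of the FFT, explicit loops instead of vectorized recursions,
# hand-solved tridiagonal systems instead of stats::splinefun, enumeration
# instead of closed forms.

# Direct DFT (matrix product, no FFT).
oracle_dft <- function(x, inverse = FALSE) {
  n <- length(x)
  k <- 0:(n - 1)
  W <- exp((if (inverse) 2i else -2i) * pi * outer(k, k) / n)
  as.vector(W %*% x)
}

# Analytic-signal envelope: zero negative frequencies, double positives.
oracle_envelope <- function(y) {
  n <- length(y)
  w <- numeric(n)
  if (n %% 2 == 0) {
    w[1] <- 1; w[n / 2 + 1] <- 1; w[2:(n / 2)] <- 2
  } else {
    w[1] <- 1; w[2:((n + 1) / 2)] <- 2
  }
  Mod(oracle_dft(oracle_dft(y) * w, inverse = TRUE) / n)
}

# Frame-by-frame clutter recursion, plain loop.
oracle_residuals <- function(frames, alpha) {
  C <- frames[1, ]
  out <- matrix(NA_real_, nrow(frames), ncol(frames))
  for (n in seq_len(nrow(frames))) {
    C <- alpha * C + (1 - alpha) * frames[n, ]
    out[n, ] <- frames[n, ] - C
  }
  out
}

# Classical one-way two-group ANOVA F via explicit sums of squares.
oracle_anova_F <- function(v, g) {
  g <- factor(g)
  means <- tapply(v, g, mean)
  ns <- table(g)
  grand <- mean(v)
  SSB <- sum(ns * (means - grand)^2)
  SSW <- sum((v - means[g])^2)
  (SSB / (nlevels(g) - 1)) / (SSW / (length(v) - nlevels(g)))
}

# Trapezoid quadrature by explicit summation.
oracle_trapz <- function(x, y) {
  sum((y[-1] + y[-length(y)]) / 2 * diff(x))
}

# Natural cubic spline: solve the standard tridiagonal system for second
# derivatives (natural boundary M_1 = M_n = 0), then evaluate piecewise.
oracle_natural_spline <- function(x, y, xout) {
  n <- length(x)
  h <- diff(x)
  A <- matrix(0, n, n)
  b <- numeric(n)
  A[1, 1] <- 1
  A[n, n] <- 1
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- h[i - 1]
    A[i, i] <- 2 * (h[i - 1] + h[i])
    A[i, i + 1] <- h[i]
    b[i] <- 6 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1])
  }
  M <- solve(A, b)
  vapply(xout, function(t) {
    i <- max(1, min(n - 1, findInterval(t, x)))
    hi <- h[i]
    M[i] * (x[i + 1] - t)^3 / (6 * hi) + M[i + 1] * (t - x[i])^3 / (6 * hi) +
      (y[i] / hi - M[i] * hi / 6) * (x[i + 1] - t) +
      (y[i + 1] / hi - M[i + 1] * hi / 6) * (t - x[i])
  }, numeric(1))
}

# Spearman rho with midranks computed from first principles.
oracle_spearman_rho <- function(x, y) {
  midrank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (1 + sum(v == vi)) / 2, numeric(1))
  }
  rx <- midrank(x)
  ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Exact two-sided rank-sum p by full enumeration of group assignments.
oracle_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(pooled), n1)
  sums <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- mean(sums)
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-12)
}

# Small fixtures -------------------------------------------------------------

tiny_radar <- function(...) {
  radar_config(n_sensors = 2L, fps = 10, n_bins = 32L, noise_sigma = 0.05, ...)
}

# A short recording with a moving target, for pipeline-level tests.
tiny_recording <- function(minutes = 2, seed = 1L, radar = tiny_radar(),
                           baseline = 1, trend = 0) {
  scene <- default_scene(radar, seed = seed)
  prof <- trajectory_profile(baseline_intensity = baseline,
                             trend_per_minute = trend,
                             changepoint_minute = 0,
                             duration_minutes = minutes, noise_sd = 0.1)
  traj <- simulate_trajectory(prof, radar$fps, seed = seed + 1L)
  simulate_recording(scene, traj, radar, seed = seed + 2L,
                     subject_id = paste0("S", seed), jitter_gain = 1)
}

tiny_thresholds <- function(radar = tiny_radar(), seed = 99L, n_frames = 600L) {
  empty <- simulate_empty_room(radar, n_frames, seed = seed)
  calibrate_threshold(empty, alpha = 0.97, multiplier = 3, burn_in = 50L)
}
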