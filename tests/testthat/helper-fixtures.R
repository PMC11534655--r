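# Fixtures and independent oracles shared across test files.

# Flat baseline followed by a linear ramp, no noise.  Ramp starts exactly at
# `ramp_start_s` (force still zero there) with slope `slope_n_per_s`.
make_ramp_trial <- function(ramp_start_s = 1, slope_n_per_s = 5000,
                            baseline_n = 0, duration_s = 2, fs = 1000,
                            trial_type = "explosive_1s") {
  t <- seq(0, duration_s, by = 1 / fs)
  f <- baseline_n + pmax(0, (t - ramp_start_s)) * slope_n_per_s
  force_time_trial(t, f, trial_type = trial_type,
                   baseline_window_s = c(0, ramp_start_s - 0.1))
}

# Exhaustive brute-force scan over every admissible sliding window, written
# as a plain loop so it shares nothing with the implementation.
brute_force_rfd_peak <- function(force, fs, onset_index, window_ms = 20,
                                 end_index = length(force)) {
  w <- round(window_ms / 1000 * fs)
  best <- -Inf
  for (i in onset_index:(end_index - w)) {
    slope <- (force[i + w] - force[i]) / (w / fs)
    if (slope > best) best <- slope
  }
  best
}

# From-definition Pearson correlation: covariance over product of SDs.
oracle_pearson_r <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Direct normal-equations least squares: solve(t(X) X) t(X) y.
oracle_normal_equations <- function(X, y) {
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# A train of half-sine torque lobes with known boundaries, for segmentation
# tests.  Returns the trace plus the true per-lobe means and windows.
make_lobe_train <- function(amplitudes, lobe_s = 0.3, gap_s = 0.1,
                            fs = 256, lead_s = 0.3) {
  total <- lead_s + length(amplitudes) * (lobe_s + gap_s)
  t <- seq(0, total, by = 1 / fs)
  torque <- numeric(length(t))
  windows <- matrix(NA_real_, length(amplitudes), 2)
  start <- lead_s
  for (k in seq_along(amplitudes)) {
    lobe_start <- start + gap_s
    idx <- which(t >= lobe_start & t < lobe_start + lobe_s)
    u <- (t[idx] - lobe_start) / lobe_s
    torque[idx] <- amplitudes[k] * sin(pi * u)
    windows[k, ] <- c(lobe_start, lobe_start + lobe_s)
    start <- start + gap_s + lobe_s
  }
  mean_torque <- vapply(seq_along(amplitudes), function(k) {
    inside <- t >= windows[k, 1] & t < windows[k, 2] & torque > 0
    mean(torque[inside])
  }, numeric(1))
  list(trace = tibble::tibble(time_s = t, torque_nm = torque),
       windows = windows,
       mean_torque = mean_torque)
}

# Noiseless logistic trial plus its closed-form signal values.
make_noiseless_logistic <- function(pf = 1500, seed = 1, ...) {
  gt <- imtp_ground_truth(pf_true = pf, noise_sd = 0, ...)
  trial <- generate_imtp_trial(gt, seed = seed)
  p0 <- plogis(gt$rise_rate * (gt$onset_true_s - gt$rise_midpoint_s))
  signal <- function(t) {
    s <- gt$pf_true *
      (plogis(gt$rise_rate * (t - gt$rise_midpoint_s)) - p0) / (1 - p0)
    ifelse(t < gt$onset_true_s, 0, s)
  }
  list(trial = trial, gt = gt, signal = signal)
}
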