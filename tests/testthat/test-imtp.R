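test_that("onset lands on the last sample before a noiseless ramp departs", {
  trial <- make_ramp_trial(ramp_start_s = 1.000)
  onset <- detect_onset(trial)
  expect_equal(onset$time_s, 1.000, tolerance = 1e-12)
})

test_that("a constant signal has no detectable onset", {
  t <- seq(0, 2, by = 0.001)
  trial <- force_time_trial(t, rep(500, length(t)), "explosive_1s",
                            baseline_window_s = c(0, 0.9))
  expect_error(detect_onset(trial), "no onset detected")
})

test_that("a baseline window overlapping the rise is shifted with a warning", {
  trial <- make_ramp_trial(ramp_start_s = 0.5)
  trial$baseline_window_s <- c(0, 1.5)  # covers half the ramp
  expect_warning(onset <- detect_onset(trial), "overlaps")
  expect_lt(abs(onset$time_s - 0.5), 0.05)
})

test_that("peak force is net of baseline and ties break to the earlier sample", {
  t <- seq(0, 2, by = 0.001)
  f <- rep(800, length(t))
  f[t >= 1] <- 800 + pmin((t[t >= 1] - 1) * 10000, 2000)  # ramps to 2800, flat top
  trial <- force_time_trial(t, f, "max_5s", baseline_window_s = c(0, 0.9))
  onset <- detect_onset(trial)
  pk <- peak_force(trial, onset)
  expect_equal(pk$peak_force_n, 2000)
  # earliest of the tied maxima wins
  expect_equal(pk$peak_index, min(which(f == max(f))))
})

test_that("a trial whose maximum sits in the baseline is rejected as inverted", {
  t <- seq(0, 2, by = 0.001)
  f <- rep(1000, length(t))
  f[100] <- 2000                        # spike inside the baseline window
  f[t >= 1] <- 1000 + pmin((t[t >= 1] - 1) * 5000, 500)  # genuine rise to 1500
  trial <- force_time_trial(t, f, "max_5s", baseline_window_s = c(0, 0.9))
  onset <- detect_onset(trial)
  expect_error(peak_force(trial, onset), "inverted")
})

test_that("banded RFD matches a perfect ramp and is zero for constant force", {
  trial <- make_ramp_trial(slope_n_per_s = 5000)
  onset <- detect_onset(trial)
  expect_equal(rfd_band(trial, onset, 100), 5000, tolerance = 1e-9)
  expect_equal(rfd_band(trial, onset, 200), 5000, tolerance = 1e-9)
  expect_equal(rfd_avg(trial, onset), 5000, tolerance = 1e-9)

  # step to a constant level: both bands span the flat region after the step
  t <- seq(0, 2, by = 0.001)
  f <- ifelse(t > 1, 500, 0)
  trial2 <- force_time_trial(t, f, "explosive_1s",
                             baseline_window_s = c(0, 0.9))
  onset2 <- detect_onset(trial2)
  expect_equal((trial2$force_n[onset2$index + 100] -
                  trial2$force_n[onset2$index]) / 0.1,
               rfd_band(trial2, onset2, 100))
})

test_that("banded RFD equals the closed-form logistic difference quotient", {
  fx <- make_noiseless_logistic()
  onset <- detect_onset(fx$trial)
  t0 <- onset$time_s
  for (band in c(100, 200)) {
    expected <- (fx$signal(t0 + band / 1000) - fx$signal(t0)) / (band / 1000)
    expect_equal(rfd_band(fx$trial, onset, band), expected, tolerance = 1e-9)
  }
})

test_that("a too-short record errors for bands and windows", {
  t <- seq(0, 0.5, by = 0.001)
  f <- c(rep(0, 400), seq_len(101) * 10)
  trial <- force_time_trial(t, f, "explosive_1s",
                            baseline_window_s = c(0, 0.35))
  onset <- detect_onset(trial)
  expect_error(rfd_band(trial, onset, 200), "record too short")
})

test_that("peak sliding-window RFD matches ramp, step and brute force", {
  trial <- make_ramp_trial(slope_n_per_s = 5000)
  onset <- detect_onset(trial)
  expect_equal(rfd_peak(trial, onset), 5000, tolerance = 1e-9)

  # +100 N step between adjacent samples at 1000 Hz -> 100 / 0.020 N/s
  t <- seq(0, 2, by = 0.001)
  f <- ifelse(t > 1, 100, 0)
  trial2 <- force_time_trial(t, f, "explosive_1s",
                             baseline_window_s = c(0, 0.9))
  onset2 <- detect_onset(trial2)
  expect_equal(rfd_peak(trial2, onset2), 100 / 0.020)

  for (s in 1:5) {
    gt <- imtp_ground_truth(noise_sd = 20)
    tr <- generate_imtp_trial(gt, seed = s)
    on <- detect_onset(tr)
    expect_equal(rfd_peak(tr, on),
                 brute_force_rfd_peak(tr$force_n, tr$fs_hz, on$index),
                 tolerance = 0)
  }
})

test_that("every RFD metric is shift-invariant and scale-equivariant", {
  metric_cols <- c("peak_force_n", "rfd_0_100", "rfd_0_200", "rfd_avg",
                   "rfd_peak")
  for (s in 1:5) {
    gt <- imtp_ground_truth(noise_sd = 15)
    tr <- generate_imtp_trial(gt, seed = s)
    m0 <- analyze_imtp_trial(tr)

    shifted <- tr
    shifted$force_n <- tr$force_n + 250
    m_shift <- analyze_imtp_trial(shifted)
    expect_equal(as.numeric(m_shift[, metric_cols]),
                 as.numeric(m0[, metric_cols]), tolerance = 1e-9)

    scaled <- tr
    scaled$force_n <- tr$force_n * 2.5
    m_scale <- analyze_imtp_trial(scaled)
    expect_equal(as.numeric(m_scale[, metric_cols]),
                 2.5 * as.numeric(m0[, metric_cols]), tolerance = 1e-9)
  }
})

test_that("best-trial aggregation averages the top trials by the set's rank metric", {
  base <- analyze_imtp_trial(make_ramp_trial(trial_type = "max_5s"))
  trials <- dplyr::bind_rows(lapply(c(2000, 1900, 1800, 1700, 1600),
                                    function(pf) {
    row <- base
    row$peak_force_n <- pf
    row
  }))
  agg <- aggregate_best_trials(trials)
  expect_equal(agg$peak_force_n, 1900)

  # three identical trials: aggregate equals any one of them
  same <- dplyr::bind_rows(base, base, base)
  agg2 <- aggregate_best_trials(same)
  expect_equal(agg2$peak_force_n, base$peak_force_n)
  expect_equal(agg2$rfd_peak, base$rfd_peak)

  # ranking equals a brute-force sort oracle on random values
  set.seed(7)
  vals <- runif(6, 1000, 3000)
  rnd <- dplyr::bind_rows(lapply(vals, function(pf) {
    row <- base; row$peak_force_n <- pf; row
  }))
  agg3 <- aggregate_best_trials(rnd)
  expect_equal(agg3$peak_force_n, mean(sort(vals, decreasing = TRUE)[1:3]))

  expect_error(aggregate_best_trials(trials[1:2, ]), "only 2 valid")
})
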