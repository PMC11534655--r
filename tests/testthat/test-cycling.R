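test_that("a half-sine lobe train segments into its true lobes", {
  fx <- make_lobe_train(amplitudes = c(180, 150, 130, 110, 95, 80))
  segs <- segment_downstrokes(fx$trace)
  expect_length(segs, 6)
  for (k in 1:6) {
    expect_lt(abs(segs[[k]]$lobe_window_s[1] - fx$windows[k, 1]), 0.01)
    expect_lt(abs(segs[[k]]$lobe_window_s[2] - fx$windows[k, 2]), 0.01)
    expect_equal(segs[[k]]$mean_torque_nm, fx$mean_torque[k],
                 tolerance = 0.01)
  }
})

test_that("segmentation rejects traces without usable lobes", {
  t <- seq(0, 3, by = 1 / 256)
  expect_error(segment_downstrokes(
    tibble::tibble(time_s = t, torque_nm = rep(0, length(t)))),
    "no positive torque")
  two <- make_lobe_train(amplitudes = c(100, 90))
  expect_error(segment_downstrokes(two$trace), "fewer than 3")
})

test_that("downstroke RTD matches hand-computed values on a triangular lobe", {
  # triangular lobe rising 60 Nm in 200 ms then falling; 1000 Hz grid
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)
  torque <- numeric(length(t))
  rise <- t >= 1 & t < 1.2
  fall <- t >= 1.2 & t < 1.4
  torque[rise] <- (t[rise] - 1) * 300
  torque[fall] <- 60 - (t[fall] - 1.2) * 300
  seg <- structure(
    list(stroke_index = 1L, time_s = t, torque_nm = torque, fs_hz = fs,
         lobe_window_s = c(1, 1.4), baseline_window_s = c(0.95, 0.999),
         mean_torque_nm = 30, peak_torque_nm = 60, peak_time_s = 1.2),
    class = "downstroke")
  rtd <- rtd_downstroke(seg)
  expect_equal(rtd$rtd_0_200, 300, tolerance = 1e-6)
  expect_equal(rtd$rtd_0_100, 300, tolerance = 1e-6)
  expect_equal(rtd$rtd_avg, 300, tolerance = 2)   # onset one sample early
  expect_equal(rtd$rtd_peak, 300, tolerance = 1e-6)
})

test_that("sprint RTD averages downstrokes 2 and 3 and guards the condition", {
  sess <- generate_sprint_session(cycling_ground_truth(torque_noise_sd = 0),
                                  seed = 1)
  trial06 <- Filter(function(tr) tr$resistance_nm_per_kg == 0.6 &&
                      tr$start_type == "stationary", sess$trials)[[1]]
  segs <- segment_downstrokes(trial06)
  per <- dplyr::bind_rows(lapply(segs[2:3], rtd_downstroke))
  avg <- rtd_sprint(trial06)
  expect_equal(avg$rtd_avg, mean(per$rtd_avg))
  expect_equal(avg$rtd_peak, mean(per$rtd_peak))

  rolling <- Filter(function(tr) tr$start_type == "rolling", sess$trials)[[1]]
  expect_error(rtd_sprint(rolling), "0.6")
})

test_that("observed session peaks are the maxima over all sprints", {
  sess <- generate_sprint_session(cycling_ground_truth(), seed = 3)
  peaks <- observed_session_peaks(sess)
  strokes <- dplyr::bind_rows(lapply(sess$trials, function(tr) tr$strokes))
  expect_equal(peaks$ppo_w, max(strokes$power_w))
  expect_equal(peaks$rpm_peak, max(strokes$cadence_rpm))
  expect_equal(peaks$t_peak_nm, sess$truth$t_peak_true_nm)
  expect_equal(peaks$ppo_per_bm, peaks$ppo_w / sess$body_mass_kg)

  # worked example: 1186 W at 77.0 kg is 15.4 W/kg
  sess$trials <- sess$trials[1]
  sess$trials[[1]]$strokes$power_w <- c(900, 1186, 1000, 950)
  sess$body_mass_kg <- 77.0
  expect_equal(round(observed_session_peaks(sess)$ppo_per_bm, 1), 15.4)
})

test_that("torque-cadence fit recovers an exact line and rejects bad input", {
  strokes <- tibble::tibble(cadence_rpm = c(40, 80, 120, 160),
                            mean_torque_nm = 200 - c(40, 80, 120, 160))
  fit <- fit_torque_cadence(strokes)
  expect_equal(fit$t0_nm, 200, tolerance = 1e-9)
  expect_equal(fit$rpmmax_rpm, 200, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-12)

  expect_error(fit_torque_cadence(strokes[1:2, ]), "at least 3")
  rising <- tibble::tibble(cadence_rpm = c(40, 80, 120),
                           mean_torque_nm = c(50, 90, 130))
  expect_error(fit_torque_cadence(rising), "non-decreasing")
})

test_that("power-cadence cubic recovers a known cubic and a parabola apex", {
  # exact cubic with an interior apex
  a <- c(30, -0.1, -0.0004)
  cad <- c(30, 60, 90, 120, 150, 180)
  p <- a[1] * cad + a[2] * cad^2 + a[3] * cad^3
  fit <- fit_power_cadence(tibble::tibble(cadence_rpm = cad, power_w = p))
  expect_equal(unname(fit$coeffs), a, tolerance = 1e-6)
  apex_true <- (-2 * a[2] - sqrt(4 * a[2]^2 - 12 * a[3] * a[1])) / (6 * a[3])
  expect_equal(fit$rpmopt_rpm, apex_true, tolerance = 1e-6)

  # parabola induced by the linear torque-cadence profile of the pre-training
  # group means: T0 = 165.2 Nm, RPMmax = 232.2 rpm
  t0 <- 165.2; rmax <- 232.2
  cad2 <- c(30, 55, 75, 95, 110, 125, 140, 160, 180, 200)
  p2 <- (2 * pi / 60) * t0 * cad2 * (1 - cad2 / rmax)
  fit2 <- fit_power_cadence(tibble::tibble(cadence_rpm = cad2, power_w = p2))
  expect_equal(fit2$rpmopt_rpm, rmax / 2, tolerance = 1e-3)
  expect_equal(fit2$pmax_w, pi * t0 * rmax / 120, tolerance = 1e-6)

  expect_error(fit_power_cadence(
    tibble::tibble(cadence_rpm = cad[1:3], power_w = p[1:3])), "at least 4")
})

test_that("profile fits are invariant to stroke order and unit-equivariant", {
  sess <- generate_sprint_session(cycling_ground_truth(), seed = 4)
  strokes <- dplyr::bind_rows(lapply(sess$trials, function(tr) tr$strokes))
  tc <- fit_torque_cadence(strokes)
  pc <- fit_power_cadence(strokes)

  set.seed(8)
  perm <- strokes[sample.int(nrow(strokes)), ]
  expect_equal(fit_torque_cadence(perm)$t0_nm, tc$t0_nm, tolerance = 1e-9)
  expect_equal(fit_power_cadence(perm)$rpmopt_rpm, pc$rpmopt_rpm,
               tolerance = 1e-9)

  doubled <- strokes
  doubled$mean_torque_nm <- 2 * strokes$mean_torque_nm
  doubled$power_w <- 2 * strokes$power_w
  tc2 <- fit_torque_cadence(doubled)
  pc2 <- fit_power_cadence(doubled)
  expect_equal(tc2$t0_nm, 2 * tc$t0_nm, tolerance = 1e-9)
  expect_equal(tc2$rpmmax_rpm, tc$rpmmax_rpm, tolerance = 1e-9)
  expect_equal(pc2$pmax_w, 2 * pc$pmax_w, tolerance = 1e-6)
  expect_equal(pc2$rpmopt_rpm, pc$rpmopt_rpm, tolerance = 1e-6)
})

test_that("least-squares fits agree with a direct normal-equations solver", {
  sess <- generate_sprint_session(cycling_ground_truth(), seed = 6)
  strokes <- dplyr::bind_rows(lapply(sess$trials, function(tr) tr$strokes))
  tc <- fit_torque_cadence(strokes)
  beta <- oracle_normal_equations(
    cbind(1, strokes$cadence_rpm), strokes$mean_torque_nm)
  expect_equal(tc$t0_nm, beta[1], tolerance = 1e-9)

  pc <- fit_power_cadence(strokes)
  X <- cbind(strokes$cadence_rpm, strokes$cadence_rpm^2,
             strokes$cadence_rpm^3)
  alpha <- oracle_normal_equations(X, strokes$power_w)
  expect_equal(unname(pc$coeffs), alpha, tolerance = 1e-7)
})

test_that("session profiling matches the generator truth without noise", {
  gt <- cycling_ground_truth(torque_noise_sd = 0)
  sess <- generate_sprint_session(gt, seed = 1)
  prof <- profile_session(sess)
  m <- prof$metrics
  expect_equal(m$t0_nm, gt$t0_true, tolerance = 1e-6 * gt$t0_true)
  expect_equal(m$rpmmax_rpm, gt$rpmmax_true,
               tolerance = 1e-6 * gt$rpmmax_true)
  expect_equal(m$rpmopt_rpm, gt$rpmmax_true / 2,
               tolerance = 0.005 * gt$rpmmax_true / 2)
  expect_equal(m$pmax_w, pi * gt$t0_true * gt$rpmmax_true / 120,
               tolerance = 0.005 * pi * gt$t0_true * gt$rpmmax_true / 120)
  expect_equal(m$ppo_w, sess$truth$ppo_true_w)
  expect_true(m$rpmopt_rpm < m$rpmmax_rpm)

  # dropping the 0.6 sprint leaves RTD missing with a warning
  sess2 <- sess
  sess2$trials <- Filter(function(tr) tr$resistance_nm_per_kg != 0.6 ||
                           tr$start_type != "stationary", sess$trials)
  expect_warning(prof2 <- profile_session(sess2), "RTD")
  expect_true(is.na(prof2$metrics$rtd_avg))
})
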