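test_that("noiseless per-stroke points lie exactly on the linear torque-cadence truth", {
  gt <- cycling_ground_truth(t0_true = 200, rpmmax_true = 200,
                             torque_noise_sd = 0)
  sess <- generate_sprint_session(gt, seed = 1)
  strokes <- dplyr::bind_rows(lapply(sess$trials, function(tr) tr$strokes))
  expect_equal(strokes$mean_torque_nm, 200 - strokes$cadence_rpm,
               tolerance = 1e-9)
})

test_that("stroke power equals torque times angular velocity", {
  sess <- generate_sprint_session(cycling_ground_truth(), seed = 2)
  strokes <- dplyr::bind_rows(lapply(sess$trials, function(tr) tr$strokes))
  expect_equal(strokes$power_w,
               strokes$mean_torque_nm * strokes$cadence_rpm * 2 * pi / 60,
               tolerance = 1e-9)
})

test_that("session generation is deterministic and seed-sensitive", {
  gt <- cycling_ground_truth()
  expect_identical(generate_sprint_session(gt, seed = 5),
                   generate_sprint_session(gt, seed = 5))
  s1 <- generate_sprint_session(gt, seed = 1)
  s2 <- generate_sprint_session(gt, seed = 2)
  expect_false(identical(s1$trials[[1]]$strokes, s2$trials[[1]]$strokes))
})

test_that("higher resistance saturates at lower cadence", {
  sess <- generate_sprint_session(cycling_ground_truth(torque_noise_sd = 0),
                                  seed = 1)
  stationary <- Filter(function(tr) tr$start_type == "stationary",
                       sess$trials)
  res <- vapply(stationary, function(tr) tr$resistance_nm_per_kg, numeric(1))
  last_cad <- vapply(stationary, function(tr) max(tr$strokes$cadence_rpm),
                     numeric(1))
  expect_true(all(diff(last_cad[order(res)]) < 0))
})

test_that("an unreachable rolling-start cadence is a generation error", {
  gt <- cycling_ground_truth(rpmmax_true = 200,
                             rolling_start_cadence_rpm = 250)
  expect_error(generate_sprint_session(gt, seed = 1), "rpmmax_true")
})

test_that("trace lobe means reproduce the per-stroke mean torques", {
  gt <- cycling_ground_truth(torque_noise_sd = 0)
  sess <- generate_sprint_session(gt, seed = 1)
  for (tr in sess$trials) {
    segs <- segment_downstrokes(tr)
    expect_length(segs, nrow(tr$strokes))
    seg_means <- vapply(segs, function(s) s$mean_torque_nm, numeric(1))
    expect_equal(seg_means, tr$strokes$mean_torque_nm, tolerance = 0.01)
  }
})
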