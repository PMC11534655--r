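#' Ground truth for a synthetic IMTP trial
#'
#' Describes the generative model for one isometric mid-thigh pull force-time
#' trial: a quiet-standing baseline (body weight on the plate) plus a logistic
#' force rise to a plateau, with additive Gaussian white noise.  The logistic
#' is rescaled so that the deterministic signal is exactly zero before
#' `onset_true_s` and asymptotes to `pf_true` above baseline, which makes the
#' stored onset and peak force exact recovery targets for the analyser.
#'
#' Defaults emulate a maximal-intent pull: the rise midpoint sits 50 ms after
#' onset so that force leaves the baseline noise band within a few
#' milliseconds of the true onset, as it does in a well-performed explosive
#' trial.
#'
#' @param baseline_force Quiet-standing force in N (body weight plus posture
#'   load on the plate).
#' @param pf_true True net peak force above baseline, N.
#' @param onset_true_s True onset time, s.
#' @param rise_midpoint_s Time of the logistic midpoint, s.  Default
#'   `onset_true_s + 0.05`.
#' @param rise_rate Logistic steepness, 1/s.
#' @param noise_sd Gaussian noise SD, N.
#' @param fs_hz Sampling rate, Hz.
#' @param duration_s Record length, s.  Default: onset plus the pull length
#'   implied by `trial_type` (1 s or 5 s).
#' @param trial_type `"explosive_1s"` or `"max_5s"`.
#'
#' @return A validated list of class `imtp_ground_truth`.
#' @export
imtp_ground_truth <- function(baseline_force = 820,
                              pf_true = 1800,
                              onset_true_s = 1.0,
                              rise_midpoint_s = onset_true_s + 0.05,
                              rise_rate = 60,
                              noise_sd = 20,
                              fs_hz = 1000,
                              duration_s = NULL,
                              trial_type = c("explosive_1s", "max_5s")) {
  trial_type <- match.arg(trial_type)
  duration_s <- duration_s %||%
    (onset_true_s + if (trial_type == "explosive_1s") 1 else 5)
  check_number(baseline_force, "baseline_force", lower = 0)
  check_number(pf_true, "pf_true", lower = 0, allow_equal_lower = FALSE)
  check_number(onset_true_s, "onset_true_s", lower = 0.2)
  check_number(rise_rate, "rise_rate", lower = 0, allow_equal_lower = FALSE)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(fs_hz, "fs_hz", lower = 0, allow_equal_lower = FALSE)
  check_number(duration_s, "duration_s", lower = 0, allow_equal_lower = FALSE)
  check_number(rise_midpoint_s, "rise_midpoint_s",
               lower = onset_true_s, allow_equal_lower = FALSE)
  if (rise_midpoint_s >= duration_s) {
    stop("`rise_midpoint_s` must be earlier than `duration_s`", call. = FALSE)
  }
  structure(
    list(baseline_force = baseline_force, pf_true = pf_true,
         onset_true_s = onset_true_s, rise_midpoint_s = rise_midpoint_s,
         rise_rate = rise_rate, noise_sd = noise_sd, fs_hz = fs_hz,
         duration_s = duration_s, trial_type = trial_type),
    class = "imtp_ground_truth")
}

# Deterministic (noise-free) component of the generated force signal.
imtp_signal <- function(gt, t) {
  p0 <- stats::plogis(gt$rise_rate * (gt$onset_true_s - gt$rise_midpoint_s))
  s <- gt$pf_true *
    (stats::plogis(gt$rise_rate * (t - gt$rise_midpoint_s)) - p0) / (1 - p0)
  ifelse(t < gt$onset_true_s, 0, s)
}

#' Generate one synthetic IMTP trial
#'
#' Samples the generative model of [imtp_ground_truth()] at `fs_hz` and adds
#' Gaussian white noise.  The result is a [force_time_trial()] whose
#' `baseline_window_s` ends 0.1 s before the true onset, with the ground
#' truth attached as the `truth` element for recovery testing.
#'
#' @param gt An [imtp_ground_truth()] object.
#' @param seed Integer seed; the same `gt` and `seed` give a bit-identical
#'   trial.
#' @return A `force_trial` with an extra `truth` element.
#' @export
#' @examples
#' trial <- generate_imtp_trial(imtp_ground_truth(noise_sd = 0), seed = 1)
#' max(trial$force_n) - trial$truth$baseline_force
generate_imtp_trial <- function(gt, seed) {
  if (!inherits(gt, "imtp_ground_truth")) {
    stop("`gt` must be an `imtp_ground_truth` object", call. = FALSE)
  }
  n <- round(gt$duration_s * gt$fs_hz)
  t <- (seq_len(n) - 1L) / gt$fs_hz
  noise <- with_fixed_seed(seed, stats::rnorm(n, 0, gt$noise_sd))
  f <- gt$baseline_force + imtp_signal(gt, t) + noise
  trial <- force_time_trial(
    t, f, trial_type = gt$trial_type,
    baseline_window_s = c(0, gt$onset_true_s - 0.1),
    fs_hz = gt$fs_hz)
  trial$truth <- gt
  trial
}
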