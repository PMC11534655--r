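#' Ground truth for a synthetic sprint-cycling session
#'
#' Describes the generative model for one participant-timepoint's set of
#' sprint trials on an isoinertial ergometer.  The torque-cadence truth is
#' linear, `T(c) = t0_true * (1 - c / rpmmax_true)`, so the induced
#' power-cadence curve is the parabola `P(c) = (2*pi/60) * c * T(c)` with a
#' closed-form apex at `c = rpmmax_true / 2`,
#' `Pmax = pi * t0_true * rpmmax_true / 120` -- an analytic oracle for the
#' profile fits.
#'
#' Each sprint condition is a stationary or rolling start against an external
#' resistance expressed per kg of body mass.  Per-stroke cadence follows a
#' saturating exponential towards the condition's steady-state cadence (where
#' rider torque balances the brake torque), so sprints at higher resistance
#' saturate at lower cadence.  Per-stroke mean torque is drawn from the
#' linear truth with Gaussian noise, power is torque times angular velocity,
#' and the continuous 256 Hz crank-torque trace is built as one half-sine
#' lobe per downstroke scaled so the lobe mean equals the stroke's mean
#' torque.
#'
#' @param t0_true Torque-cadence y-intercept (theoretical maximal torque), Nm.
#' @param rpmmax_true Torque-cadence x-intercept (theoretical maximal
#'   cadence), rpm.
#' @param torque_noise_sd SD of per-stroke mean-torque noise, Nm.
#' @param body_mass_kg Participant body mass, kg.
#' @param conditions Data frame with columns `start_type`
#'   (`"stationary"`/`"rolling"`) and `resistance_nm_per_kg`.  Defaults to the
#'   five-condition protocol: stationary starts at 0.2/0.4/0.6 and rolling
#'   starts at 0.0/0.2 Nm per kg.
#' @param strokes_per_sprint Downstrokes generated per sprint.  The default 4
#'   gives about 20 profile points per session, matching the typical number
#'   of modelling points in a five-sprint torque-velocity test.
#' @param fs_hz Trace sampling rate, Hz (crank power meters log at 256 Hz).
#' @param rolling_start_cadence_rpm Initial cadence of rolling starts, rpm.
#' @param cadence_tau_strokes Time constant (in strokes) of the saturating
#'   cadence trajectory.
#' @param lobe_fill Fraction of each half-revolution occupied by the torque
#'   lobe; the remainder is the inter-lobe trough.
#'
#' @return A validated list of class `cycling_ground_truth`.
#' @export
cycling_ground_truth <- function(t0_true = 165,
                                 rpmmax_true = 232,
                                 torque_noise_sd = 4,
                                 body_mass_kg = 84,
                                 conditions = default_sprint_conditions(),
                                 strokes_per_sprint = 4,
                                 fs_hz = 256,
                                 rolling_start_cadence_rpm = 80,
                                 cadence_tau_strokes = 3,
                                 lobe_fill = 0.75) {
  check_number(t0_true, "t0_true", lower = 0, allow_equal_lower = FALSE)
  check_number(rpmmax_true, "rpmmax_true", lower = 0, allow_equal_lower = FALSE)
  check_number(torque_noise_sd, "torque_noise_sd", lower = 0)
  check_number(body_mass_kg, "body_mass_kg", lower = 0,
               allow_equal_lower = FALSE)
  check_number(strokes_per_sprint, "strokes_per_sprint", lower = 3)
  check_number(fs_hz, "fs_hz", lower = 0, allow_equal_lower = FALSE)
  check_number(rolling_start_cadence_rpm, "rolling_start_cadence_rpm",
               lower = 0, allow_equal_lower = FALSE)
  check_number(cadence_tau_strokes, "cadence_tau_strokes", lower = 0,
               allow_equal_lower = FALSE)
  check_number(lobe_fill, "lobe_fill", lower = 0.3, upper = 1)
  if (!is.data.frame(conditions) ||
      !all(c("start_type", "resistance_nm_per_kg") %in% names(conditions))) {
    stop(paste("`conditions` must be a data frame with columns `start_type`",
               "and `resistance_nm_per_kg`"), call. = FALSE)
  }
  if (!all(conditions$start_type %in% c("stationary", "rolling"))) {
    stop("`start_type` must be 'stationary' or 'rolling'", call. = FALSE)
  }
  structure(
    list(t0_true = t0_true, rpmmax_true = rpmmax_true,
         torque_noise_sd = torque_noise_sd, body_mass_kg = body_mass_kg,
         conditions = conditions,
         strokes_per_sprint = as.integer(strokes_per_sprint), fs_hz = fs_hz,
         rolling_start_cadence_rpm = rolling_start_cadence_rpm,
         cadence_tau_strokes = cadence_tau_strokes, lobe_fill = lobe_fill),
    class = "cycling_ground_truth")
}

#' The five-sprint testing protocol
#'
#' Three 5-s sprints from stationary starts against 0.2, 0.4 and 0.6 Nm per
#' kg of body mass, plus two 5-s sprints from rolling starts (~80 rpm lead-in)
#' against 0.0 and 0.2 Nm per kg.
#'
#' @return A tibble with columns `start_type` and `resistance_nm_per_kg`.
#' @export
default_sprint_conditions <- function() {
  tibble::tibble(
    start_type = c("stationary", "stationary", "stationary",
                   "rolling", "rolling"),
    resistance_nm_per_kg = c(0.2, 0.4, 0.6, 0.0, 0.2))
}

#' Generate one synthetic sprint-cycling session
#'
#' Draws a full session under the model of [cycling_ground_truth()]: one
#' sprint trial per condition, each with a per-stroke summary table
#' (`stroke_index`, `mean_torque_nm`, `cadence_rpm`, `power_w`) and a
#' continuous crank-torque trace of half-sine downstroke lobes at `fs_hz`.
#' The session's ground truth (including the noiseless per-stroke values and
#' the true instantaneous peak torque) is attached for recovery testing.
#'
#' @param gt A [cycling_ground_truth()] object.
#' @param seed Integer seed; same `gt` and `seed` give an identical session.
#' @param participant,timepoint Optional identifiers stored on the session.
#' @return A list of class `sprint_session` with elements `participant`,
#'   `timepoint`, `body_mass_kg`, `trials` (list of `sprint_trial`) and
#'   `truth`.
#' @export
#' @examples
#' sess <- generate_sprint_session(cycling_ground_truth(torque_noise_sd = 0),
#'                                 seed = 1)
#' sess$trials[[1]]$strokes
generate_sprint_session <- function(gt, seed, participant = NA_character_,
                                    timepoint = NA_character_) {
  if (!inherits(gt, "cycling_ground_truth")) {
    stop("`gt` must be a `cycling_ground_truth` object", call. = FALSE)
  }
  if (gt$rolling_start_cadence_rpm >= gt$rpmmax_true) {
    stop(paste("`rpmmax_true` must exceed the rolling-start cadence;",
               "the requested lead-in cadence is unreachable"), call. = FALSE)
  }
  trials <- with_fixed_seed(seed, {
    lapply(seq_len(nrow(gt$conditions)), function(i) {
      generate_sprint_trial(gt,
                            start_type = gt$conditions$start_type[i],
                            resistance = gt$conditions$resistance_nm_per_kg[i])
    })
  })
  truth_strokes <- dplyr::bind_rows(lapply(trials, function(tr) tr$truth_strokes))
  truth <- list(
    t0_true = gt$t0_true, rpmmax_true = gt$rpmmax_true,
    body_mass_kg = gt$body_mass_kg,
    strokes = truth_strokes,
    t_peak_true_nm = max(vapply(trials, function(tr) max(tr$trace$torque_nm),
                                numeric(1))),
    ppo_true_w = max(truth_strokes$power_w),
    rpm_peak_true = max(truth_strokes$cadence_rpm))
  trials <- lapply(trials, function(tr) { tr$truth_strokes <- NULL; tr })
  structure(
    list(participant = participant, timepoint = timepoint,
         body_mass_kg = gt$body_mass_kg, trials = trials, truth = truth),
    class = "sprint_session")
}

# One sprint: per-stroke summaries plus the half-sine-lobe torque trace.
generate_sprint_trial <- function(gt, start_type, resistance) {
  K <- gt$strokes_per_sprint
  brake_nm <- resistance * gt$body_mass_kg
  c_ss <- gt$rpmmax_true * (1 - brake_nm / gt$t0_true)
  if (c_ss <= 0) {
    stop(sprintf(
      "resistance %.2f Nm/kg exceeds the torque capability implied by t0_true",
      resistance), call. = FALSE)
  }
  k <- seq_len(K)
  cadence <- if (start_type == "stationary") {
    c_ss * (1 - exp(-k / gt$cadence_tau_strokes))
  } else {
    c_ss + (gt$rolling_start_cadence_rpm - c_ss) *
      exp(-(k - 1) / gt$cadence_tau_strokes)
  }
  torque_true <- gt$t0_true * (1 - cadence / gt$rpmmax_true)
  torque <- pmax(torque_true + stats::rnorm(K, 0, gt$torque_noise_sd), 0.5)
  power <- torque * cadence * 2 * pi / 60

  strokes <- tibble::tibble(
    stroke_index = k, mean_torque_nm = torque,
    cadence_rpm = cadence, power_w = power)

  trace <- build_torque_trace(cadence, torque, gt$fs_hz, gt$lobe_fill,
                              lead_in_s = 0.3)
  structure(
    list(start_type = start_type, resistance_nm_per_kg = resistance,
         trace = trace, strokes = strokes, fs_hz = gt$fs_hz,
         truth_strokes = tibble::tibble(
           start_type = start_type, resistance_nm_per_kg = resistance,
           stroke_index = k, cadence_rpm = cadence,
           mean_torque_true_nm = torque_true, mean_torque_nm = torque,
           power_w = power)),
    class = "sprint_trial")
}

# Half-sine lobe train: stroke k occupies one half revolution at its cadence;
# the lobe fills `lobe_fill` of that window (preceded by a flat trough) and
# is scaled so its mean equals the stroke's mean torque.
build_torque_trace <- function(cadence_rpm, mean_torque_nm, fs_hz, lobe_fill,
                               lead_in_s = 0.3) {
  half_rev_s <- 30 / cadence_rpm
  total_s <- lead_in_s + sum(half_rev_s)
  n <- ceiling(total_s * fs_hz)
  t <- (seq_len(n) - 1L) / fs_hz
  torque <- numeric(n)
  start <- lead_in_s
  for (k in seq_along(cadence_rpm)) {
    gap <- (1 - lobe_fill) * half_rev_s[k]
    lobe_start <- start + gap
    lobe_len <- lobe_fill * half_rev_s[k]
    idx <- which(t >= lobe_start & t < lobe_start + lobe_len)
    u <- (t[idx] - lobe_start) / lobe_len
    shape <- sin(pi * u)
    # scale so the mean over the lobe's positive samples equals the stroke
    # mean exactly on this grid (the continuous-lobe factor would be pi/2)
    torque[idx] <- mean_torque_nm[k] * shape / mean(shape[shape > 0])
    start <- start + half_rev_s[k]
  }
  tibble::tibble(time_s = t, torque_nm = torque)
}

#' @export
print.sprint_session <- function(x, ...) {
  cat(sprintf("<sprint_session> %s/%s: %d sprints, body mass %.1f kg\n",
              x$participant, x$timepoint, length(x$trials), x$body_mass_kg))
  invisible(x)
}
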