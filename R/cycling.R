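#' Segment pedal downstrokes from a crank-torque trace
#'
#' Splits a continuous crank-torque trace into downstroke lobes.  Candidate
#' lobes are local maxima of the trace; boundaries are placed at the local
#' minima between consecutive maxima whenever the trough falls below
#' `trough_frac` of the smaller adjacent peak, otherwise the two maxima are
#' treated as one lobe.  Each returned segment carries the lobe samples plus
#' surrounding context (`pad_s` before and after), the lobe window, a
#' pre-lobe baseline window for torque-onset detection, and the lobe's mean
#' and peak torque.
#'
#' @param trace A tibble with columns `time_s` and `torque_nm` (or a
#'   `sprint_trial`, whose trace is used).
#' @param trough_frac Boundary rule: a trough separates two lobes when it is
#'   below this fraction of the smaller adjacent peak.
#' @param min_peak_frac Local maxima below this fraction of the global
#'   maximum are ignored as noise rather than treated as lobes.
#' @param pad_s Context (seconds) retained before and after each lobe.
#' @param baseline_s Length (seconds) of the pre-lobe trough window used as
#'   onset baseline.
#' @return A list of `downstroke` segments, one per lobe in temporal order.
#' @export
segment_downstrokes <- function(trace, trough_frac = 0.3,
                                min_peak_frac = 0.05, pad_s = 0.25,
                                baseline_s = 0.03) {
  if (inherits(trace, "sprint_trial")) trace <- trace$trace
  if (!is.data.frame(trace) ||
      !all(c("time_s", "torque_nm") %in% names(trace))) {
    stop("`trace` must have columns `time_s` and `torque_nm`", call. = FALSE)
  }
  t <- trace$time_s
  x <- trace$torque_nm
  n <- length(x)
  fs <- (n - 1) / (t[n] - t[1])
  gmax <- max(x)
  if (!is.finite(gmax) || gmax <= 0) {
    stop("no positive torque lobes found in trace", call. = FALSE)
  }
  eps <- min_peak_frac * gmax
  # extent floor: near-zero inter-lobe samples, far below any real torque
  eps_ext <- 1e-4 * gmax

  # Local maxima above the noise floor (plateau-tolerant: first sample of a
  # maximal run counts).
  rising <- c(FALSE, diff(x) > 0)
  falling <- c(diff(x) < 0, FALSE)
  peaks <- which(rising & falling & x > eps)
  # Merge peaks that are not separated by a deep enough trough.
  if (length(peaks) > 1L) {
    kept <- peaks[1]
    for (p in peaks[-1]) {
      last <- kept[length(kept)]
      trough_val <- min(x[last:p])
      if (trough_val < trough_frac * min(x[last], x[p])) {
        kept <- c(kept, p)
      } else if (x[p] > x[last]) {
        kept[length(kept)] <- p
      }
    }
    peaks <- kept
  }
  if (length(peaks) < 3L) {
    stop(sprintf("fewer than 3 downstrokes found (%d)", length(peaks)),
         call. = FALSE)
  }

  # Lobe extent: walk out from each peak to where torque drops below eps (or
  # to the boundary trough with the neighbouring lobe).
  bounds <- vapply(seq_along(peaks), function(k) {
    p <- peaks[k]
    left_lim <- if (k == 1L) 1L else {
      prev <- peaks[k - 1L]
      prev - 1L + which.min(x[prev:p])
    }
    right_lim <- if (k == length(peaks)) n else {
      nxt <- peaks[k + 1L]
      p - 1L + which.min(x[p:nxt])
    }
    lo <- p
    while (lo > left_lim && x[lo - 1L] > eps_ext) lo <- lo - 1L
    hi <- p
    while (hi < right_lim && x[hi + 1L] > eps_ext) hi <- hi + 1L
    c(lo, hi)
  }, integer(2))

  pad_n <- round(pad_s * fs)
  base_n <- max(3L, round(baseline_s * fs))
  lapply(seq_along(peaks), function(k) {
    lo <- bounds[1, k]; hi <- bounds[2, k]
    seg_lo <- max(1L, lo - pad_n)
    seg_hi <- min(n, hi + pad_n)
    base_lo <- max(seg_lo, lo - base_n)
    structure(
      list(stroke_index = k,
           time_s = t[seg_lo:seg_hi],
           torque_nm = x[seg_lo:seg_hi],
           fs_hz = fs,
           lobe_window_s = c(t[lo], t[hi]),
           baseline_window_s = c(t[base_lo], t[max(base_lo, lo - 1L)]),
           mean_torque_nm = mean(x[lo:hi]),
           peak_torque_nm = x[peaks[k]],
           peak_time_s = t[peaks[k]]),
      class = "downstroke")
  })
}

#' Rate of torque development within one downstroke
#'
#' Applies the IMTP onset and RFD machinery to a crank-torque downstroke:
#' torque onset is detected against the pre-lobe trough baseline, banded RTD
#' (0-100 and 0-200 ms) is taken from the onset along the padded record,
#' while average and peak RTD are confined to the lobe itself (onset to lobe
#' peak / fall) so a following downstroke cannot leak in.  Band metrics are
#' `NA` when the record ends before the band does.
#'
#' @param segment A `downstroke` from [segment_downstrokes()].
#' @param k_sd,extremum_lookback_s Onset-detection parameters; see
#'   [detect_onset()].  The lookback defaults to a shorter 20 ms at crank
#'   timescales.
#' @param rtd_window_ms Sliding-window length for peak RTD, ms.
#' @return A one-row tibble: `stroke_index`, `onset_time_s`,
#'   `peak_torque_nm`, `rtd_0_100`, `rtd_0_200`, `rtd_avg`, `rtd_peak`.
#' @export
rtd_downstroke <- function(segment, k_sd = 3, extremum_lookback_s = 0.02,
                           rtd_window_ms = 20) {
  stopifnot(inherits(segment, "downstroke"))
  trial <- force_time_trial(
    segment$time_s, segment$torque_nm, trial_type = "explosive_1s",
    baseline_window_s = segment$baseline_window_s, fs_hz = segment$fs_hz)
  onset <- detect_onset(trial, k_sd = k_sd,
                        extremum_lookback_s = extremum_lookback_s,
                        min_baseline_samples = 3L)
  lobe_idx <- which(trial$time_s >= segment$lobe_window_s[1] &
                      trial$time_s <= segment$lobe_window_s[2])
  lobe_end_idx <- max(lobe_idx)
  peak_rel <- lobe_idx[which.max(trial$force_n[lobe_idx])]

  band <- function(ms) {
    tryCatch(rfd_band(trial, onset, ms), error = function(e) NA_real_)
  }
  dt_pk <- trial$time_s[peak_rel] - onset$time_s
  rtd_a <- if (dt_pk > 0) {
    (trial$force_n[peak_rel] - onset$force_n) / dt_pk
  } else NA_real_
  rtd_p <- tryCatch(
    rfd_peak(trial, onset, window_ms = rtd_window_ms,
             end_index = lobe_end_idx),
    error = function(e) NA_real_)

  tibble::tibble(
    stroke_index = segment$stroke_index,
    onset_time_s = onset$time_s,
    peak_torque_nm = segment$peak_torque_nm,
    rtd_0_100 = band(100),
    rtd_0_200 = band(200),
    rtd_avg = rtd_a,
    rtd_peak = rtd_p)
}

#' RTD metrics for a sprint trial
#'
#' RTD is defined for the hardest stationary-start sprint (0.6 Nm per kg):
#' each RTD metric is the arithmetic mean over downstrokes 2 and 3 of that
#' sprint.
#'
#' @param trial A `sprint_trial` with a torque trace.
#' @param strokes Which downstrokes to average (default 2 and 3).
#' @param ... Passed to [rtd_downstroke()].
#' @return A one-row tibble: `rtd_0_100`, `rtd_0_200`, `rtd_avg`, `rtd_peak`.
#' @export
rtd_sprint <- function(trial, strokes = c(2, 3), ...) {
  stopifnot(inherits(trial, "sprint_trial"))
  if (!identical(trial$start_type, "stationary") ||
      abs(trial$resistance_nm_per_kg - 0.6) > 1e-9) {
    stop("RTD defined only for the 0.6 Nm·kg⁻¹ stationary sprint",
         call. = FALSE)
  }
  segs <- segment_downstrokes(trial)
  if (max(strokes) > length(segs)) {
    stop(sprintf("sprint has only %d downstrokes; need stroke %d",
                 length(segs), max(strokes)), call. = FALSE)
  }
  per <- dplyr::bind_rows(lapply(segs[strokes], rtd_downstroke, ...))
  tibble::tibble(
    rtd_0_100 = mean(per$rtd_0_100),
    rtd_0_200 = mean(per$rtd_0_200),
    rtd_avg = mean(per$rtd_avg),
    rtd_peak = mean(per$rtd_peak))
}

#' Observed peaks across all sprints of a session
#'
#' The observed peak power output (PPO) and peak cadence are the highest
#' per-stroke power and cadence over all strokes of all sprints; peak torque
#' is the maximum instantaneous crank torque over all downstrokes (taken
#' from the traces when present, otherwise from the per-stroke mean torques
#' with a warning).  PPO is also expressed relative to body mass.
#'
#' @param session A `sprint_session`.
#' @return A one-row tibble: `ppo_w`, `ppo_per_bm`, `rpm_peak`, `t_peak_nm`.
#' @export
observed_session_peaks <- function(session) {
  stopifnot(inherits(session, "sprint_session"))
  if (length(session$trials) == 0) {
    stop("session contains no sprints", call. = FALSE)
  }
  strokes <- dplyr::bind_rows(lapply(session$trials, function(tr) tr$strokes))
  has_trace <- vapply(session$trials,
                      function(tr) is.data.frame(tr$trace) && nrow(tr$trace) > 0,
                      logical(1))
  t_peak <- if (any(has_trace)) {
    max(vapply(session$trials[has_trace],
               function(tr) max(tr$trace$torque_nm), numeric(1)))
  } else {
    warning("no torque traces present; peak torque taken from stroke means",
            call. = FALSE)
    max(strokes$mean_torque_nm)
  }
  ppo <- max(strokes$power_w)
  tibble::tibble(
    ppo_w = ppo,
    ppo_per_bm = ppo / session$body_mass_kg,
    rpm_peak = max(strokes$cadence_rpm),
    t_peak_nm = t_peak)
}

#' Fit the linear torque-cadence profile
#'
#' Ordinary least squares of per-stroke mean torque on cadence.  The
#' theoretical maximal torque T0 is the extrapolated y-intercept and the
#' theoretical maximal cadence RPMmax the extrapolated x-intercept; both may
#' exceed any observed value.
#'
#' @param strokes A data frame with columns `cadence_rpm` and
#'   `mean_torque_nm`.
#' @return A list of class `tc_fit`: `t0_nm`, `rpmmax_rpm`, `slope_nm_per_rpm`,
#'   `r2`, `n_points` and the underlying `lm` fit.
#' @export
fit_torque_cadence <- function(strokes) {
  if (!is.data.frame(strokes) ||
      !all(c("cadence_rpm", "mean_torque_nm") %in% names(strokes))) {
    stop("`strokes` must have columns `cadence_rpm` and `mean_torque_nm`",
         call. = FALSE)
  }
  if (length(unique(strokes$cadence_rpm)) < 3L) {
    stop("need at least 3 strokes with distinct cadences", call. = FALSE)
  }
  fit <- stats::lm(mean_torque_nm ~ cadence_rpm, data = strokes)
  b <- coef(fit)
  if (!is.finite(b[2]) || b[2] >= 0) {
    stop("non-decreasing torque-cadence profile", call. = FALSE)
  }
  t0 <- unname(b[1])
  rpmmax <- unname(-b[1] / b[2])
  if (!is.finite(rpmmax) || rpmmax <= 0 || t0 <= 0) {
    stop("degenerate torque-cadence profile: non-positive intercepts",
         call. = FALSE)
  }
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((strokes$mean_torque_nm - mean(strokes$mean_torque_nm))^2)
  structure(
    list(t0_nm = t0, rpmmax_rpm = rpmmax, slope_nm_per_rpm = unname(b[2]),
         r2 = r2, n_points = nrow(strokes), fit = fit),
    class = "tc_fit")
}

#' Fit the zero-intercept cubic power-cadence profile
#'
#' Least squares of per-stroke power on cadence using
#' `P(c) = a1*c + a2*c^2 + a3*c^3` with the y-intercept fixed at zero.  The
#' apex of the fitted curve -- the admissible stationary point in
#' `(0, 1.2 * max observed cadence)` with the greatest fitted power -- gives
#' the theoretical peak power Pmax and the optimal cadence RPMopt.  When the
#' cubic coefficient is numerically negligible the stationary point is taken
#' from the quadratic term directly, which is the exact apex of a parabolic
#' profile.
#'
#' The reported r-squared is centred (1 - SS_res / SS_tot about the mean
#' power), not the uncentred statistic `lm()` reports for zero-intercept
#' models, so it is comparable to the usual regression r-squared.
#'
#' @param strokes A data frame with columns `cadence_rpm` and `power_w`.
#' @return A list of class `pc_fit`: `pmax_w`, `rpmopt_rpm`, `coeffs`
#'   (a1, a2, a3), `r2`, `n_points` and the underlying `lm` fit.
#' @export
fit_power_cadence <- function(strokes) {
  if (!is.data.frame(strokes) ||
      !all(c("cadence_rpm", "power_w") %in% names(strokes))) {
    stop("`strokes` must have columns `cadence_rpm` and `power_w`",
         call. = FALSE)
  }
  if (length(unique(strokes$cadence_rpm)) < 4L) {
    stop("need at least 4 strokes with distinct cadences", call. = FALSE)
  }
  c_ <- strokes$cadence_rpm
  p_ <- strokes$power_w
  fit <- stats::lm(p_ ~ 0 + c_ + I(c_^2) + I(c_^3))
  a <- unname(coef(fit))
  if (any(!is.finite(a))) {
    stop("degenerate design matrix for power-cadence fit", call. = FALSE)
  }
  cmax <- 1.2 * max(c_)
  pval <- function(x) a[1] * x + a[2] * x^2 + a[3] * x^3

  # Stationary points of P: a1 + 2 a2 c + 3 a3 c^2 = 0.  Guard against a
  # numerically vanishing cubic term, where the quadratic-root formula in
  # 1/a3 is unstable.
  cubic_scale <- abs(3 * a[3]) * cmax^2
  quad_scale <- abs(2 * a[2]) * cmax
  roots <- if (cubic_scale < 1e-8 * max(quad_scale, abs(a[1]))) {
    if (a[2] >= 0) numeric(0) else -a[1] / (2 * a[2])
  } else {
    disc <- (2 * a[2])^2 - 4 * (3 * a[3]) * a[1]
    if (disc < 0) numeric(0) else {
      (-2 * a[2] + c(-1, 1) * sqrt(disc)) / (2 * 3 * a[3])
    }
  }
  roots <- roots[is.finite(roots) & roots > 0 & roots < cmax]
  if (!length(roots)) stop("no interior apex", call. = FALSE)
  apex <- roots[which.max(pval(roots))]

  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((p_ - mean(p_))^2)
  structure(
    list(pmax_w = pval(apex), rpmopt_rpm = apex,
         coeffs = stats::setNames(a, c("a1", "a2", "a3")),
         r2 = r2, n_points = nrow(strokes), fit = fit),
    class = "pc_fit")
}

#' @export
print.tc_fit <- function(x, ...) {
  cat(sprintf("<tc_fit> T0 = %.1f Nm, RPMmax = %.1f rpm (slope %.3f, r2 = %.3f, n = %d)\n",
              x$t0_nm, x$rpmmax_rpm, x$slope_nm_per_rpm, x$r2, x$n_points))
  invisible(x)
}

#' @export
print.pc_fit <- function(x, ...) {
  cat(sprintf("<pc_fit> Pmax = %.1f W at RPMopt = %.1f rpm (r2 = %.3f, n = %d)\n",
              x$pmax_w, x$rpmopt_rpm, x$r2, x$n_points))
  invisible(x)
}

# Strokes used for profile modelling: the acceleration phase of each sprint,
# i.e. every stroke up to and including the sprint's maximum-cadence stroke.
profile_strokes <- function(session) {
  dplyr::bind_rows(lapply(session$trials, function(tr) {
    s <- tr$strokes
    s[seq_len(which.max(s$cadence_rpm)), , drop = FALSE]
  }))
}

#' Profile a full sprint-cycling session
#'
#' Assembles the complete cycling metric record for one session: observed
#' peaks (PPO, PPO per kg, peak cadence, peak torque), RTD metrics from
#' downstrokes 2-3 of the 0.6 Nm per kg stationary sprint, and the
#' torque-cadence / power-cadence profile parameters (T0, RPMmax, Pmax,
#' RPMopt) fitted to the acceleration-phase strokes of every sprint.
#'
#' @param session A `sprint_session`.
#' @param ... Passed to [rtd_sprint()].
#' @return A list of class `cycling_profile` with elements `metrics`
#'   (one-row tibble of all scalar metrics), `tc_fit`, `pc_fit` and
#'   `strokes_used`.
#' @export
#' @examples
#' sess <- generate_sprint_session(cycling_ground_truth(torque_noise_sd = 0),
#'                                 seed = 1)
#' profile_session(sess)$metrics
profile_session <- function(session, ...) {
  stopifnot(inherits(session, "sprint_session"))
  peaks <- observed_session_peaks(session)

  is_rtd_trial <- vapply(session$trials, function(tr) {
    identical(tr$start_type, "stationary") &&
      abs(tr$resistance_nm_per_kg - 0.6) < 1e-9
  }, logical(1))
  rtd <- if (any(is_rtd_trial)) {
    rtd_sprint(session$trials[[which(is_rtd_trial)[1]]], ...)
  } else {
    warning("no 0.6 Nm/kg stationary sprint present; RTD metrics are NA",
            call. = FALSE)
    tibble::tibble(rtd_0_100 = NA_real_, rtd_0_200 = NA_real_,
                   rtd_avg = NA_real_, rtd_peak = NA_real_)
  }

  strokes <- profile_strokes(session)
  tc <- fit_torque_cadence(strokes)
  pc <- fit_power_cadence(strokes)

  metrics <- dplyr::bind_cols(
    peaks, rtd,
    tibble::tibble(
      t0_nm = tc$t0_nm, rpmmax_rpm = tc$rpmmax_rpm,
      pmax_w = pc$pmax_w, rpmopt_rpm = pc$rpmopt_rpm,
      tc_r2 = tc$r2, pc_r2 = pc$r2, n_points = nrow(strokes)))
  structure(
    list(metrics = metrics, tc_fit = tc, pc_fit = pc, strokes_used = strokes),
    class = "cycling_profile")
}

#' @export
print.cycling_profile <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    paste0("<cycling_profile> PPO %.0f W (%.1f W/kg), Tpeak %.1f Nm, ",
           "T0 %.1f Nm, RPMmax %.1f rpm, Pmax %.0f W @ %.1f rpm\n"),
    m$ppo_w, m$ppo_per_bm, m$t_peak_nm, m$t0_nm, m$rpmmax_rpm,
    m$pmax_w, m$rpmopt_rpm))
  invisible(x)
}
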