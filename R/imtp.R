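#' Construct a force-time trial
#'
#' Container for one raw isometric mid-thigh pull (IMTP) trial: a uniformly
#' sampled vertical force record together with the trial type and the quiet
#' standing window used for baseline statistics.  No filtering is ever applied
#' to the force signal; all downstream metrics operate on the raw samples.
#'
#' @param time_s Numeric vector of sample times in seconds, strictly
#'   increasing and uniformly spaced.
#' @param force_n Numeric vector of vertical force in newtons, same length as
#'   `time_s`.
#' @param trial_type `"explosive_1s"` (short maximal-intent pull used for rate
#'   of force development) or `"max_5s"` (long pull used for peak force).
#' @param baseline_window_s Length-2 numeric: start and end (seconds) of the
#'   quiet-standing window preceding the pull.
#' @param fs_hz Sampling rate in Hz.  Inferred from `time_s` when `NULL`.
#' @param spacing_tol_s Maximum tolerated deviation from uniform sample
#'   spacing, in seconds.
#'
#' @return An object of class `force_trial`: a list with elements `time_s`,
#'   `force_n`, `fs_hz`, `trial_type` and `baseline_window_s`.
#' @export
#' @examples
#' t <- seq(0, 2, by = 0.001)
#' f <- 800 + 1500 * plogis(60 * (t - 1.05))
#' trial <- force_time_trial(t, f, "max_5s", baseline_window_s = c(0, 0.9))
force_time_trial <- function(time_s, force_n,
                             trial_type = c("explosive_1s", "max_5s"),
                             baseline_window_s,
                             fs_hz = NULL,
                             spacing_tol_s = 1e-6) {
  trial_type <- match.arg(trial_type)
  if (!is.numeric(time_s) || !is.numeric(force_n)) {
    stop("`time_s` and `force_n` must be numeric vectors", call. = FALSE)
  }
  n <- length(time_s)
  if (length(force_n) != n) {
    stop("`time_s` and `force_n` must have the same length", call. = FALSE)
  }
  if (n < 3L) stop("trial must contain at least 3 samples", call. = FALSE)
  if (any(!is.finite(force_n))) {
    stop("`force_n` contains non-finite values", call. = FALSE)
  }
  dt <- diff(time_s)
  if (any(dt <= 0)) stop("`time_s` must be strictly increasing", call. = FALSE)
  dt_med <- stats::median(dt)
  if (max(abs(dt - dt_med)) > spacing_tol_s) {
    stop(sprintf(
      "`time_s` is not uniformly sampled: spacing deviates by %.3g s (tolerance %.3g s)",
      max(abs(dt - dt_med)), spacing_tol_s), call. = FALSE)
  }
  fs <- fs_hz %||% (1 / dt_med)
  check_number(fs, "fs_hz", lower = 0, allow_equal_lower = FALSE)
  if (n < 0.3 * fs) {
    stop("trial is shorter than 0.3 s of samples", call. = FALSE)
  }
  if (!is.numeric(baseline_window_s) || length(baseline_window_s) != 2L ||
      baseline_window_s[2] <= baseline_window_s[1]) {
    stop("`baseline_window_s` must be c(start, end) with end > start",
         call. = FALSE)
  }
  structure(
    list(time_s = as.numeric(time_s), force_n = as.numeric(force_n),
         fs_hz = fs, trial_type = trial_type,
         baseline_window_s = as.numeric(baseline_window_s)),
    class = "force_trial")
}

#' @export
print.force_trial <- function(x, ...) {
  cat(sprintf("<force_trial> %s: %d samples @ %g Hz (%.2f s), baseline [%g, %g] s\n",
              x$trial_type, length(x$force_n), x$fs_hz,
              length(x$force_n) / x$fs_hz,
              x$baseline_window_s[1], x$baseline_window_s[2]))
  invisible(x)
}

baseline_indices <- function(trial, window = trial$baseline_window_s) {
  which(trial$time_s >= window[1] & trial$time_s <= window[2])
}

#' Detect force onset in a trial
#'
#' Automates the standard visual rule "the last peak/trough before the signal
#' deflects away from baseline noise".  The signal is declared to have
#' deflected at the first sample that exceeds baseline mean + `k_sd` baseline
#' SDs and stays above that threshold for at least `sustain_s`; the onset is
#' then backtracked to the last local extremum (peak or trough) of the raw
#' signal within `extremum_lookback_s` before that crossing.
#'
#' If the detected crossing falls inside the supplied baseline window the
#' window is shrunk to end before the crossing, a warning is issued, and
#' detection is repeated once with the shifted window.
#'
#' @param trial A [force_time_trial()] object.
#' @param k_sd Threshold in baseline standard deviations above the baseline
#'   mean.
#' @param extremum_lookback_s How far (seconds) to backtrack from the
#'   threshold crossing when searching for the last local extremum.
#' @param sustain_s Minimum time the signal must remain above threshold for a
#'   crossing to count, guarding against isolated noise spikes.
#' @param min_baseline_samples Minimum number of samples required in the
#'   baseline window.
#'
#' @return A list of class `force_onset`: `index`, `time_s`, `force_n`,
#'   `baseline_mean_n`, `baseline_sd_n`, `threshold_n`, `crossing_index`.
#' @export
detect_onset <- function(trial, k_sd = 3, extremum_lookback_s = 0.05,
                         sustain_s = 0.010, min_baseline_samples = 5L) {
  stopifnot(inherits(trial, "force_trial"))
  check_number(k_sd, "k_sd", lower = 0)
  check_number(extremum_lookback_s, "extremum_lookback_s", lower = 0)
  check_number(sustain_s, "sustain_s", lower = 0)

  window <- trial$baseline_window_s
  # Guard against a baseline window that engulfs the start of the rise: a
  # stationary baseline has equal first- and second-half means, so shrink the
  # window while the second half drifts upward beyond sampling error.
  warned <- FALSE
  for (shrink in 1:6) {
    bi <- baseline_indices(trial, window)
    if (length(bi) < 2L * min_baseline_samples) break
    half <- bi[seq_len(floor(length(bi) / 2))]
    rest <- setdiff(bi, half)
    se <- stats::sd(trial$force_n[half]) * sqrt(2 / length(half))
    drift <- mean(trial$force_n[rest]) - mean(trial$force_n[half])
    scale_tol <- 1e-9 * max(abs(trial$force_n))
    if (drift <= 5 * se + scale_tol) break
    window[2] <- trial$time_s[half[length(half)]]
    if (!warned) {
      warning(sprintf(
        "baseline window overlaps the force rise; shrinking window end to %g s",
        window[2]), call. = FALSE)
      warned <- TRUE
    }
  }
  for (attempt in 1:2) {
    bi <- baseline_indices(trial, window)
    if (length(bi) < min_baseline_samples) {
      stop(sprintf("baseline window contains only %d samples (need >= %d)",
                   length(bi), min_baseline_samples), call. = FALSE)
    }
    mu <- mean(trial$force_n[bi])
    sigma <- stats::sd(trial$force_n[bi])
    threshold <- mu + k_sd * sigma
    cross <- find_sustained_crossing(trial, threshold,
                                     start_index = min(bi),
                                     sustain_s = sustain_s)
    if (is.na(cross)) stop("no onset detected", call. = FALSE)
    if (trial$time_s[cross] <= window[2]) {
      if (attempt == 2L) stop("no onset detected", call. = FALSE)
      new_end <- trial$time_s[cross] - 2 * extremum_lookback_s
      warning(sprintf(
        "baseline window overlaps the detected rise; shifting window end from %g to %g s",
        window[2], new_end), call. = FALSE)
      window <- c(window[1], new_end)
      next
    }
    break
  }

  lb_n <- floor(extremum_lookback_s * trial$fs_hz)
  lo <- max(2L, cross - lb_n)
  hi <- min(cross, length(trial$force_n) - 1L)
  onset_idx <- cross
  if (hi >= lo) {
    js <- lo:hi
    f <- trial$force_n
    # weak-left/strict-right rule: the final sample of a flat stretch counts,
    # the first sample of a plateau does not
    peak <- f[js] >= f[js - 1L] & f[js] > f[js + 1L]
    trough <- f[js] <= f[js - 1L] & f[js] < f[js + 1L]
    ext <- js[peak | trough]
    if (length(ext)) onset_idx <- max(ext)
  }
  structure(
    list(index = onset_idx,
         time_s = trial$time_s[onset_idx],
         force_n = trial$force_n[onset_idx],
         baseline_mean_n = mu,
         baseline_sd_n = sigma,
         threshold_n = threshold,
         crossing_index = cross),
    class = "force_onset")
}

# First index i >= start_index such that force > threshold for a run of at
# least ceil(sustain_s * fs) consecutive samples beginning at i.  NA if none.
find_sustained_crossing <- function(trial, threshold, start_index, sustain_s) {
  above <- trial$force_n > threshold
  n <- length(above)
  run <- max(1L, ceiling(sustain_s * trial$fs_hz))
  if (n < run) return(NA_integer_)
  cs <- cumsum(above)
  counts <- cs[run:n] - c(0, cs)[1:(n - run + 1L)]
  cand <- which(counts == run)
  cand <- cand[cand >= start_index]
  if (!length(cand)) NA_integer_ else cand[1]
}

#' Peak force net of baseline
#'
#' Peak force is the maximum raw force in the trial minus the baseline
#' (quiet-standing) mean, which embodies the participant's body weight on the
#' plate.  The earliest sample wins when the maximum is tied.
#'
#' @param trial A [force_time_trial()] object.
#' @param onset A `force_onset` from [detect_onset()].
#' @return A list with `peak_force_n` (net of baseline), `peak_force_raw_n`,
#'   `peak_index` and `time_to_pf_s` (time from onset to the peak sample).
#' @export
peak_force <- function(trial, onset) {
  stopifnot(inherits(trial, "force_trial"), inherits(onset, "force_onset"))
  imax <- which.max(trial$force_n)   # which.max returns the first maximum
  bw <- trial$baseline_window_s
  if (trial$time_s[imax] >= bw[1] && trial$time_s[imax] <= bw[2]) {
    stop("inverted trial: maximum force occurs in the baseline window",
         call. = FALSE)
  }
  list(peak_force_n = trial$force_n[imax] - onset$baseline_mean_n,
       peak_force_raw_n = trial$force_n[imax],
       peak_index = imax,
       time_to_pf_s = trial$time_s[imax] - onset$time_s)
}

#' Rate of force development over a fixed time band
#'
#' Computes RFD over the band from onset to `band_end_ms` after onset as the
#' quotient of the force change and the elapsed time.  The band endpoint is
#' snapped to the nearest sample on the uniform grid, and the elapsed time is
#' the actual grid time spanned.
#'
#' @param trial A [force_time_trial()] object.
#' @param onset A `force_onset` from [detect_onset()].
#' @param band_end_ms Band end in milliseconds after onset (e.g. 100 or 200).
#' @return RFD in N/s (or Nm/s for torque input).
#' @export
rfd_band <- function(trial, onset, band_end_ms) {
  stopifnot(inherits(trial, "force_trial"), inherits(onset, "force_onset"))
  check_number(band_end_ms, "band_end_ms", lower = 0, allow_equal_lower = FALSE)
  di <- round(band_end_ms / 1000 * trial$fs_hz)
  if (di < 1) stop("band is shorter than one sample", call. = FALSE)
  iend <- onset$index + di
  if (iend > length(trial$force_n)) {
    stop(sprintf("record too short for the 0-%g ms band", band_end_ms),
         call. = FALSE)
  }
  (trial$force_n[iend] - trial$force_n[onset$index]) / (di / trial$fs_hz)
}

#' Average rate of force development from onset to peak force
#'
#' The change in force from onset to the peak sample divided by the time
#' elapsed.
#'
#' @inheritParams rfd_band
#' @return RFD in N/s.
#' @export
rfd_avg <- function(trial, onset) {
  pk <- peak_force(trial, onset)
  if (pk$time_to_pf_s <= 0) {
    stop("peak force does not occur after onset; average RFD undefined",
         call. = FALSE)
  }
  (pk$peak_force_raw_n - onset$force_n) / pk$time_to_pf_s
}

#' Peak rate of force development over a sliding window
#'
#' The fastest RFD during any window of `window_ms` milliseconds, advanced one
#' sample at a time from onset to the end of the record (or `end_index`).
#' Equivalent to an exhaustive scan of every admissible window.
#'
#' @inheritParams rfd_band
#' @param window_ms Window length in milliseconds (default 20).
#' @param end_index Optional last sample index to include in the scan;
#'   defaults to the end of the record.
#' @return Peak windowed RFD in N/s.
#' @export
rfd_peak <- function(trial, onset, window_ms = 20, end_index = NULL) {
  stopifnot(inherits(trial, "force_trial"), inherits(onset, "force_onset"))
  check_number(window_ms, "window_ms", lower = 0, allow_equal_lower = FALSE)
  n <- end_index %||% length(trial$force_n)
  w <- round(window_ms / 1000 * trial$fs_hz)
  if (w < 1) stop("RFD window is shorter than one sample", call. = FALSE)
  i0 <- onset$index
  if (i0 + w > n) {
    stop(sprintf("record shorter than one %g ms window after onset", window_ms),
         call. = FALSE)
  }
  starts <- i0:(n - w)
  max((trial$force_n[starts + w] - trial$force_n[starts]) / (w / trial$fs_hz))
}

#' Analyse one IMTP trial
#'
#' Runs onset detection and derives the full metric set for one trial: onset
#' time/force, net peak force, time to peak force, banded RFD (0-100 and
#' 0-200 ms), average RFD (onset to peak) and peak 20-ms-window RFD.
#'
#' By convention RFD variables are canonical for the short explosive trials
#' and peak force is canonical for the long maximal trials; the returned
#' `canonical_pf` / `canonical_rfd` flags record this so that aggregation can
#' pick the right trials without discarding the remaining columns.
#'
#' @param trial A [force_time_trial()] object.
#' @param k_sd,extremum_lookback_s Passed to [detect_onset()].
#' @param rfd_window_ms Sliding-window length for peak RFD, in ms.
#' @param trial_id Optional identifier copied into the output row.
#' @return A one-row [tibble::tibble()] with the metric columns described
#'   above.
#' @export
#' @examples
#' gt <- imtp_ground_truth(pf_true = 1500, noise_sd = 0)
#' trial <- generate_imtp_trial(gt, seed = 1)
#' analyze_imtp_trial(trial)
analyze_imtp_trial <- function(trial, k_sd = 3, extremum_lookback_s = 0.05,
                               rfd_window_ms = 20, trial_id = NA_character_) {
  onset <- detect_onset(trial, k_sd = k_sd,
                        extremum_lookback_s = extremum_lookback_s)
  pk <- peak_force(trial, onset)
  tibble::tibble(
    trial_id = trial_id,
    trial_type = trial$trial_type,
    onset_time_s = onset$time_s,
    onset_force_n = onset$force_n,
    baseline_mean_n = onset$baseline_mean_n,
    peak_force_n = pk$peak_force_n,
    time_to_pf_s = pk$time_to_pf_s,
    rfd_0_100 = rfd_band(trial, onset, 100),
    rfd_0_200 = rfd_band(trial, onset, 200),
    rfd_avg = rfd_avg(trial, onset),
    rfd_peak = rfd_peak(trial, onset, window_ms = rfd_window_ms),
    canonical_pf = trial$trial_type == "max_5s",
    canonical_rfd = trial$trial_type == "explosive_1s")
}

#' Aggregate the best trials of a set
#'
#' Ranks the trials of one set and returns the arithmetic mean of every metric
#' across the top `n_best`.  Long maximal (`max_5s`) sets are ranked by net
#' peak force; short explosive (`explosive_1s`) sets by peak RFD.
#'
#' @param metrics A tibble of rows from [analyze_imtp_trial()], all of the
#'   same trial type.
#' @param n_best Number of best trials to average (default 3).
#' @param rank_by Optional metric column to rank by, overriding the
#'   trial-type default.
#' @return A one-row tibble of averaged metrics with `n_trials_used` added.
#' @export
aggregate_best_trials <- function(metrics, n_best = 3, rank_by = NULL) {
  if (!is.data.frame(metrics) || nrow(metrics) == 0) {
    stop("`metrics` must be a non-empty data frame of trial metrics",
         call. = FALSE)
  }
  types <- unique(metrics$trial_type)
  if (length(types) != 1L) {
    stop("all trials in a set must share one trial_type", call. = FALSE)
  }
  rank_by <- rank_by %||%
    if (types == "max_5s") "peak_force_n" else "rfd_peak"
  if (!rank_by %in% names(metrics)) {
    stop(sprintf("ranking metric `%s` not found", rank_by), call. = FALSE)
  }
  ok <- is.finite(metrics[[rank_by]])
  if (sum(ok) < n_best) {
    bad <- which(!ok)
    stop(sprintf(
      "only %d valid trials (need %d); excluded trial rows: %s",
      sum(ok), n_best,
      if (length(bad)) paste(bad, collapse = ", ") else "none"),
      call. = FALSE)
  }
  kept <- metrics[ok, ][order(metrics[[rank_by]][ok], decreasing = TRUE), ]
  kept <- kept[seq_len(n_best), ]
  num <- vapply(kept, is.numeric, logical(1))
  out <- kept[1, ]
  out[num] <- lapply(kept[num], mean)
  out$trial_id <- NA_character_
  out$n_trials_used <- n_best
  tibble::as_tibble(out)
}
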