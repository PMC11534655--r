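#' Analysis configuration
#'
#' Bundles every tunable analysis parameter so a run can be reproduced from
#' its serialized configuration.  The configuration is embedded in every
#' output artifact written by [write_results()].
#'
#' @param k_sd Onset threshold in baseline SDs (see [detect_onset()]).
#' @param extremum_lookback_s Onset backtrack window, seconds.
#' @param rfd_window_ms Sliding-window length for peak RFD/RTD, ms.
#' @param n_best Trials averaged per IMTP set (see
#'   [aggregate_best_trials()]).
#' @param pct_convention Percent-change convention for summary tables.
#' @param ci_level Confidence level for effect-size intervals.
#' @param trough_frac Downstroke boundary rule (see [segment_downstrokes()]).
#' @param seed Seed recorded for provenance (the analysis itself is
#'   deterministic).
#' @return A list of class `run_config`.
#' @export
run_config <- function(k_sd = 3, extremum_lookback_s = 0.05,
                       rfd_window_ms = 20, n_best = 3,
                       pct_convention = c("ratio-of-means", "mean-of-ratios"),
                       ci_level = 0.95, trough_frac = 0.3, seed = NA_integer_) {
  pct_convention <- match.arg(pct_convention)
  check_number(k_sd, "k_sd", lower = 0)
  check_number(extremum_lookback_s, "extremum_lookback_s", lower = 0,
               upper = 1)
  check_number(rfd_window_ms, "rfd_window_ms", lower = 1, upper = 1000)
  check_number(n_best, "n_best", lower = 1)
  check_number(ci_level, "ci_level", lower = 0.5, upper = 0.999)
  check_number(trough_frac, "trough_frac", lower = 0, upper = 1,
               allow_equal_lower = FALSE)
  structure(
    list(k_sd = k_sd, extremum_lookback_s = extremum_lookback_s,
         rfd_window_ms = rfd_window_ms, n_best = as.integer(n_best),
         pct_convention = pct_convention, ci_level = ci_level,
         trough_frac = trough_frac, seed = seed),
    class = "run_config")
}

# The canonical session-level IMTP metrics: RFD family from the short
# explosive set, peak force from the long maximal set.
session_imtp_metrics <- function(imtp_trials, config) {
  per_trial <- dplyr::bind_rows(lapply(seq_along(imtp_trials), function(i) {
    analyze_imtp_trial(imtp_trials[[i]], k_sd = config$k_sd,
                       extremum_lookback_s = config$extremum_lookback_s,
                       rfd_window_ms = config$rfd_window_ms,
                       trial_id = sprintf("trial%02d", i))
  }))
  agg <- function(type) {
    sub <- per_trial[per_trial$trial_type == type, ]
    if (nrow(sub) == 0) return(NULL)
    aggregate_best_trials(sub, n_best = config$n_best)
  }
  best_1s <- agg("explosive_1s")
  best_5s <- agg("max_5s")
  metrics <- tibble::tibble(
    imtp_pf = if (!is.null(best_5s)) best_5s$peak_force_n else NA_real_,
    rfd_0_100 = if (!is.null(best_1s)) best_1s$rfd_0_100 else NA_real_,
    rfd_0_200 = if (!is.null(best_1s)) best_1s$rfd_0_200 else NA_real_,
    rfd_avg = if (!is.null(best_1s)) best_1s$rfd_avg else NA_real_,
    rfd_peak = if (!is.null(best_1s)) best_1s$rfd_peak else NA_real_)
  list(per_trial = per_trial, metrics = metrics)
}

#' Run the full profiling and statistics pipeline
#'
#' Takes a study (a list of participant-timepoint sessions, either from
#' [simulate_study()] or assembled from manifests via [load_session()]) and
#' produces the complete results bundle: per-trial IMTP metrics, per-session
#' IMTP and cycling metrics, the tidy long metric table, the pre/post
#' summary table, and the change-correlation matrix between cycling torque
#' and IMTP force measures (plus PPO and theoretical peak power as
#' outcomes).  The pipeline is deterministic: rerunning it on the same
#' sessions with the same configuration reproduces the bundle exactly.
#'
#' Statistics stages require at least one participant with both timepoints;
#' with a partial cohort they are skipped with a warning.
#'
#' @param study A `study` from [simulate_study()], or a plain list of
#'   session entries (each with `participant`, `timepoint`, `body_mass_kg`,
#'   `imtp_trials`, `sprint_session`).
#' @param config A [run_config()].
#' @return A list of class `pipeline_result`: `per_trial_imtp`,
#'   `session_metrics` (wide, one row per session), `metric_table` (long),
#'   `summary`, `change_correlations`, `config`.
#' @export
#' @examples
#' \donttest{
#' study <- simulate_study(n_participants = 3, seed = 1, n_imtp_trials = 3)
#' res <- run_pipeline(study)
#' res$summary
#' }
run_pipeline <- function(study, config = run_config()) {
  sessions <- if (inherits(study, "study")) study$sessions else study
  if (!is.list(sessions) || length(sessions) == 0) {
    stop("no sessions to analyse", call. = FALSE)
  }
  stopifnot(inherits(config, "run_config"))

  per_trial <- list()
  session_rows <- list()
  for (s in sessions) {
    imtp <- session_imtp_metrics(s$imtp_trials, config)
    pt <- imtp$per_trial
    pt$participant <- s$participant
    pt$timepoint <- s$timepoint
    per_trial[[length(per_trial) + 1L]] <- pt

    cyc <- profile_session(s$sprint_session)
    session_rows[[length(session_rows) + 1L]] <- dplyr::bind_cols(
      tibble::tibble(participant = s$participant, timepoint = s$timepoint,
                     body_mass_kg = s$body_mass_kg),
      imtp$metrics, cyc$metrics)
  }
  per_trial <- dplyr::bind_rows(per_trial)
  session_metrics <- dplyr::bind_rows(session_rows)

  stat_cols <- setdiff(names(session_metrics),
                       c("participant", "timepoint", "body_mass_kg",
                         "tc_r2", "pc_r2", "n_points"))
  metric_table <- tidyr::pivot_longer(
    session_metrics[, c("participant", "timepoint", stat_cols)],
    cols = dplyr::all_of(stat_cols),
    names_to = "metric", values_to = "value")

  n_pairs <- length(intersect(
    session_metrics$participant[session_metrics$timepoint == "pre"],
    session_metrics$participant[session_metrics$timepoint == "post"]))
  summary_tbl <- NULL
  change_cor <- NULL
  if (n_pairs >= 1) {
    summary_tbl <- build_summary_table(
      metric_table, pct_convention = config$pct_convention,
      ci_level = config$ci_level)
  } else {
    warning("no participant has both timepoints; statistics stages skipped",
            call. = FALSE)
  }
  if (n_pairs >= 3) {
    torque_predictors <- c("t_peak_nm", "t0_nm",
                           "rtd_0_100", "rtd_0_200", "rtd_avg", "rtd_peak")
    force_outcomes <- c("imtp_pf", "rfd_0_100", "rfd_0_200",
                        "rfd_avg", "rfd_peak")
    change_cor <- change_correlation_matrix(
      metric_table,
      predictors = c(torque_predictors, force_outcomes),
      outcomes = c(force_outcomes, "ppo_w", "pmax_w"))
  }

  structure(
    list(per_trial_imtp = per_trial, session_metrics = session_metrics,
         metric_table = metric_table, summary = summary_tbl,
         change_correlations = change_cor, config = config),
    class = "pipeline_result")
}

#' Write a results bundle to disk
#'
#' Writes each table of a [run_pipeline()] bundle as CSV with the run
#' configuration embedded as a commented JSON header line, plus a single
#' `results.json` holding every table and the configuration.
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg_json <- jsonlite::toJSON(unclass(result$config), auto_unbox = TRUE,
                               digits = NA)
  write_with_provenance <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# run_config: ", cfg_json), con)
    utils::write.csv(as.data.frame(df), con, row.names = FALSE)
    path
  }
  paths <- c()
  for (nm in c("per_trial_imtp", "session_metrics", "metric_table",
               "summary", "change_correlations")) {
    if (!is.null(result[[nm]])) {
      paths <- c(paths, write_with_provenance(
        result[[nm]], file.path(dir, paste0(nm, ".csv"))))
    }
  }
  json_path <- file.path(dir, "results.json")
  jsonlite::write_json(
    list(config = unclass(result$config),
         session_metrics = result$session_metrics,
         summary = result$summary,
         change_correlations = result$change_correlations),
    json_path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(paths, json_path))
}

#' Parse the configuration embedded in a results CSV
#'
#' @param path A CSV written by [write_results()].
#' @return The `run_config` list recovered from the provenance header.
#' @export
read_provenance <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "# run_config: ")) {
    stop("no provenance header found", call. = FALSE)
  }
  cfg <- jsonlite::fromJSON(sub("^# run_config: ", "", first))
  structure(cfg, class = "run_config")
}
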