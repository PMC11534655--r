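# Readers and writers for the package's CSV/JSON interchange formats.
# CSV is the canonical on-disk form for all time series and metric tables;
# session manifests are JSON or YAML.

read_csv_ci <- function(path, required, optional = character(0)) {
  df <- utils::read.csv(path, check.names = FALSE)
  names(df) <- tolower(trimws(names(df)))
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s",
                 basename(path), paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  tibble::as_tibble(df[, c(required, intersect(optional, names(df)))])
}

#' Read a force-time trial from CSV
#'
#' Expects a header `time_s,force_n` (case-insensitive).  Sampling must be
#' uniform within `spacing_tol_s`; jittered timestamps are rejected.
#'
#' @param path CSV file path.
#' @param trial_type `"explosive_1s"` or `"max_5s"`.
#' @param baseline_window_s Length-2 numeric quiet-standing window, seconds.
#' @param spacing_tol_s Uniform-spacing tolerance in seconds.
#' @return A [force_time_trial()].
#' @export
read_force_trial <- function(path, trial_type, baseline_window_s,
                             spacing_tol_s = 1e-6) {
  df <- read_csv_ci(path, c("time_s", "force_n"))
  force_time_trial(df$time_s, df$force_n, trial_type = trial_type,
                   baseline_window_s = baseline_window_s,
                   spacing_tol_s = spacing_tol_s)
}

#' Write a force-time trial to CSV
#'
#' @param trial A `force_trial`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_force_trial <- function(trial, path) {
  stopifnot(inherits(trial, "force_trial"))
  utils::write.csv(
    data.frame(time_s = trial$time_s, force_n = trial$force_n),
    path, row.names = FALSE)
  invisible(path)
}

#' Read a sprint trial from trace and stroke-summary CSVs
#'
#' The trace CSV has header `time_s,torque_left_nm[,torque_right_nm]`
#' (case-insensitive); when both crank columns are present they are summed
#' into total crank torque.  The stroke CSV has header
#' `stroke_index,mean_torque_nm,cadence_rpm,power_w`.
#'
#' @param trace_path Path to the crank-torque trace CSV (may be `NULL` when
#'   only stroke summaries are available).
#' @param strokes_path Path to the per-stroke summary CSV.
#' @param start_type `"stationary"` or `"rolling"`.
#' @param resistance_nm_per_kg External resistance, Nm per kg body mass.
#' @param power_tol Relative tolerance for the consistency check
#'   `power_w == mean_torque_nm * cadence_rpm * 2 * pi / 60`.
#' @return A `sprint_trial`.
#' @export
read_sprint_trial <- function(trace_path, strokes_path,
                              start_type = c("stationary", "rolling"),
                              resistance_nm_per_kg,
                              power_tol = 0.05) {
  start_type <- match.arg(start_type)
  if (!resistance_nm_per_kg %in% c(0.0, 0.2, 0.4, 0.6)) {
    stop("`resistance_nm_per_kg` must be one of 0.0, 0.2, 0.4, 0.6",
         call. = FALSE)
  }
  strokes <- read_csv_ci(strokes_path,
                         c("stroke_index", "mean_torque_nm", "cadence_rpm",
                           "power_w"))
  expected <- strokes$mean_torque_nm * strokes$cadence_rpm * 2 * pi / 60
  bad <- abs(strokes$power_w - expected) > power_tol * pmax(abs(expected), 1)
  if (any(bad)) {
    warning(sprintf(
      "%d stroke(s) violate power = torque x angular velocity beyond %g%%",
      sum(bad), 100 * power_tol), call. = FALSE)
  }
  trace <- NULL
  fs <- NA_real_
  if (!is.null(trace_path)) {
    tr <- read_csv_ci(trace_path, c("time_s", "torque_left_nm"),
                      optional = "torque_right_nm")
    torque <- tr$torque_left_nm
    if ("torque_right_nm" %in% names(tr)) torque <- torque + tr$torque_right_nm
    trace <- tibble::tibble(time_s = tr$time_s, torque_nm = torque)
    fs <- (nrow(trace) - 1) / (trace$time_s[nrow(trace)] - trace$time_s[1])
  }
  structure(
    list(start_type = start_type,
         resistance_nm_per_kg = resistance_nm_per_kg,
         trace = trace, strokes = strokes, fs_hz = fs),
    class = "sprint_trial")
}

#' Write a sprint trial's trace and strokes to CSV
#'
#' @param trial A `sprint_trial`.
#' @param trace_path,strokes_path Output CSV paths (`trace_path` may be
#'   `NULL`).
#' @return Invisibly, a list of the paths written.
#' @export
write_sprint_trial <- function(trial, trace_path, strokes_path) {
  stopifnot(inherits(trial, "sprint_trial"))
  if (!is.null(trace_path) && !is.null(trial$trace)) {
    utils::write.csv(
      data.frame(time_s = trial$trace$time_s,
                 torque_left_nm = trial$trace$torque_nm),
      trace_path, row.names = FALSE)
  }
  utils::write.csv(as.data.frame(trial$strokes), strokes_path,
                   row.names = FALSE)
  invisible(list(trace = trace_path, strokes = strokes_path))
}

#' Read a session manifest
#'
#' A manifest describes one participant-timepoint testing session: the
#' participant id, timepoint (`"pre"` or `"post"`), body mass, the IMTP trial
#' files with their trial types and baseline windows, and the sprint trial
#' entries (start type, resistance, trace and strokes paths).  JSON and YAML
#' are supported, chosen by file extension.
#'
#' @param path Manifest file path (`.json`, `.yaml` or `.yml`).
#' @return The validated manifest as a list of class `session_manifest`.
#' @export
read_manifest <- function(path) {
  ext <- tolower(tools::file_ext(path))
  man <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("manifest must be .json, .yaml or .yml", call. = FALSE))
  required <- c("participant", "timepoint", "body_mass_kg")
  missing <- setdiff(required, names(man))
  if (length(missing)) {
    stop(sprintf("manifest missing field(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (!man$timepoint %in% c("pre", "post")) {
    stop("manifest `timepoint` must be 'pre' or 'post'", call. = FALSE)
  }
  base <- dirname(path)
  resolve <- function(p) {
    ifelse(file.exists(p), p, file.path(base, p))
  }
  if (!is.null(man$imtp_trials)) {
    man$imtp_trials <- as.data.frame(man$imtp_trials)
    man$imtp_trials$path <- resolve(man$imtp_trials$path)
    bad <- !file.exists(man$imtp_trials$path)
    if (any(bad)) {
      stop(sprintf("manifest references missing IMTP file(s): %s",
                   paste(man$imtp_trials$path[bad], collapse = ", ")),
           call. = FALSE)
    }
  }
  if (!is.null(man$sprints)) {
    man$sprints <- as.data.frame(man$sprints)
    ok_res <- man$sprints$resistance_nm_per_kg %in% c(0.0, 0.2, 0.4, 0.6)
    if (!all(ok_res)) {
      stop("manifest sprint resistances must be from {0.0, 0.2, 0.4, 0.6}",
           call. = FALSE)
    }
    for (col in c("trace_path", "strokes_path")) {
      if (col %in% names(man$sprints)) {
        man$sprints[[col]] <- resolve(man$sprints[[col]])
        bad <- !is.na(man$sprints[[col]]) & !file.exists(man$sprints[[col]])
        if (any(bad)) {
          stop(sprintf("manifest references missing sprint file(s): %s",
                       paste(man$sprints[[col]][bad], collapse = ", ")),
               call. = FALSE)
        }
      }
    }
  }
  structure(man, class = "session_manifest")
}

#' Load a testing session from a manifest
#'
#' Reads every file referenced by a [read_manifest()] manifest and assembles
#' the in-memory session object consumed by [run_pipeline()].
#'
#' @param manifest A `session_manifest`.
#' @return A list with `participant`, `timepoint`, `body_mass_kg`,
#'   `imtp_trials` and `sprint_session`.
#' @export
load_session <- function(manifest) {
  stopifnot(inherits(manifest, "session_manifest"))
  imtp_trials <- list()
  if (!is.null(manifest$imtp_trials)) {
    for (i in seq_len(nrow(manifest$imtp_trials))) {
      row <- manifest$imtp_trials[i, ]
      bw <- if (!is.null(row$baseline_start_s)) {
        c(row$baseline_start_s, row$baseline_end_s)
      } else c(0, 0.9)
      imtp_trials[[i]] <- read_force_trial(row$path, row$trial_type, bw)
    }
  }
  sprint_session <- NULL
  if (!is.null(manifest$sprints)) {
    trials <- lapply(seq_len(nrow(manifest$sprints)), function(i) {
      row <- manifest$sprints[i, ]
      trace_path <- if (!is.null(row$trace_path) && !is.na(row$trace_path)) {
        row$trace_path
      } else NULL
      read_sprint_trial(trace_path, row$strokes_path, row$start_type,
                        row$resistance_nm_per_kg)
    })
    sprint_session <- structure(
      list(participant = manifest$participant,
           timepoint = manifest$timepoint,
           body_mass_kg = manifest$body_mass_kg,
           trials = trials, truth = NULL),
      class = "sprint_session")
  }
  list(participant = manifest$participant, timepoint = manifest$timepoint,
       body_mass_kg = manifest$body_mass_kg,
       imtp_trials = imtp_trials, sprint_session = sprint_session)
}

#' Write a synthetic session to disk in the interchange formats
#'
#' Serialises a generated session (IMTP trial CSVs, sprint trace and stroke
#' CSVs, JSON manifest, and a JSON ground-truth sidecar when truth is
#' present) so that the readers can consume exactly what the generator
#' produced.
#'
#' @param session A session entry as produced by [simulate_study()]
#'   (elements `participant`, `timepoint`, `body_mass_kg`, `imtp_trials`,
#'   `sprint_session`).
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- sprintf("%s_%s", session$participant, session$timepoint)
  imtp_entries <- NULL
  if (length(session$imtp_trials)) {
    imtp_entries <- do.call(rbind, lapply(seq_along(session$imtp_trials),
                                          function(i) {
      trial <- session$imtp_trials[[i]]
      fn <- sprintf("%s_imtp_%02d.csv", stem, i)
      write_force_trial(trial, file.path(dir, fn))
      data.frame(path = fn, trial_type = trial$trial_type,
                 baseline_start_s = trial$baseline_window_s[1],
                 baseline_end_s = trial$baseline_window_s[2])
    }))
  }
  sprint_entries <- NULL
  if (!is.null(session$sprint_session)) {
    sprint_entries <- do.call(rbind, lapply(
      seq_along(session$sprint_session$trials), function(i) {
        tr <- session$sprint_session$trials[[i]]
        trace_fn <- sprintf("%s_sprint_%02d_trace.csv", stem, i)
        strokes_fn <- sprintf("%s_sprint_%02d_strokes.csv", stem, i)
        write_sprint_trial(tr, file.path(dir, trace_fn),
                           file.path(dir, strokes_fn))
        data.frame(start_type = tr$start_type,
                   resistance_nm_per_kg = tr$resistance_nm_per_kg,
                   trace_path = trace_fn, strokes_path = strokes_fn)
      }))
    truth <- session$sprint_session$truth
    if (!is.null(truth)) {
      jsonlite::write_json(
        list(t0_true = truth$t0_true, rpmmax_true = truth$rpmmax_true,
             t_peak_true_nm = truth$t_peak_true_nm,
             ppo_true_w = truth$ppo_true_w),
        file.path(dir, sprintf("%s_truth.json", stem)), auto_unbox = TRUE,
        digits = NA)
    }
  }
  manifest <- list(participant = session$participant,
                   timepoint = session$timepoint,
                   body_mass_kg = session$body_mass_kg,
                   imtp_trials = imtp_entries,
                   sprints = sprint_entries)
  manifest_path <- file.path(dir, sprintf("%s_manifest.json", stem))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       dataframe = "rows", digits = NA)
  invisible(manifest_path)
}
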