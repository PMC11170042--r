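#' Signal-processing parameters for the pipeline
#'
#' All thresholds of the measurement stage in one validated list, with the
#' package defaults. Unknown names are rejected.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of class `process_params`.
#' @export
process_params <- function(...) {
  defaults <- list(
    epoch_length = 5,
    supine_threshold_deg = 50,
    longitudinal_axis = "z",
    median_kernel = 2,
    min_valid_frac = 0.5,
    activity_threshold = 0.05,
    cadence_band = c(1, 3),
    msda_window = 2,
    msda_calibration = 1,
    night_window = c("00:00", "05:00"),
    min_night_minutes = 30,
    hr_max_formula = "fox"
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    abort(paste0("unknown process parameter(s): ", paste(unknown, collapse = ", ")),
          class = "wearrehab_error_config")
  }
  defaults[names(over)] <- over
  structure(defaults, class = "process_params")
}

#' Process one recording session end to end
#'
#' Runs the measurement stage (posture classification with walking
#' refinement, MSDA, resting and maximum heart rate, %HRR) and the
#' aggregation stage (calendar-day splitting, per-day summaries) for one
#' patient-session.
#'
#' @param accel An [accel_series()].
#' @param hr An [hr_series()].
#' @param schedule A [period_schedule()].
#' @param profile One-row profile tibble with at least `age` (and optionally
#'   `hr_max_measured`).
#' @param session `"0W"` or `"4W"`.
#' @param params A [process_params()] list.
#' @return A list with `posture`, `msda`, `hrr_params`, `hrr`, `days` and
#'   `daily` (tibble of per-day summaries).
#' @export
process_session <- function(accel, hr, schedule, profile, session = "0W",
                            params = process_params()) {
  posture <- classify_posture(
    accel, epoch_length = params$epoch_length,
    supine_threshold_deg = params$supine_threshold_deg,
    longitudinal_axis = params$longitudinal_axis,
    median_kernel = params$median_kernel,
    min_valid_frac = params$min_valid_frac,
    activity_threshold = params$activity_threshold,
    cadence_band = params$cadence_band)
  msda <- compute_msda(accel, params$msda_window)
  if (params$msda_calibration != 1) {
    msda$windows$msda <- msda$windows$msda * params$msda_calibration
  }
  hp <- session_hrr_params(hr, posture, profile,
                           formula = params$hr_max_formula,
                           night_window = params$night_window,
                           min_minutes = params$min_night_minutes)
  hrrs <- percent_hrr(hr, hp)
  days <- split_days(accel)
  pid <- accel$patient_id %||% NA_character_
  daily <- do.call(rbind, lapply(seq_len(nrow(days)), function(i) {
    aggregate_day(msda, hrrs, posture, schedule, days[i, ],
                  hr_rest = hp$hr_rest, patient_id = pid, session = session)
  }))
  list(posture = posture, msda = msda, hrr_params = hp, hrr = hrrs,
       days = days, daily = daily)
}

check_out_dir <- function(out_dir, force) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force) {
    abort(sprintf("output directory %s is not empty (use force = TRUE to overwrite)",
                  out_dir),
          class = "wearrehab_error_output")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  invisible(out_dir)
}

#' Simulate a synthetic cohort to disk
#'
#' Generates the configured cohort one session at a time (so memory stays
#' bounded) and writes per-session acceleration, heart-rate and schedule
#' CSVs, ground-truth JSON, the profile table, the resolved configuration and
#' a checksum manifest.
#'
#' @param config A [scenario_config()].
#' @param out_dir Output directory.
#' @param force Overwrite a non-empty output directory?
#' @return The manifest tibble, invisibly.
#' @export
run_simulate <- function(config, out_dir, force = FALSE) {
  check_out_dir(out_dir, force)
  profiles <- generate_profiles(config)
  struct <- inject_cohort_structure(profiles, config)
  write_table_csv(profiles, file.path(out_dir, "profiles.csv"))
  write_table_csv(struct, file.path(out_dir, "cohort_structure.csv"))
  write_scenario_json(config, file.path(out_dir, "scenario_config.json"))
  for (i in seq_len(nrow(profiles))) {
    for (ss in SESSION_LEVELS) {
      mrow <- struct[struct$patient_id == profiles$patient_id[i] &
                       struct$session == ss, ]
      sess <- generate_session(profiles[i, ], config, session = ss,
                               m_training = mrow$m_training,
                               m_nontraining = mrow$m_nontraining)
      stem <- file.path(out_dir, paste0(profiles$patient_id[i], "_", ss))
      write_accel_csv(sess$accel, paste0(stem, "_accel.csv"))
      write_hr_csv(sess$hr, paste0(stem, "_hr.csv"))
      write_schedule_csv(sess$schedule, paste0(stem, "_schedule.csv"),
                         sess$accel$start_time)
      write_truth_json(sess$truth, paste0(stem, "_truth.json"))
    }
  }
  invisible(write_manifest(out_dir))
}

#' Process simulated (or same-format) recordings to daily and cohort tables
#'
#' Discovers `<patient>_<session>_accel.csv` files in `in_dir`, runs
#' [process_session()] on each, and writes `daily_summaries.csv`,
#' `cohort_table.csv` and a provenance JSON with the resolved parameters.
#' A session without a schedule file is processed as all-nontraining, with a
#' warning.
#'
#' @param in_dir Directory produced by [run_simulate()] (or files in the same
#'   layout).
#' @param out_dir Output directory.
#' @param params A [process_params()] list.
#' @param force Overwrite a non-empty output directory?
#' @return The cohort table, invisibly.
#' @export
run_process <- function(in_dir, out_dir, params = process_params(),
                        force = FALSE) {
  check_out_dir(out_dir, force)
  profiles <- read_table_csv(file.path(in_dir, "profiles.csv"))
  cfg_path <- file.path(in_dir, "scenario_config.json")
  rates <- if (file.exists(cfg_path)) {
    cfg <- read_scenario_json(cfg_path)
    list(accel = cfg$accel_rate, hr = cfg$hr_rate, span = cfg$session_hours * 3600)
  } else {
    list(accel = NULL, hr = NULL, span = NULL)
  }
  accel_files <- list.files(in_dir, pattern = "_accel\\.csv$", full.names = TRUE)
  if (length(accel_files) == 0) {
    abort(sprintf("no *_accel.csv recordings found in %s", in_dir),
          class = "wearrehab_error_input")
  }
  daily <- list()
  for (af in accel_files) {
    stem <- sub("_accel\\.csv$", "", af)
    parts <- strsplit(basename(stem), "_")[[1]]
    pid <- parts[1]; ss <- parts[2]
    t0 <- Sys.time()
    accel <- read_accel_csv(af, rate = rates$accel, span = rates$span,
                            patient_id = pid, session = ss)
    hr <- read_hr_csv(paste0(stem, "_hr.csv"), rate = rates$hr,
                      span = rates$span, patient_id = pid, session = ss)
    sched_path <- paste0(stem, "_schedule.csv")
    schedule <- if (file.exists(sched_path)) {
      read_schedule_csv(sched_path, accel$start_time)
    } else {
      warn(sprintf("no schedule for %s %s: treating the whole session as nontraining",
                   pid, ss))
      period_schedule(tibble(start = numeric(0), end = numeric(0),
                             label = character(0)), source = "missing")
    }
    profile <- profiles[profiles$patient_id == pid, ]
    res <- process_session(accel, hr, schedule, profile, session = ss,
                           params = params)
    daily[[basename(stem)]] <- res$daily
    message(sprintf("processed %s %s in %.1f s (%d samples, %.0f gap min)",
                    pid, ss, as.numeric(difftime(Sys.time(), t0, units = "secs")),
                    nrow(accel$data), sum(res$daily$minutes_gap)))
  }
  daily <- do.call(rbind, daily)
  cohort <- cohort_summaries(daily, profiles)
  write_table_csv(daily, file.path(out_dir, "daily_summaries.csv"))
  write_table_csv(cohort, file.path(out_dir, "cohort_table.csv"))
  prov <- list(package = "wearrehab",
               version = as.character(utils::packageVersion("wearrehab")),
               params = unclass(params))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(cohort)
}

#' Run the statistics stage on a cohort table
#'
#' @param cohort_path Path to a `cohort_table.csv` (or the directory holding
#'   it).
#' @param out_dir Output directory for `correlations.csv`,
#'   `comparisons.csv` and `report.md`.
#' @param p_method,n_perm,seed Passed to [build_results_tables()].
#' @param force Overwrite a non-empty output directory?
#' @return The `results_bundle`, invisibly.
#' @export
run_stats <- function(cohort_path, out_dir, p_method = "t_approx",
                      n_perm = 99999, seed = 1L, force = FALSE) {
  if (dir.exists(cohort_path)) {
    cohort_path <- file.path(cohort_path, "cohort_table.csv")
  }
  cohort <- read_table_csv(cohort_path)
  check_out_dir(out_dir, force)
  n_pairs <- length(intersect(cohort$patient_id[cohort$session == "0W"],
                              cohort$patient_id[cohort$session == "4W"]))
  if (n_pairs < 3) {
    warn(sprintf("only %d complete 0W/4W pairs: paired tests reported as missing",
                 n_pairs))
  }
  bundle <- build_results_tables(cohort, p_method = p_method, n_perm = n_perm,
                                 seed = seed)
  write_table_csv(bundle$correlations, file.path(out_dir, "correlations.csv"))
  write_table_csv(bundle$comparisons, file.path(out_dir, "comparisons.csv"))
  writeLines(format_results_report(bundle), file.path(out_dir, "report.md"))
  jsonlite::write_json(list(p_method = p_method, n_perm = n_perm, seed = seed,
                            alpha = bundle$alpha),
                       file.path(out_dir, "stats_config.json"),
                       auto_unbox = TRUE)
  invisible(bundle)
}

#' Run simulate, process and stats in sequence
#'
#' @param config A [scenario_config()].
#' @param out_dir Root output directory; stages write to `simulated/`,
#'   `processed/` and `stats/` beneath it.
#' @param params A [process_params()] list.
#' @param p_method,seed Passed to [run_stats()].
#' @param force Overwrite non-empty output directories?
#' @return The `results_bundle`, invisibly.
#' @export
run_all <- function(config, out_dir, params = process_params(),
                    p_method = "t_approx", seed = 1L, force = FALSE) {
  check_out_dir(out_dir, force)
  run_simulate(config, file.path(out_dir, "simulated"), force = force)
  run_process(file.path(out_dir, "simulated"), file.path(out_dir, "processed"),
              params = params, force = force)
  run_stats(file.path(out_dir, "processed"), file.path(out_dir, "stats"),
            p_method = p_method, seed = seed, force = force)
}

#' Load a pipeline configuration from YAML
#'
#' The file may hold three top-level sections: `scenario` (fields of
#' [scenario_config()]), `process` (fields of [process_params()]) and
#' `stats` (`p_method`, `n_perm`, `seed`). Unknown keys at any level are
#' rejected.
#'
#' @param path YAML file path.
#' @return A list with validated `scenario`, `process` and `stats` entries.
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path),
          class = "wearrehab_error_config")
  }
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), c("scenario", "process", "stats"))
  if (length(unknown)) {
    abort(paste0("unknown config section(s): ", paste(unknown, collapse = ", ")),
          class = "wearrehab_error_config")
  }
  scen_args <- raw$scenario %||% list()
  bad <- setdiff(names(scen_args), names(formals(scenario_config)))
  if (length(bad)) {
    abort(paste0("unknown scenario key(s): ", paste(bad, collapse = ", ")),
          class = "wearrehab_error_config")
  }
  for (nm in c("posture_noise_sd", "hrr_mean_by_period")) {
    if (!is.null(scen_args[[nm]])) scen_args[[nm]] <- unlist(scen_args[[nm]])
  }
  stats_args <- raw$stats %||% list()
  bad <- setdiff(names(stats_args), c("p_method", "n_perm", "seed"))
  if (length(bad)) {
    abort(paste0("unknown stats key(s): ", paste(bad, collapse = ", ")),
          class = "wearrehab_error_config")
  }
  list(scenario = do.call(scenario_config, scen_args),
       process = do.call(process_params, raw$process %||% list()),
       stats = stats_args)
}
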