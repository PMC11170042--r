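#' @importFrom data.table fread fwrite data.table as.data.table
NULL

# Vectorized timezone-naive ISO-8601 timestamps (millisecond precision) for
# session seconds `t` anchored at `start_time`.
format_iso <- function(start_time, t, digits = 3) {
  off0 <- seconds_of_day(start_time)
  abs_s <- off0 + t
  day <- floor(abs_s / 86400)
  sod <- abs_s - day * 86400
  dates <- format(trunc(start_time, "days") + unique(day) * 86400, "%Y-%m-%d")
  date_str <- dates[match(day, unique(day))]
  hh <- floor(sod / 3600); mm <- floor((sod - hh * 3600) / 60)
  ss <- sod - hh * 3600 - mm * 60
  fmt <- sprintf("%%sT%%02d:%%02d:%%0%d.%df", if (digits > 0) 3 + digits else 2,
                 digits)
  sprintf(fmt, date_str, hh, mm, ss)
}

parse_iso <- function(x, path = "<memory>") {
  tt <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  bad <- which(is.na(tt))
  if (length(bad)) {
    abort(sprintf("malformed timestamp in %s, data row %d: '%s'",
                  path, bad[1], x[bad[1]]),
          class = "wearrehab_error_format")
  }
  tt
}

# Snap parsed times to the sampling grid and infer gaps from discontinuities.
relative_times <- function(tt, rate) {
  num <- as.numeric(tt)
  t <- num - num[1]
  if (is.null(rate)) {
    dt <- diff(t)
    rate <- round(1 / median(dt))
  }
  t <- round(t * rate) / rate
  gaps <- NULL
  if (length(t) > 1) {
    dt <- diff(t)
    i <- which(dt > 1.5 / rate)
    if (length(i)) gaps <- tibble(start = t[i] + 1 / rate, end = t[i + 1])
  }
  list(time = t, rate = rate, start_time = tt[1], gaps = gaps)
}

#' Write / read a tri-axial acceleration series as CSV
#'
#' Column layout `timestamp_iso8601,ax_g,ay_g,az_g`; timestamps are
#' timezone-naive local time at millisecond precision; gaps are represented
#' by absent rows and re-inferred on read from sampling discontinuities.
#'
#' @param series An [accel_series()].
#' @param path CSV file path.
#' @return `write_accel_csv` returns `path` invisibly; `read_accel_csv`
#'   returns an [accel_series()].
#' @export
write_accel_csv <- function(series, path) {
  stopifnot(inherits(series, "accel_series"))
  dt <- data.table(
    timestamp_iso8601 = format_iso(series$start_time, series$data$time),
    ax_g = series$data$ax, ay_g = series$data$ay, az_g = series$data$az)
  fwrite(dt, path)
  invisible(path)
}

#' @param rate Sampling rate in samples/s; inferred from the data when `NULL`.
#' @param span Session duration in seconds (optional).
#' @param patient_id,session Optional provenance labels.
#' @rdname write_accel_csv
#' @export
read_accel_csv <- function(path, rate = NULL, span = NULL,
                           patient_id = NA_character_, session = NA_character_) {
  dt <- fread(path, colClasses = list(character = "timestamp_iso8601"))
  req <- c("timestamp_iso8601", "ax_g", "ay_g", "az_g")
  if (!all(req %in% names(dt))) {
    abort(sprintf("%s: expected columns %s", path, paste(req, collapse = ", ")),
          class = "wearrehab_error_format")
  }
  tt <- parse_iso(dt$timestamp_iso8601, path)
  rt <- relative_times(tt, rate)
  accel_series(tibble(time = rt$time, ax = dt$ax_g, ay = dt$ay_g, az = dt$az_g),
               rate = rt$rate, start_time = rt$start_time, gaps = rt$gaps,
               span = span, patient_id = patient_id, session = session)
}

#' Write / read a heart-rate series as CSV
#'
#' Column layout `timestamp_iso8601,hr_bpm`.
#'
#' @param series An [hr_series()].
#' @param path CSV file path.
#' @return `write_hr_csv` returns `path` invisibly; `read_hr_csv` returns an
#'   [hr_series()].
#' @export
write_hr_csv <- function(series, path) {
  stopifnot(inherits(series, "hr_series"))
  dt <- data.table(
    timestamp_iso8601 = format_iso(series$start_time, series$data$time),
    hr_bpm = series$data$hr)
  fwrite(dt, path)
  invisible(path)
}

#' @inheritParams read_accel_csv
#' @rdname write_hr_csv
#' @export
read_hr_csv <- function(path, rate = NULL, span = NULL,
                        patient_id = NA_character_, session = NA_character_) {
  dt <- fread(path, colClasses = list(character = "timestamp_iso8601"))
  req <- c("timestamp_iso8601", "hr_bpm")
  if (!all(req %in% names(dt))) {
    abort(sprintf("%s: expected columns %s", path, paste(req, collapse = ", ")),
          class = "wearrehab_error_format")
  }
  tt <- parse_iso(dt$timestamp_iso8601, path)
  rt <- relative_times(tt, rate)
  hr_series(tibble(time = rt$time, hr = dt$hr_bpm),
            rate = rt$rate, start_time = rt$start_time, gaps = rt$gaps,
            span = span, patient_id = patient_id, session = session)
}

#' Write / read a period schedule as CSV
#'
#' Column layout `start,end,label` with ISO-8601 timestamps; intervals are
#' half-open `[start, end)`.
#'
#' @param schedule A [period_schedule()].
#' @param path CSV file path.
#' @param start_time `POSIXct` anchor of session second 0.
#' @return `write_schedule_csv` returns `path` invisibly; `read_schedule_csv`
#'   returns a [period_schedule()].
#' @export
write_schedule_csv <- function(schedule, path, start_time) {
  stopifnot(inherits(schedule, "period_schedule"))
  iv <- schedule$intervals
  dt <- data.table(start = format_iso(start_time, iv$start, digits = 0),
                   end = format_iso(start_time, iv$end, digits = 0),
                   label = iv$label)
  fwrite(dt, path)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path, start_time) {
  dt <- fread(path, colClasses = "character")
  req <- c("start", "end", "label")
  if (!all(req %in% names(dt))) {
    abort(sprintf("%s: expected columns start, end, label", path),
          class = "wearrehab_error_format")
  }
  if (nrow(dt) == 0) {
    return(period_schedule(tibble(start = numeric(0), end = numeric(0),
                                  label = character(0)), source = path))
  }
  s0 <- as.numeric(as_naive_time(start_time))
  period_schedule(tibble(
    start = as.numeric(parse_iso(dt$start, path)) - s0,
    end = as.numeric(parse_iso(dt$end, path)) - s0,
    label = dt$label), source = path)
}

#' Write / read a ground-truth annotation as JSON
#'
#' @param truth Annotation tibble from [generate_session()].
#' @param path JSON file path.
#' @return `write_truth_json` returns `path` invisibly; `read_truth_json`
#'   returns the annotation tibble.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Write / read a scenario configuration as JSON
#'
#' @param config A [scenario_config()].
#' @param path JSON file path.
#' @return `write_scenario_json` returns `path` invisibly;
#'   `read_scenario_json` returns a validated [scenario_config()].
#' @export
write_scenario_json <- function(config, path) {
  raw <- unclass(config)
  # keep the names of named-vector fields through JSON
  for (nm in c("posture_noise_sd", "hrr_mean_by_period")) {
    raw[[nm]] <- as.list(raw[[nm]])
  }
  jsonlite::write_json(raw, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_scenario_json
#' @export
read_scenario_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("posture_noise_sd", "hrr_mean_by_period")) {
    raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(scenario_config, raw)
}

#' Write a tabular summary as CSV
#'
#' Used for daily summaries, cohort tables, correlation grids and paired
#' comparisons. Plain UTF-8 CSV with `NA` for missing values.
#'
#' @param x A data frame.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  fwrite(as.data.table(x), path, na = "NA")
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "wearrehab_error_input")
  }
  dt <- fread(path, na.strings = "NA")
  if (nrow(dt) == 0) {
    abort(sprintf("%s is empty", path), class = "wearrehab_error_format")
  }
  as_tibble(dt)
}

#' Write a manifest of output files with checksums
#'
#' @param dir Directory whose files are listed.
#' @param path Output JSON path (default `manifest.json` inside `dir`).
#' @return The manifest tibble, invisibly.
#' @export
write_manifest <- function(dir, path = file.path(dir, "manifest.json")) {
  files <- sort(setdiff(list.files(dir, recursive = TRUE),
                        basename(path)))
  full <- file.path(dir, files)
  man <- tibble(file = files,
                bytes = file.size(full),
                md5 = unname(tools::md5sum(full)))
  jsonlite::write_json(man, path, digits = NA)
  invisible(man)
}

#' Packaged cohort-mean calibration values
#'
#' Cohort-level calibration constants used as generator defaults and in the
#' aggregation-contract checks: mean %HRR by period (24-hour, training,
#' nontraining) and daily MSDA components (total, training, nontraining) at
#' admission and 4 weeks.
#'
#' @return A nested list; see `inst/extdata/admission_calibration.json`.
#' @export
admission_calibration <- function() {
  jsonlite::read_json(system.file("extdata", "admission_calibration.json",
                                  package = "wearrehab", mustWork = TRUE),
                      simplifyVector = TRUE)
}
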