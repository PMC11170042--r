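#' @importFrom rlang abort warn
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median sd rnorm runif rbinom fft mvfft pnorm pt setNames
#' @importFrom utils head tail
NULL

POSTURE_LEVELS <- c("lying", "sitting_standing", "walking", "gap")
PERIOD_LEVELS <- c("training", "nontraining", "gap")
SCHEDULE_LEVELS <- c("training", "bathing_gap", "device_swap")
SESSION_LEVELS <- c("0W", "4W")

#' Tri-axial acceleration series
#'
#' A gap-aware container for chest-worn accelerometry. Sample times are
#' seconds since session start; `start_time` anchors them to wall-clock time
#' (timezone-naive local time, represented as UTC). Declared gaps are
#' half-open `[start, end)` intervals during which no samples exist.
#'
#' @param data Data frame with columns `time` (seconds, strictly increasing)
#'   and `ax`, `ay`, `az` (units of g).
#' @param rate Nominal sampling rate in samples/s.
#' @param start_time `POSIXct` wall-clock time of session second 0.
#' @param gaps Data frame with columns `start`, `end` (seconds), or `NULL`.
#' @param span Session duration in seconds; defaults to the last sample time
#'   rounded up to a whole second.
#' @param patient_id,session Optional provenance labels.
#' @return An object of class `accel_series`.
#' @export
accel_series <- function(data, rate, start_time, gaps = NULL, span = NULL,
                         patient_id = NA_character_, session = NA_character_) {
  data <- as_tibble(data)
  stopifnot(all(c("time", "ax", "ay", "az") %in% names(data)))
  if (rate <= 0) abort("`rate` must be > 0", class = "wearrehab_error_input")
  check_times_gaps(data$time, gaps)
  if (is.null(span)) span <- if (nrow(data)) ceiling(max(data$time) + 1 / rate) else 0
  structure(
    list(data = data, rate = rate, start_time = as_naive_time(start_time),
         gaps = normalize_gaps(gaps), span = span,
         patient_id = patient_id, session = session),
    class = "accel_series"
  )
}

#' Heart-rate series
#'
#' @param data Data frame with columns `time` (seconds) and `hr` (beats/min,
#'   all positive).
#' @inheritParams accel_series
#' @return An object of class `hr_series`.
#' @export
hr_series <- function(data, rate, start_time, gaps = NULL, span = NULL,
                      patient_id = NA_character_, session = NA_character_) {
  data <- as_tibble(data)
  stopifnot(all(c("time", "hr") %in% names(data)))
  if (any(data$hr <= 0)) abort("heart rate must be > 0 everywhere",
                               class = "wearrehab_error_input")
  check_times_gaps(data$time, gaps)
  if (is.null(span)) span <- if (nrow(data)) ceiling(max(data$time) + 1 / rate) else 0
  structure(
    list(data = data, rate = rate, start_time = as_naive_time(start_time),
         gaps = normalize_gaps(gaps), span = span,
         patient_id = patient_id, session = session),
    class = "hr_series"
  )
}

#' Posture epoch series
#'
#' Epochs are half-open intervals labelled `lying`, `sitting_standing`,
#' `walking` or `gap` that tile the session exactly.
#'
#' @param epochs Data frame with columns `start`, `end`, `label`.
#' @param epoch_length Epoch granularity used to build the series (seconds).
#' @return An object of class `posture_series`.
#' @export
posture_series <- function(epochs, epoch_length = NA_real_) {
  epochs <- as_tibble(epochs)
  stopifnot(all(c("start", "end", "label") %in% names(epochs)))
  bad <- setdiff(unique(epochs$label), POSTURE_LEVELS)
  if (length(bad)) abort(paste0("unknown posture label(s): ",
                                paste(bad, collapse = ", ")),
                         class = "wearrehab_error_input")
  if (nrow(epochs) > 1 &&
      any(abs(epochs$start[-1] - epochs$end[-nrow(epochs)]) > 1e-9)) {
    abort("posture epochs must tile the session without holes or overlaps",
          class = "wearrehab_error_input")
  }
  structure(list(epochs = epochs, epoch_length = epoch_length),
            class = "posture_series")
}

#' Windowed MSDA series
#'
#' Moving standard deviation of acceleration: per non-overlapping window, the
#' sample SD (denominator n - 1) of the Euclidean norm of the tri-axial
#' signal, in g.
#'
#' @param windows Data frame with columns `start` (seconds) and `msda` (g).
#' @param window_length Window length in seconds.
#' @return An object of class `msda_series`.
#' @export
msda_series <- function(windows, window_length) {
  windows <- as_tibble(windows)
  stopifnot(all(c("start", "msda") %in% names(windows)))
  if (any(windows$msda < 0)) abort("msda must be >= 0",
                                   class = "wearrehab_error_input")
  if (is.unsorted(windows$start, strictly = TRUE) && nrow(windows) > 1) {
    abort("msda windows must be ordered and non-overlapping",
          class = "wearrehab_error_input")
  }
  structure(list(windows = windows, window_length = window_length),
            class = "msda_series")
}

#' Therapist-recorded period schedule
#'
#' Labelled half-open intervals in session seconds: `training` blocks,
#' `bathing_gap` pauses, and the `device_swap` gap. Wear time not covered by a
#' training interval is the nontraining period.
#'
#' @param intervals Data frame with columns `start`, `end`, `label`.
#' @param source Free-text provenance note.
#' @return An object of class `period_schedule`.
#' @export
period_schedule <- function(intervals, source = "unspecified") {
  intervals <- as_tibble(intervals)
  stopifnot(all(c("start", "end", "label") %in% names(intervals)))
  bad <- setdiff(unique(intervals$label), SCHEDULE_LEVELS)
  if (length(bad)) abort(paste0("unknown schedule label(s): ",
                                paste(bad, collapse = ", ")),
                         class = "wearrehab_error_input")
  tr <- intervals[intervals$label == "training", , drop = FALSE]
  if (nrow(tr) > 1) {
    tr <- tr[order(tr$start), ]
    if (any(tr$start[-1] < tr$end[-nrow(tr)] - 1e-9)) {
      abort("training intervals must not overlap",
            class = "wearrehab_error_input")
    }
  }
  structure(list(intervals = intervals[order(intervals$start), ],
                 source = source),
            class = "period_schedule")
}

#' Heart-rate-reserve anchors
#'
#' @param hr_rest Resting heart rate (beats/min), the lower anchor.
#' @param hr_max Maximum heart rate (beats/min), the upper anchor.
#' @param source_max Either `"measured"` or `"age_estimated"`.
#' @return An object of class `hrr_params`.
#' @export
hrr_params <- function(hr_rest, hr_max, source_max = c("age_estimated", "measured")) {
  source_max <- match.arg(source_max)
  if (!(hr_max > hr_rest && hr_rest > 0)) {
    abort(sprintf("need hr_max > hr_rest > 0, got hr_max = %.6g, hr_rest = %.6g",
                  hr_max, hr_rest),
          class = "wearrehab_error_input")
  }
  structure(list(hr_rest = hr_rest, hr_max = hr_max, source_max = source_max),
            class = "hrr_params")
}

# ---- internal helpers --------------------------------------------------------

as_naive_time <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(format(x, tz = attr(x, "tzone") %||% ""), tz = "UTC"))
  as.POSIXct(x, tz = "UTC")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

normalize_gaps <- function(gaps) {
  if (is.null(gaps) || NROW(gaps) == 0) {
    return(tibble(start = numeric(0), end = numeric(0)))
  }
  gaps <- as_tibble(gaps)[, c("start", "end")]
  gaps[order(gaps$start), ]
}

check_times_gaps <- function(time, gaps) {
  if (length(time) > 1 && is.unsorted(time, strictly = TRUE)) {
    abort("timestamps must be strictly increasing", class = "wearrehab_error_input")
  }
  if (!is.null(gaps) && NROW(gaps) > 0 && length(time)) {
    if (any(in_intervals(time, as_tibble(gaps)))) {
      abort("samples found inside a declared gap", class = "wearrehab_error_input")
    }
  }
  invisible(TRUE)
}

# TRUE for points inside the union of sorted, non-overlapping half-open
# [start, end) intervals.
in_intervals <- function(t, intervals) {
  if (NROW(intervals) == 0) return(rep(FALSE, length(t)))
  intervals <- intervals[order(intervals$start), , drop = FALSE]
  idx <- findInterval(t, intervals$start)
  ok <- idx > 0
  ok[ok] <- t[ok] < intervals$end[idx[ok]]
  ok
}

# Total length of the overlap of [a0, a1) with each [start, end) interval.
overlap_minutes <- function(a0, a1, starts, ends) {
  sum(pmax(0, pmin(a1, ends) - pmax(a0, starts))) / 60
}

# "HH:MM" or "HH:MM:SS" -> seconds from midnight
clock_seconds <- function(x) {
  parts <- lapply(strsplit(x, ":", fixed = TRUE), as.numeric)
  vapply(parts, function(p) sum(p * c(3600, 60, 1)[seq_along(p)]), numeric(1))
}

# seconds-of-day of a naive POSIXct
seconds_of_day <- function(tt) {
  as.numeric(tt) - as.numeric(trunc(tt, "days"))
}

# Deterministic sub-seed derivation: every random stream in the package draws
# from a seed derived from the single config seed. Kept below 2^31 - 1.
derive_seed <- function(seed, ...) {
  ids <- c(...)
  s <- as.numeric(seed) %% 2147483647
  for (k in seq_along(ids)) {
    s <- (s * 48271 + as.numeric(ids[k]) * 1009 + k) %% 2147483647
  }
  as.integer(s)
}

#' @export
print.accel_series <- function(x, ...) {
  cat(sprintf("<accel_series> %d samples @ %g Hz, span %.0f s, %d gap(s)\n",
              nrow(x$data), x$rate, x$span, nrow(x$gaps)))
  invisible(x)
}

#' @export
print.hr_series <- function(x, ...) {
  cat(sprintf("<hr_series> %d samples @ %g Hz, span %.0f s, %d gap(s)\n",
              nrow(x$data), x$rate, x$span, nrow(x$gaps)))
  invisible(x)
}

#' @export
print.posture_series <- function(x, ...) {
  durs <- tapply((x$epochs$end - x$epochs$start) / 60, x$epochs$label, sum)
  cat("<posture_series> minutes by label:\n")
  print(round(durs, 1))
  invisible(x)
}

#' @export
print.msda_series <- function(x, ...) {
  cat(sprintf("<msda_series> %d windows of %g s, total %.3f g\n",
              nrow(x$windows), x$window_length, sum(x$windows$msda)))
  invisible(x)
}
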