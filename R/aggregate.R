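#' Split a session into calendar days
#'
#' Days are `[00:00, 24:00)` local-clock slices of the session timeline.
#' Leading/trailing partial slices are flagged (`full = FALSE`) and excluded
#' from cohort means by default downstream.
#'
#' @param start_time `POSIXct` wall-clock time of session second 0, or any
#'   series object (`accel_series`, `hr_series`, `hrr_series`) carrying
#'   `start_time` and `span`.
#' @param span Session duration in seconds (ignored when a series is given).
#' @return A tibble with `day_index`, `start`, `end` (session seconds),
#'   `date` and `full`.
#' @export
split_days <- function(start_time, span = NULL) {
  if (is.list(start_time) && !is.null(start_time$start_time)) {
    span <- start_time$span
    start_time <- start_time$start_time
  }
  stopifnot(inherits(start_time, "POSIXct"), is.numeric(span), span > 0)
  off0 <- seconds_of_day(start_time)
  k <- seq_len(ceiling((off0 + span) / 86400))
  bounds <- sort(unique(c(0, k * 86400 - off0, span)))
  bounds <- bounds[bounds >= 0 & bounds <= span]
  tibble(
    day_index = seq_len(length(bounds) - 1),
    start = bounds[-length(bounds)],
    end = bounds[-1],
    date = format(start_time + bounds[-length(bounds)], "%Y-%m-%d"),
    full = abs(diff(bounds) - 86400) < 1e-6
  )
}

#' Per-day activity, intensity and posture summary
#'
#' Aggregates one calendar day: posture minutes from epoch durations, MSDA
#' totals split into training/nontraining by each window's start time, and
#' unweighted mean %HRR overall and per period. A window or sample inside a
#' recording gap counts toward no period; a fully gapped day yields missing
#' values, never zeros.
#'
#' Any of `msda`, `hrr`, `posture` may be `NULL`, in which case the
#' corresponding summary fields are missing — useful when only part of the
#' measurement stage was run.
#'
#' @param msda An [msda_series()], or `NULL`.
#' @param hrr An `hrr_series` from [percent_hrr()], or `NULL`.
#' @param posture A [posture_series()], or `NULL`.
#' @param schedule A [period_schedule()].
#' @param day One row of [split_days()].
#' @param hr_rest Resting heart rate to report alongside (beats/min).
#' @param patient_id,session Provenance labels.
#' @return A one-row tibble (one `DailySummary`).
#' @export
aggregate_day <- function(msda, hrr, posture, schedule, day,
                          hr_rest = NA_real_,
                          patient_id = NA_character_, session = NA_character_) {
  stopifnot(is.null(msda) || inherits(msda, "msda_series"),
            is.null(posture) || inherits(posture, "posture_series"),
            inherits(schedule, "period_schedule"))
  d0 <- day$start; d1 <- day$end
  training <- schedule$intervals[schedule$intervals$label == "training",
                                 c("start", "end")]

  # posture minutes from epoch overlap with the day
  if (is.null(posture)) {
    mins <- setNames(rep(NA_real_, length(POSTURE_LEVELS)), POSTURE_LEVELS)
  } else {
    ep <- posture$epochs
    mins <- vapply(POSTURE_LEVELS, function(lb) {
      sel <- ep$label == lb
      overlap_minutes(d0, d1, ep$start[sel], ep$end[sel])
    }, numeric(1))
  }

  # MSDA sums; window belongs to a period by its start time
  w <- if (is.null(msda)) tibble(start = numeric(0), msda = numeric(0)) else
    msda$windows[msda$windows$start >= d0 & msda$windows$start < d1, ]
  if (nrow(w) == 0) {
    msda_tr <- msda_nt <- msda_tot <- NA_real_
  } else {
    in_tr <- in_intervals(w$start, training)
    msda_tr <- sum(w$msda[in_tr])
    msda_nt <- sum(w$msda[!in_tr])
    msda_tot <- msda_tr + msda_nt
  }

  # %HRR means: unweighted over samples in each period
  h <- if (is.null(hrr)) tibble(time = numeric(0), hrr = numeric(0)) else
    hrr$data[hrr$data$time >= d0 & hrr$data$time < d1, ]
  if (nrow(h) == 0) {
    m_tot <- m_tr <- m_nt <- NA_real_
    n_tr <- n_nt <- 0L
  } else {
    in_tr <- in_intervals(h$time, training)
    n_tr <- sum(in_tr); n_nt <- sum(!in_tr)
    m_tr <- if (n_tr) mean(h$hrr[in_tr]) else NA_real_
    m_nt <- if (n_nt) mean(h$hrr[!in_tr]) else NA_real_
    m_tot <- mean(h$hrr)
  }

  tibble(
    patient_id = patient_id, session = session,
    day_index = day$day_index, date = day$date %||% NA_character_,
    full = day$full,
    minutes_lying = mins[["lying"]],
    minutes_sitting_standing = mins[["sitting_standing"]],
    minutes_walking = mins[["walking"]],
    minutes_gap = mins[["gap"]],
    msda_total = msda_tot, msda_training = msda_tr, msda_nontraining = msda_nt,
    hrr_mean_total = m_tot, hrr_mean_training = m_tr, hrr_mean_nontraining = m_nt,
    hrr_n_training = n_tr, hrr_n_nontraining = n_nt,
    hr_rest = hr_rest,
    valid = nrow(w) > 0 || nrow(h) > 0
  )
}

#' Per patient-session cohort summaries
#'
#' Averages each metric over a session's full days and emits one row per
#' patient per session, joined with age, sex and the session's FIM motor
#' score. Patients missing a session get a row of missing markers.
#'
#' @param daily Tibble of [aggregate_day()] rows.
#' @param profiles Profile tibble with `patient_id`, `age`, `sex`,
#'   `fim_motor_0w`, `fim_motor_4w`.
#' @param sessions Sessions the table should cover.
#' @param include_partial Include partial days in the means? Default `FALSE`.
#' @return A `CohortTable` tibble, one row per patient-session.
#' @export
cohort_summaries <- function(daily, profiles, sessions = SESSION_LEVELS,
                             include_partial = FALSE) {
  metrics <- c("minutes_lying", "minutes_sitting_standing", "minutes_walking",
               "minutes_gap", "msda_total", "msda_training", "msda_nontraining",
               "hrr_mean_total", "hrr_mean_training", "hrr_mean_nontraining",
               "hr_rest")
  use <- daily[daily$valid & (include_partial | daily$full), , drop = FALSE]
  grid <- expand.grid(patient_id = profiles$patient_id, session = sessions,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    pid <- grid$patient_id[i]; ss <- grid$session[i]
    p <- profiles[profiles$patient_id == pid, ]
    sub <- use[use$patient_id == pid & use$session == ss, , drop = FALSE]
    vals <- if (nrow(sub)) {
      vapply(metrics, function(m) mean(sub[[m]], na.rm = FALSE), numeric(1))
    } else {
      setNames(rep(NA_real_, length(metrics)), metrics)
    }
    fim <- if (ss == "0W") p$fim_motor_0w else p$fim_motor_4w
    out <- tibble(patient_id = pid, session = ss, n_days = nrow(sub),
                  age = p$age, sex = p$sex, fim_motor = fim)
    for (m in metrics) out[[m]] <- vals[[m]]
    out
  })
  do.call(rbind, rows)
}

#' Reconstruct the overall %HRR mean from period means
#'
#' Identity check used by the test-suite and provenance reports: the overall
#' daily %HRR mean must equal the sample-count-weighted mean of the
#' training and nontraining period means.
#'
#' @param summary A one-row tibble from [aggregate_day()].
#' @return The reconstructed overall mean (percent).
#' @export
reconstruct_hrr_total <- function(summary) {
  n_tr <- summary$hrr_n_training; n_nt <- summary$hrr_n_nontraining
  m_tr <- ifelse(n_tr > 0, summary$hrr_mean_training, 0)
  m_nt <- ifelse(n_nt > 0, summary$hrr_mean_nontraining, 0)
  (n_tr * m_tr + n_nt * m_nt) / (n_tr + n_nt)
}
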