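#' Intensity-recovery harness for one synthetic day
#'
#' Generates a single-patient session from `config`, then runs the intensity
#' pipeline exactly as on real data: posture classification, resting heart
#' rate (median lying heart rate in the night window), age-based maximum
#' heart rate, the %HRR transform, and the per-day aggregation. Returns the
#' recovered daily means next to the generator's configured truth, so
#' calibration fidelity can be measured.
#'
#' @param config A [scenario_config()]; the first generated patient is used.
#' @param session `"0W"` or `"4W"`.
#' @return A one-row tibble: recovered and true daily mean %HRR (overall,
#'   training, nontraining) and the estimated and true resting heart rate.
#' @export
hrr_recovery_run <- function(config, session = "0W") {
  profiles <- generate_profiles(config)
  prof <- profiles[1, ]
  s <- generate_session(prof, config, session)
  posture <- classify_posture(s$accel, refine_walking = FALSE)
  hp <- session_hrr_params(s$hr, posture, prof)
  hrr <- percent_hrr(s$hr, hp)
  days <- split_days(s$hr)
  day <- days[days$full, ][1, ]
  agg <- aggregate_day(NULL, hrr, posture, s$schedule, day)

  # configured truth, weighted by measured (non-gap) time inside the day
  tr <- s$truth
  dur <- pmax(0, pmin(tr$end, day$end) - pmax(tr$start, day$start))
  meas <- !is.na(tr$hrr_mean) & dur > 0
  truth_wmean <- function(sel) {
    sum(tr$hrr_mean[sel] * dur[sel]) / sum(dur[sel])
  }
  tibble(
    recovered_total = agg$hrr_mean_total,
    recovered_training = agg$hrr_mean_training,
    recovered_nontraining = agg$hrr_mean_nontraining,
    truth_total = truth_wmean(meas),
    truth_training = truth_wmean(meas & tr$period == "training"),
    truth_nontraining = truth_wmean(meas & tr$period == "nontraining"),
    hr_rest_est = hp$hr_rest,
    hr_rest_true = prof$hr_rest_true
  )
}

#' Cohort structure-recovery harness
#'
#' Generates the configured cohort one patient at a time, computes MSDA and
#' the per-day training/nontraining decomposition through the standard
#' aggregation path, and returns one row per patient with the recovered
#' first-day MSDA components next to the covariates (FIM motor score, age),
#' ready for rank-correlation against the generator's coupling structure.
#'
#' @param config A [scenario_config()].
#' @param session `"0W"` or `"4W"`.
#' @return A tibble with `patient_id`, `fim_motor`, `age`, `msda_total`,
#'   `msda_training`, `msda_nontraining`.
#' @export
msda_structure_run <- function(config, session = "0W") {
  profiles <- generate_profiles(config)
  struct <- inject_cohort_structure(profiles, config)
  rows <- lapply(seq_len(nrow(profiles)), function(i) {
    mrow <- struct[struct$patient_id == profiles$patient_id[i] &
                     struct$session == session, ]
    s <- generate_session(profiles[i, ], config, session,
                          m_training = mrow$m_training,
                          m_nontraining = mrow$m_nontraining)
    msda <- compute_msda(s$accel)
    day <- split_days(s$accel)[1, ]
    agg <- aggregate_day(msda, NULL, NULL, s$schedule, day)
    tibble(patient_id = profiles$patient_id[i],
           fim_motor = if (session == "0W") profiles$fim_motor_0w[i] else
             profiles$fim_motor_4w[i],
           age = profiles$age[i],
           msda_total = agg$msda_total,
           msda_training = agg$msda_training,
           msda_nontraining = agg$msda_nontraining)
  })
  do.call(rbind, rows)
}
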