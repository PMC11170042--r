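#' Scenario configuration for the synthetic cohort generator
#'
#' Defines the emulated ward recording protocol: 48-hour continuous wear with
#' a chest strap sampling tri-axial acceleration at 25 Hz and heart rate at
#' 1 Hz, a structured ward day (night lying block, daytime sitting/standing
#' with short walking bouts, scheduled training blocks, one bathing pause per
#' day, a device swap at wear hour 24), an intensity process calibrated in
#' percent heart rate reserve, and a cohort coupling in which training-period
#' activity scales with the FIM motor score while nontraining activity
#' declines with age.
#'
#' @param n_patients Number of patients in the cohort.
#' @param session_hours Recording duration per session (hours).
#' @param accel_rate Accelerometer sampling rate (samples/s).
#' @param hr_rate Heart-rate sampling rate (samples/s).
#' @param training_minutes_per_day Scheduled training time per day (minutes),
#'   split over the training blocks.
#' @param posture_noise_sd Named vector of per-posture activity levels (g):
#'   the 2-s-window MSDA each posture realizes in expectation.
#' @param walking_cadence Gait cadence (Hz) of the walking oscillation.
#' @param walking_amplitude Amplitude (g) of the walking oscillation along the
#'   trunk axis.
#' @param hrr_mean_by_period Named vector (`training`, `nontraining`): true
#'   mean percent heart rate reserve over each period, in percent.
#' @param hrr_mean_sleep True mean %HRR during the night lying block
#'   (percent). Kept low so the night median heart rate identifies the
#'   resting heart rate; the daytime nontraining level is derived so the
#'   overall nontraining mean equals `hrr_mean_by_period["nontraining"]`.
#' @param coupling_fim_to_training_activity Slope (per SD of FIM motor score)
#'   of the log training-activity multiplier.
#' @param coupling_age_to_nontraining_activity Slope (per SD of age) of the
#'   log nontraining-activity multiplier; negative means older patients move
#'   less outside training.
#' @param coupling_noise_sd SD of the patient-level log-normal noise on the
#'   activity multipliers.
#' @param bathing_gap_minutes Daily measurement pause for bathing (minutes).
#' @param device_swap_gap_minutes Recording gap while the strap and
#'   transmitter are replaced at wear hour 24 (minutes).
#' @param rng_seed Integer seed; all randomness derives from it.
#' @param start_date,start_clock Wall-clock start of each session
#'   (timezone-naive local time).
#' @param rise,lights_out Clock times bounding the daytime (upright) part of
#'   the ward day.
#' @param training_blocks Clock start times of the training blocks.
#' @param bathing_start Clock start time of the daily bathing pause.
#' @param walking_minutes_nontraining,walking_minutes_training Walking-bout
#'   minutes per day placed outside/inside training blocks.
#' @param walking_bout_minutes Length of one walking bout (minutes).
#' @param accel_noise_tau Correlation time (s) of the AR(1) postural-sway
#'   noise on each accelerometer axis.
#' @param hr_noise_sd SD (in %HRR points) of the AR(1) noise on the intensity
#'   process.
#' @param hr_noise_tau Correlation time (s) of the intensity noise.
#' @param hr_rest_mean,hr_rest_sd Cohort distribution of the true resting
#'   heart rate (beats/min).
#' @param age_mean,age_sd,fim_mean,fim_sd Cohort distributions of age (years)
#'   and FIM motor score at admission.
#' @param fim_gain_mean,fim_gain_sd Distribution of the 4-week FIM motor gain.
#' @param allow_fim_decline If `FALSE` (default) the 4-week score never drops
#'   below admission.
#' @param p_female Probability a generated patient is female.
#' @param hr_max_formula `"fox"` (220 - age) or `"tanaka"` (208 - 0.7 age) for
#'   the generator's maximum heart rate when no measured value exists.
#' @return An object of class `scenario_config` (a validated list).
#' @export
scenario_config <- function(n_patients = 11,
                            session_hours = 48,
                            accel_rate = 25,
                            hr_rate = 1,
                            training_minutes_per_day = 180,
                            posture_noise_sd = c(lying = 0.005,
                                                 sitting_standing = 0.02,
                                                 walking = 0.05),
                            walking_cadence = 1.9,
                            walking_amplitude = 0.35,
                            hrr_mean_by_period = c(training = 22.13,
                                                   nontraining = 9.47),
                            hrr_mean_sleep = 0,
                            coupling_fim_to_training_activity = 0.7,
                            coupling_age_to_nontraining_activity = -0.7,
                            coupling_noise_sd = 0.28,
                            bathing_gap_minutes = 30,
                            device_swap_gap_minutes = 2,
                            rng_seed = 1L,
                            start_date = "2024-03-04",
                            start_clock = "00:00",
                            rise = "06:00",
                            lights_out = "21:00",
                            training_blocks = c("09:30", "14:00"),
                            bathing_start = "17:30",
                            walking_minutes_nontraining = 12,
                            walking_minutes_training = 6,
                            walking_bout_minutes = 2,
                            accel_noise_tau = 1,
                            hr_noise_sd = 3,
                            hr_noise_tau = 30,
                            hr_rest_mean = 62,
                            hr_rest_sd = 6,
                            age_mean = 65,
                            age_sd = 13,
                            fim_mean = 52.2,
                            fim_sd = 16.6,
                            fim_gain_mean = 12,
                            fim_gain_sd = 6,
                            allow_fim_decline = FALSE,
                            p_female = 6 / 11,
                            hr_max_formula = c("fox", "tanaka")) {
  cfg <- list(
    n_patients = n_patients, session_hours = session_hours,
    accel_rate = accel_rate, hr_rate = hr_rate,
    training_minutes_per_day = training_minutes_per_day,
    posture_noise_sd = posture_noise_sd,
    walking_cadence = walking_cadence, walking_amplitude = walking_amplitude,
    hrr_mean_by_period = hrr_mean_by_period, hrr_mean_sleep = hrr_mean_sleep,
    coupling_fim_to_training_activity = coupling_fim_to_training_activity,
    coupling_age_to_nontraining_activity = coupling_age_to_nontraining_activity,
    coupling_noise_sd = coupling_noise_sd,
    bathing_gap_minutes = bathing_gap_minutes,
    device_swap_gap_minutes = device_swap_gap_minutes,
    rng_seed = as.integer(rng_seed),
    start_date = start_date, start_clock = start_clock,
    rise = rise, lights_out = lights_out,
    training_blocks = training_blocks, bathing_start = bathing_start,
    walking_minutes_nontraining = walking_minutes_nontraining,
    walking_minutes_training = walking_minutes_training,
    walking_bout_minutes = walking_bout_minutes,
    accel_noise_tau = accel_noise_tau,
    hr_noise_sd = hr_noise_sd, hr_noise_tau = hr_noise_tau,
    hr_rest_mean = hr_rest_mean, hr_rest_sd = hr_rest_sd,
    age_mean = age_mean, age_sd = age_sd,
    fim_mean = fim_mean, fim_sd = fim_sd,
    fim_gain_mean = fim_gain_mean, fim_gain_sd = fim_gain_sd,
    allow_fim_decline = allow_fim_decline, p_female = p_female,
    hr_max_formula = match.arg(hr_max_formula)
  )
  class(cfg) <- "scenario_config"
  validate_scenario_config(cfg)
  cfg
}

validate_scenario_config <- function(cfg) {
  err <- function(msg) abort(msg, class = "wearrehab_error_config")
  if (cfg$n_patients < 1) err("n_patients must be >= 1")
  if (cfg$accel_rate <= 0 || cfg$hr_rate <= 0) err("all sampling rates must be > 0")
  if (cfg$session_hours <= 0) err("session_hours must be > 0")
  hrm <- cfg$hrr_mean_by_period
  if (!all(c("training", "nontraining") %in% names(hrm))) {
    err("hrr_mean_by_period needs named entries 'training' and 'nontraining'")
  }
  if (any(hrm < 0 | hrm > 100) || cfg$hrr_mean_sleep < 0 || cfg$hrr_mean_sleep > 100) {
    err("%HRR means must lie in [0, 100]")
  }
  if (cfg$training_minutes_per_day < 0 || cfg$training_minutes_per_day >= 24 * 60) {
    err("training_minutes_per_day must lie in [0, 1440)")
  }
  if (!all(POSTURE_LEVELS[1:3] %in% names(cfg$posture_noise_sd))) {
    err("posture_noise_sd needs entries lying, sitting_standing, walking")
  }
  if (any(cfg$posture_noise_sd < 0)) err("posture_noise_sd must be >= 0")
  if (!is.finite(cfg$coupling_fim_to_training_activity) ||
      !is.finite(cfg$coupling_age_to_nontraining_activity)) {
    err("coupling slopes must be finite")
  }
  # Session length must resolve to whole samples on both grids
  if (abs(cfg$session_hours * 3600 * cfg$accel_rate -
          round(cfg$session_hours * 3600 * cfg$accel_rate)) > 1e-6) {
    err("session_hours * accel_rate must give a whole number of samples")
  }
  # Training blocks must fit the daytime window and must never touch the
  # night resting-HR window [00:00, 05:00): the resting-HR extraction relies
  # on undisturbed lying sleep there.
  n_blocks <- length(cfg$training_blocks)
  if (cfg$training_minutes_per_day > 0) {
    if (n_blocks < 1) err("training_minutes_per_day > 0 needs >= 1 training block")
    dur <- cfg$training_minutes_per_day * 60 / n_blocks
    bs <- clock_seconds(cfg$training_blocks)
    be <- bs + dur
    rise_s <- clock_seconds(cfg$rise); lo_s <- clock_seconds(cfg$lights_out)
    if (any(bs < rise_s | be > lo_s)) {
      err("training blocks must lie within the daytime window [rise, lights_out)")
    }
    if (any(pmin(be, 5 * 3600) > pmax(bs, 0))) {
      err("training blocks must not overlap the 00:00-05:00 night window")
    }
    if (n_blocks > 1 && any(bs[-1] < be[-n_blocks])) err("training blocks overlap")
    bath_s <- clock_seconds(cfg$bathing_start)
    bath_e <- bath_s + cfg$bathing_gap_minutes * 60
    if (any(pmin(be, bath_e) > pmax(bs, bath_s))) {
      err("bathing pause overlaps a training block")
    }
    if (bath_s < rise_s || bath_e > lo_s) err("bathing pause must be in the daytime window")
  }
  invisible(cfg)
}

# ---- day plan and session ground truth --------------------------------------

# Split `parent` rows of a tiling by the rows in `cuts` (each cut lies inside
# exactly one parent row); returns the refined tiling, sorted.
carve_intervals <- function(base, cuts) {
  if (NROW(cuts) == 0) return(base[order(base$start), ])
  cuts <- cuts[order(cuts$start), , drop = FALSE]
  for (i in seq_len(nrow(cuts))) {
    ct <- cuts[i, , drop = FALSE]
    j <- which(base$start <= ct$start + 1e-9 & base$end >= ct$end - 1e-9)
    if (length(j) == 0) abort("internal: cut not inside a single segment")
    j <- j[1]
    parent <- base[j, , drop = FALSE]
    pieces <- list()
    if (ct$start > parent$start + 1e-9) {
      left <- parent; left$end <- ct$start; pieces <- c(pieces, list(left))
    }
    pieces <- c(pieces, list(ct))
    if (ct$end < parent$end - 1e-9) {
      right <- parent; right$start <- ct$end; pieces <- c(pieces, list(right))
    }
    base <- rbind(base[seq_len(j - 1), , drop = FALSE],
                  do.call(rbind, pieces),
                  if (j < nrow(base)) base[(j + 1):nrow(base), , drop = FALSE])
  }
  base[order(base$start), ]
}

seg_row <- function(start, end, posture, period, sleep = FALSE, kind = NA_character_) {
  tibble(start = start, end = end, posture = posture, period = period,
         sleep = sleep, kind = kind)
}

# Deterministically place `n` walking bouts of `bout_s` seconds inside the
# given segments, proportionally to segment length, at evenly spaced interior
# positions. Returns a tibble of bout intervals.
place_bouts <- function(segments, n, bout_s, margin = 120) {
  if (n <= 0 || NROW(segments) == 0) {
    return(tibble(start = numeric(0), end = numeric(0)))
  }
  segments <- segments[order(segments$start), , drop = FALSE]
  len <- segments$end - segments$start
  eligible <- len >= bout_s + 2 * margin
  if (!any(eligible)) return(tibble(start = numeric(0), end = numeric(0)))
  len_e <- ifelse(eligible, len, 0)
  raw <- n * len_e / sum(len_e)
  quota <- floor(raw)
  rem <- n - sum(quota)
  if (rem > 0) {
    ord <- order(raw - quota, decreasing = TRUE)
    quota[ord[seq_len(rem)]] <- quota[ord[seq_len(rem)]] + 1
  }
  out <- vector("list", nrow(segments))
  for (i in seq_len(nrow(segments))) {
    q <- quota[i]
    if (q == 0) next
    usable0 <- segments$start[i] + margin
    usable1 <- segments$end[i] - margin - bout_s
    # cap the quota so bouts stay disjoint with some slack
    q <- min(q, max(1, floor((usable1 - usable0) / (2 * bout_s))))
    pos <- usable0 + (seq_len(q) - 0.5) / q * (usable1 - usable0)
    pos <- round(pos)
    out[[i]] <- tibble(start = pos, end = pos + bout_s)
  }
  do.call(rbind, c(out, list(tibble(start = numeric(0), end = numeric(0)))))
}

# One generic ward day in clock seconds [0, 86400), as a posture/period tiling.
build_day_plan <- function(cfg) {
  rise_s <- clock_seconds(cfg$rise)
  lo_s <- clock_seconds(cfg$lights_out)
  plan <- rbind(
    seg_row(0, rise_s, "lying", "nontraining", sleep = TRUE),
    seg_row(rise_s, lo_s, "sitting_standing", "nontraining"),
    seg_row(lo_s, 86400, "lying", "nontraining", sleep = TRUE)
  )
  # training blocks
  if (cfg$training_minutes_per_day > 0) {
    dur <- cfg$training_minutes_per_day * 60 / length(cfg$training_blocks)
    bs <- clock_seconds(cfg$training_blocks)
    plan <- carve_intervals(plan, seg_row(bs, bs + dur, "sitting_standing", "training"))
  }
  # bathing pause (measurement halted)
  if (cfg$bathing_gap_minutes > 0) {
    b0 <- clock_seconds(cfg$bathing_start)
    plan <- carve_intervals(
      plan, seg_row(b0, b0 + cfg$bathing_gap_minutes * 60, "gap", "gap",
                    kind = "bathing_gap"))
  }
  bout_s <- cfg$walking_bout_minutes * 60
  # walking bouts outside training
  sit_nt <- plan[plan$posture == "sitting_standing" & plan$period == "nontraining", ]
  n_nt <- round(cfg$walking_minutes_nontraining / cfg$walking_bout_minutes)
  bouts <- place_bouts(sit_nt, n_nt, bout_s)
  if (nrow(bouts)) {
    plan <- carve_intervals(plan, seg_row(bouts$start, bouts$end, "walking", "nontraining"))
  }
  # walking bouts inside training (gait training)
  tr <- plan[plan$period == "training" & plan$posture == "sitting_standing", ]
  n_tr <- round(cfg$walking_minutes_training / cfg$walking_bout_minutes)
  bouts <- place_bouts(tr, n_tr, bout_s, margin = 60)
  if (nrow(bouts)) {
    plan <- carve_intervals(plan, seg_row(bouts$start, bouts$end, "walking", "training"))
  }
  plan
}

merge_tiling <- function(x, keys = c("posture", "period", "sleep", "kind")) {
  if (nrow(x) < 2) return(x)
  key <- do.call(paste, c(x[keys], sep = "\r"))
  new_run <- c(TRUE, key[-1] != key[-length(key)] |
                 abs(x$start[-1] - x$end[-nrow(x)]) > 1e-9)
  run <- cumsum(new_run)
  first <- !duplicated(run)
  out <- x[first, , drop = FALSE]
  out$end <- tapply(x$end, run, max)[as.character(unique(run))]
  out$end <- as.numeric(out$end)
  out
}

# Ground-truth tiling and therapist schedule for one session, in session
# seconds [0, span).
build_session_truth <- function(cfg) {
  span <- cfg$session_hours * 3600
  off0 <- clock_seconds(cfg$start_clock)
  plan <- build_day_plan(cfg)
  k_days <- seq(0, floor((off0 + span - 1) / 86400))
  rows <- lapply(k_days, function(k) {
    p <- plan
    p$start <- p$start + k * 86400 - off0
    p$end <- p$end + k * 86400 - off0
    p <- p[p$end > 0 & p$start < span, , drop = FALSE]
    p$start <- pmax(p$start, 0); p$end <- pmin(p$end, span)
    p
  })
  truth <- do.call(rbind, rows)
  truth <- truth[order(truth$start), ]
  # device swap: short recording gap at wear hour 24
  if (span > 86400 && cfg$device_swap_gap_minutes > 0) {
    swap <- seg_row(86400, min(span, 86400 + cfg$device_swap_gap_minutes * 60),
                    "gap", "gap", kind = "device_swap")
    truth <- carve_intervals(truth, swap)
  }
  truth <- merge_tiling(truth)
  stopifnot(abs(truth$start[1]) < 1e-9,
            abs(truth$end[nrow(truth)] - span) < 1e-9,
            all(abs(truth$start[-1] - truth$end[-nrow(truth)]) < 1e-9))

  # therapist schedule: training blocks (whole blocks, not split by posture),
  # bathing pauses, device swap
  sched <- merge_tiling(truth[truth$period == "training", , drop = FALSE],
                        keys = "period")
  sched_rows <- list()
  if (nrow(sched)) {
    sched_rows <- c(sched_rows, list(tibble(start = sched$start, end = sched$end,
                                            label = "training")))
  }
  gaps <- truth[truth$posture == "gap", , drop = FALSE]
  if (nrow(gaps)) {
    sched_rows <- c(sched_rows, list(tibble(start = gaps$start, end = gaps$end,
                                            label = ifelse(is.na(gaps$kind),
                                                           "bathing_gap", gaps$kind))))
  }
  schedule <- period_schedule(do.call(rbind, c(sched_rows,
                                               list(tibble(start = numeric(0),
                                                           end = numeric(0),
                                                           label = character(0))))),
                              source = "synthetic therapist log")
  list(truth = truth, schedule = schedule, span = span)
}

# Attach true %HRR means and activity SDs to a truth tiling.
annotate_truth <- function(truth, cfg, m_training = 1, m_nontraining = 1) {
  hrm <- cfg$hrr_mean_by_period
  # derive the daytime nontraining %HRR level so the measured nontraining
  # period mean equals the configured value despite the low-%HRR sleep block
  t_sleep <- sum((truth$end - truth$start)[truth$period == "nontraining" & truth$sleep])
  t_day_nt <- sum((truth$end - truth$start)[truth$period == "nontraining" & !truth$sleep])
  if (t_day_nt > 0) {
    h_day <- (hrm[["nontraining"]] * (t_sleep + t_day_nt) -
                cfg$hrr_mean_sleep * t_sleep) / t_day_nt
    if (h_day < 0 || h_day > 100) {
      abort(sprintf(paste0("derived daytime nontraining %%HRR (%.2f) outside [0, 100]; ",
                           "adjust hrr_mean_by_period / hrr_mean_sleep"), h_day),
            class = "wearrehab_error_config")
    }
  } else {
    h_day <- NA_real_
  }
  hrr <- ifelse(truth$period == "gap", NA_real_,
         ifelse(truth$period == "training", hrm[["training"]],
         ifelse(truth$sleep, cfg$hrr_mean_sleep, h_day)))
  mult <- ifelse(truth$period == "training", m_training,
          ifelse(truth$sleep | truth$period == "gap", 1, m_nontraining))
  base_sd <- cfg$posture_noise_sd[truth$posture]
  base_sd[truth$posture == "gap"] <- NA_real_
  noise_sd <- unname(base_sd) * mult
  # walking bouts keep a fixed oscillation; their realized window SD includes it
  eff_sd <- ifelse(truth$posture == "walking",
                   sqrt(noise_sd^2 + cfg$walking_amplitude^2 / 2), noise_sd)
  truth$hrr_mean <- unname(hrr)
  truth$activity_sd <- eff_sd
  truth$noise_sd <- noise_sd
  truth
}

# Marginal-to-window-SD calibration for AR(1) noise: the expected sample SD
# of n consecutive AR(1) values, per unit marginal SD. Exact first and second
# moments of s^2 from the covariance matrix, with a Satterthwaite chi-square
# approximation for E[s] = E[sqrt(s^2)] (the Jensen gap matters for the
# short, strongly correlated windows used here).
ar1_window_sd_factor <- function(phi, n) {
  if (n < 2) return(1)
  S <- phi^abs(outer(seq_len(n), seq_len(n), "-"))
  MS <- S - matrix(colMeans(S), n, n, byrow = TRUE)  # (I - J/n) S
  e1 <- sum(diag(MS)) / (n - 1)
  v <- 2 * sum(MS * t(MS)) / (n - 1)^2
  nu <- 2 * e1^2 / v
  sqrt(e1) * sqrt(2 / nu) * exp(lgamma((nu + 1) / 2) - lgamma(nu / 2))
}

stationary_ar1 <- function(n, phi) {
  if (n == 0) return(numeric(0))
  innov <- rnorm(n) * sqrt(1 - phi^2)
  as.numeric(stats::filter(innov, phi, method = "recursive", init = rnorm(1)))
}

# ---- patient profiles and cohort structure ----------------------------------

#' Generate synthetic patient profiles
#'
#' Ages, sexes, FIM motor scores (admission and 4 weeks) and true resting
#' heart rates drawn from the configured cohort distributions.
#'
#' @param config A [scenario_config()].
#' @return A tibble with one row per patient: `patient_id`, `age`, `sex`,
#'   `fim_motor_0w`, `fim_motor_4w`, `hr_max_measured`, and the generator
#'   truth column `hr_rest_true`.
#' @export
generate_profiles <- function(config) {
  withr::with_seed(derive_seed(config$rng_seed, 101), {
    n <- config$n_patients
    age <- pmin(95L, pmax(18L, as.integer(round(rnorm(n, config$age_mean, config$age_sd)))))
    sex <- ifelse(runif(n) < config$p_female, "female", "male")
    fim0 <- pmin(91L, pmax(13L, as.integer(round(rnorm(n, config$fim_mean, config$fim_sd)))))
    gain <- as.integer(round(rnorm(n, config$fim_gain_mean, config$fim_gain_sd)))
    if (!config$allow_fim_decline) gain <- pmax(0L, gain)
    fim4 <- pmin(91L, fim0 + gain)
    hr_rest <- pmin(95, pmax(45, rnorm(n, config$hr_rest_mean, config$hr_rest_sd)))
    tibble(
      patient_id = sprintf("P%02d", seq_len(n)),
      age = age, sex = sex,
      fim_motor_0w = fim0, fim_motor_4w = fim4,
      hr_max_measured = NA_real_,
      hr_rest_true = round(hr_rest, 1)
    )
  })
}

#' Inject cohort activity structure
#'
#' Assigns each patient-session a training and a nontraining activity
#' multiplier: `m = exp(slope * z + eps)` where `z` is the standardized FIM
#' motor score (training) or age (nontraining) and `eps` is patient-level
#' log-normal noise, so realized rank correlations between recovered MSDA and
#' FIM/age are strong but not degenerate. Zero slopes give multipliers
#' independent of both covariates.
#'
#' @param profiles Profile tibble from [generate_profiles()].
#' @param config A [scenario_config()].
#' @return A tibble with columns `patient_id`, `session`, `m_training`,
#'   `m_nontraining`.
#' @export
inject_cohort_structure <- function(profiles, config) {
  stopifnot(is.finite(config$coupling_fim_to_training_activity),
            is.finite(config$coupling_age_to_nontraining_activity))
  withr::with_seed(derive_seed(config$rng_seed, 202), {
    n <- nrow(profiles)
    eps_tr <- rnorm(n, 0, config$coupling_noise_sd)
    eps_nt <- rnorm(n, 0, config$coupling_noise_sd)
    z_age <- (profiles$age - config$age_mean) / config$age_sd
    out <- lapply(SESSION_LEVELS, function(ss) {
      fim <- if (ss == "0W") profiles$fim_motor_0w else profiles$fim_motor_4w
      z_fim <- (fim - config$fim_mean) / config$fim_sd
      tibble(
        patient_id = profiles$patient_id, session = ss,
        m_training = exp(config$coupling_fim_to_training_activity * z_fim + eps_tr),
        m_nontraining = exp(config$coupling_age_to_nontraining_activity * z_age + eps_nt)
      )
    })
    do.call(rbind, out)
  })
}

# ---- session and cohort generation ------------------------------------------

#' Generate one synthetic recording session
#'
#' Produces the tri-axial acceleration series, heart-rate series, therapist
#' schedule and ground-truth annotation for one patient-session under the
#' configured ward day: acceleration is the posture-dependent gravity
#' orientation plus AR(1) activity noise (plus a cadence oscillation while
#' walking); heart rate is `HRrest + f(t) * (HRmax - HRrest)` where `f(t)` is
#' a noisy process whose mean over each annotated interval equals the true
#' %HRR / 100 for that interval.
#'
#' @param profile One-row profile tibble (see [generate_profiles()]).
#' @param config A [scenario_config()].
#' @param session `"0W"` or `"4W"`.
#' @param m_training,m_nontraining Activity multipliers for this
#'   patient-session (see [inject_cohort_structure()]).
#' @return A list with elements `profile`, `session`, `accel`
#'   ([accel_series()]), `hr` ([hr_series()]), `schedule`
#'   ([period_schedule()]) and `truth` (annotation tibble with columns
#'   `start`, `end`, `posture`, `period`, `sleep`, `hrr_mean`,
#'   `activity_sd`).
#' @export
generate_session <- function(profile, config, session = "0W",
                             m_training = 1, m_nontraining = 1) {
  session <- match.arg(session, SESSION_LEVELS)
  built <- build_session_truth(config)
  truth <- annotate_truth(built$truth, config, m_training, m_nontraining)
  span <- built$span
  start_time <- as.POSIXct(paste(config$start_date, config$start_clock),
                           tz = "UTC")
  pid_num <- sum(utf8ToInt(profile$patient_id) * seq_along(utf8ToInt(profile$patient_id)))
  sess_num <- match(session, SESSION_LEVELS)
  gaps <- truth[truth$posture == "gap", c("start", "end")]

  # --- acceleration ---
  rate <- config$accel_rate
  n <- round(span * rate)
  t <- (seq_len(n) - 1) / rate
  idx <- findInterval(t, truth$start)
  posture <- truth$posture[idx]
  phi <- exp(-1 / (rate * config$accel_noise_tau))
  cal <- ar1_window_sd_factor(phi, max(2L, round(2 * rate)))
  sdv <- truth$noise_sd[idx] / cal
  sdv[is.na(sdv)] <- 0
  accel_seed <- derive_seed(config$rng_seed, 303, pid_num, sess_num)
  acc <- withr::with_seed(accel_seed, {
    gx <- ifelse(posture == "lying", 1, 0)
    gz <- ifelse(posture == "lying" | posture == "gap", 0, 1)
    ax <- gx + sdv * stationary_ar1(n, phi)
    ay <- sdv * stationary_ar1(n, phi)
    az <- gz + sdv * stationary_ar1(n, phi)
    walk <- posture == "walking"
    if (any(walk)) {
      az[walk] <- az[walk] +
        config$walking_amplitude * sinpi(2 * config$walking_cadence * t[walk])
    }
    keep <- posture != "gap"
    tibble(time = t[keep], ax = ax[keep], ay = ay[keep], az = az[keep])
  })
  accel <- accel_series(acc, rate = rate, start_time = start_time, gaps = gaps,
                        span = span, patient_id = profile$patient_id,
                        session = session)

  # --- heart rate ---
  hr_rate <- config$hr_rate
  nh <- round(span * hr_rate)
  th <- (seq_len(nh) - 1) / hr_rate
  idxh <- findInterval(th, truth$start)
  mu <- truth$hrr_mean[idxh] / 100
  phih <- exp(-1 / (hr_rate * config$hr_noise_tau))
  hr_max <- if (is.finite(profile$hr_max_measured)) profile$hr_max_measured else
    switch(config$hr_max_formula,
           fox = 220 - profile$age,
           tanaka = 208 - 0.7 * profile$age)
  hr_rest <- profile$hr_rest_true
  hr_seed <- derive_seed(config$rng_seed, 404, pid_num, sess_num)
  hrd <- withr::with_seed(hr_seed, {
    f <- mu + (config$hr_noise_sd / 100) * stationary_ar1(nh, phih)
    hrv <- pmin(220, pmax(30, hr_rest + f * (hr_max - hr_rest)))
    keep <- !is.na(mu)
    tibble(time = th[keep], hr = hrv[keep])
  })
  hr <- hr_series(hrd, rate = hr_rate, start_time = start_time, gaps = gaps,
                  span = span, patient_id = profile$patient_id,
                  session = session)

  list(profile = profile, session = session, accel = accel, hr = hr,
       schedule = built$schedule,
       truth = truth[, c("start", "end", "posture", "period", "sleep",
                         "hrr_mean", "activity_sd")])
}

#' Generate a full synthetic cohort
#'
#' @param config A [scenario_config()].
#' @param sessions Which sessions to generate per patient (default both
#'   `"0W"` and `"4W"`).
#' @return A list with `profiles` (tibble), `structure` (multiplier tibble
#'   from [inject_cohort_structure()]) and `sessions`, a named list
#'   (`"<patient_id>_<session>"`) of [generate_session()] results.
#' @export
generate_cohort <- function(config, sessions = SESSION_LEVELS) {
  sessions <- match.arg(sessions, SESSION_LEVELS, several.ok = TRUE)
  profiles <- generate_profiles(config)
  structure_tbl <- inject_cohort_structure(profiles, config)
  out <- list()
  for (i in seq_len(nrow(profiles))) {
    for (ss in sessions) {
      mrow <- structure_tbl[structure_tbl$patient_id == profiles$patient_id[i] &
                              structure_tbl$session == ss, ]
      out[[paste0(profiles$patient_id[i], "_", ss)]] <-
        generate_session(profiles[i, ], config, session = ss,
                         m_training = mrow$m_training,
                         m_nontraining = mrow$m_nontraining)
    }
  }
  list(profiles = profiles, structure = structure_tbl, sessions = out)
}
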