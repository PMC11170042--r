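test_that("generation is deterministic under a fixed seed", {
  cfg <- scenario_config(n_patients = 2, session_hours = 6, accel_rate = 5,
                         rng_seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  cfg2 <- scenario_config(n_patients = 2, session_hours = 6, accel_rate = 5,
                          rng_seed = 8)
  c2 <- generate_cohort(cfg2)
  expect_false(identical(a$sessions[[1]]$accel$data, c2$sessions[[1]]$accel$data))
})

test_that("ground-truth intervals tile the session and account for all gap time", {
  cfg <- scenario_config(n_patients = 1, session_hours = 48, accel_rate = 1,
                         rng_seed = 3)
  prof <- generate_profiles(cfg)
  s <- generate_session(prof[1, ], cfg, "0W")
  tr <- s$truth
  expect_equal(tr$start[1], 0)
  expect_equal(tr$end[nrow(tr)], 48 * 3600)
  expect_equal(tr$start[-1], tr$end[-nrow(tr)])
  gap_min <- sum((tr$end - tr$start)[tr$posture == "gap"]) / 60
  expect_equal(gap_min, 2 * cfg$bathing_gap_minutes + cfg$device_swap_gap_minutes)
  # gap intervals carry no posture/intensity truth
  expect_true(all(is.na(tr$hrr_mean[tr$period == "gap"])))
  expect_true(all(is.na(tr$activity_sd[tr$period == "gap"])))
})

test_that("night lying block covers the resting window and training time is honored", {
  s <- shared_session()$session
  tr <- s$truth
  lying <- tr[tr$posture == "lying", ]
  covered <- sum(pmax(0, pmin(lying$end, 5 * 3600) - pmax(lying$start, 0)))
  expect_equal(covered, 5 * 3600)
  train_min <- sum((tr$end - tr$start)[tr$period == "training"]) / 60
  expect_equal(train_min, shared_session()$config$training_minutes_per_day)
})

test_that("zero-variance configuration yields exactly zero MSDA downstream", {
  cfg <- scenario_config(n_patients = 1, session_hours = 24, accel_rate = 5,
                         posture_noise_sd = c(lying = 0, sitting_standing = 0,
                                              walking = 0),
                         walking_minutes_nontraining = 0,
                         walking_minutes_training = 0, rng_seed = 5)
  prof <- generate_profiles(cfg)
  s <- generate_session(prof[1, ], cfg, "0W")
  m <- compute_msda(s$accel)
  expect_true(all(m$windows$msda == 0))
})

test_that("generated signals stay inside physiological bounds", {
  s <- shared_session()$session
  expect_true(all(s$hr$data$hr >= 30 & s$hr$data$hr <= 220))
  nrm <- with(s$accel$data, sqrt(ax^2 + ay^2 + az^2))
  expect_true(all(nrm >= 0 & nrm <= 8))
})

test_that("the intensity process mean converges to the configured truth per interval", {
  sh <- shared_session()
  s <- sh$session
  prof <- sh$profile
  hr_max <- 220 - prof$age
  f <- (s$hr$data$hr - prof$hr_rest_true) / (hr_max - prof$hr_rest_true)
  tr <- s$truth
  long <- tr[!is.na(tr$hrr_mean) & (tr$end - tr$start) >= 3600, ]
  for (i in seq_len(nrow(long))) {
    sel <- s$hr$data$time >= long$start[i] & s$hr$data$time < long$end[i]
    expect_lt(abs(mean(f[sel]) - long$hrr_mean[i] / 100), 0.01)
  }
})

test_that("period-mean %HRR recovers the configured calibration values", {
  # full resting-HR anchor + %HRR transform, posture taken from ground truth;
  # median over seeds against the configured period means
  rec <- sapply(1:5, function(seed) {
    cfg <- scenario_config(n_patients = 1, session_hours = 24, accel_rate = 1,
                           rng_seed = seed)
    prof <- generate_profiles(cfg)
    s <- generate_session(prof[1, ], cfg, "0W")
    hp <- session_hrr_params(s$hr, truth_posture(s$truth), prof)
    hrr <- percent_hrr(s$hr, hp)
    day <- split_days(s$hr)[1, ]
    agg <- aggregate_day(NULL, hrr, NULL, s$schedule, day)
    c(tr = agg$hrr_mean_training, nt = agg$hrr_mean_nontraining)
  })
  expect_lt(abs(median(rec["tr", ]) - 22.13), 0.5)
  expect_lt(abs(median(rec["nt", ]) - 9.47), 0.5)
})

test_that("cohort couplings are monotone by default and inert when zeroed", {
  cfg <- scenario_config(n_patients = 40, rng_seed = 20)
  prof <- generate_profiles(cfg)
  st <- inject_cohort_structure(prof, cfg)
  s0 <- st[st$session == "0W", ]
  expect_gt(spearman_cor(prof$fim_motor_0w, s0$m_training)$rho, 0.5)
  expect_lt(spearman_cor(prof$age, s0$m_nontraining)$rho, -0.5)

  cfg0 <- scenario_config(n_patients = 40, rng_seed = 20,
                          coupling_fim_to_training_activity = 0,
                          coupling_age_to_nontraining_activity = 0)
  st0 <- inject_cohort_structure(prof, cfg0)
  # with null coupling the multipliers depend only on patient-level noise:
  # perturbing every covariate leaves them bit-identical
  prof2 <- prof
  prof2$fim_motor_0w <- rev(prof2$fim_motor_0w)
  prof2$age <- rev(prof2$age)
  st0b <- inject_cohort_structure(prof2, cfg0)
  expect_identical(st0$m_training, st0b$m_training)
  expect_identical(st0$m_nontraining, st0b$m_nontraining)
})

test_that("invalid scenario configurations are rejected", {
  expect_error(scenario_config(accel_rate = 0), class = "wearrehab_error_config")
  expect_error(scenario_config(hrr_mean_by_period = c(training = 120,
                                                      nontraining = 9)),
               class = "wearrehab_error_config")
  expect_error(scenario_config(training_minutes_per_day = 1500),
               class = "wearrehab_error_config")
  # training must never intrude on the 00:00-05:00 resting window
  expect_error(scenario_config(rise = "02:00", training_blocks = "03:00",
                               training_minutes_per_day = 60),
               class = "wearrehab_error_config")
})

test_that("patient profiles respect the score and age invariants", {
  cfg <- scenario_config(n_patients = 50, rng_seed = 13)
  prof <- generate_profiles(cfg)
  expect_true(all(prof$fim_motor_0w >= 13 & prof$fim_motor_0w <= 91))
  expect_true(all(prof$fim_motor_4w >= 13 & prof$fim_motor_4w <= 91))
  expect_true(all(prof$fim_motor_4w >= prof$fim_motor_0w))
  expect_true(all(prof$age >= 18))
  expect_true(all(prof$sex %in% c("male", "female")))
})
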