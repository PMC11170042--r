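test_that("gravity along the trunk axis is upright, orthogonal gravity is lying", {
  up <- classify_posture(const_accel(c(0, 0, 1)), refine_walking = FALSE)
  expect_true(all(up$epochs$label == "sitting_standing"))
  flat <- classify_posture(const_accel(c(1, 0, 0)), refine_walking = FALSE)
  expect_true(all(flat$epochs$label == "lying"))
  # device worn upside down still reads as upright (axis, not direction)
  upside <- classify_posture(const_accel(c(0, 0, -1)), refine_walking = FALSE)
  expect_true(all(upside$epochs$label == "sitting_standing"))
})

test_that("posture labels agree with ground truth away from transitions", {
  sh <- shared_session()
  s <- sh$session
  post <- classify_posture(s$accel)
  ep <- 5
  mids <- seq(ep / 2, s$accel$span - ep / 2, by = ep)
  iv <- s$truth
  lab_true <- iv$posture[findInterval(mids, iv$start)]
  pe <- post$epochs
  lab_est <- pe$label[findInterval(mids, pe$start)]
  # exclude one epoch either side of every true transition
  cuts <- iv$start[-1]
  near <- vapply(mids, function(m) any(abs(m - cuts) <= ep), logical(1))
  expect_gte(mean(lab_est[!near] == lab_true[!near]), 0.95)
})

test_that("recovered walking minutes are close to the ground truth", {
  sh <- shared_session()
  s <- sh$session
  post <- classify_posture(s$accel)
  est <- sum((post$epochs$end - post$epochs$start)[post$epochs$label == "walking"]) / 60
  truth <- sum((s$truth$end - s$truth$start)[s$truth$posture == "walking"]) / 60
  expect_lt(abs(est - truth), 0.2 * truth)
})

test_that("walking needs both movement and a cadence peak", {
  # still upright: no movement at all
  still <- const_accel(c(0, 0, 1), duration = 60)
  p <- classify_posture(still)
  expect_true(all(p$epochs$label == "sitting_standing"))

  # upright with a 2 Hz, 0.3 g oscillation: gait
  rate <- 25
  t <- seq(0, 60 - 1 / rate, by = 1 / rate)
  gait <- make_accel(t, 0 * t, 0 * t, 1 + 0.3 * sin(2 * pi * 2 * t),
                     rate = rate, span = 60)
  pg <- classify_posture(gait)
  expect_true(all(pg$epochs$label == "walking"))
  # independent DFT oracle: dominant component of the norm is at 2 Hz
  nrm <- sqrt(gait$data$az^2)[1:125] - mean(sqrt(gait$data$az^2)[1:125])
  freqs <- seq(0.2, 12.4, by = 0.2)
  mags <- vapply(freqs, function(f) naive_dft_mag(nrm, f, rate), numeric(1))
  expect_equal(freqs[which.max(mags)], 2)

  # movement without a cadence peak in band: low-frequency rocking
  rock <- make_accel(t, 0 * t, 0 * t, 1 + 0.3 * sin(2 * pi * 0.2 * t),
                     rate = rate, span = 60)
  pr <- classify_posture(rock)
  expect_true(all(pr$epochs$label != "walking"))
})

test_that("msda of any constant signal is zero and matches the direct SD otherwise", {
  expect_true(all(compute_msda(const_accel(c(0.3, 0.4, 1.2)))$windows$msda == 0))

  # 50 samples alternating norm 0.9 / 1.1 in one 2-s window
  rate <- 25
  t <- seq(0, 2 - 1 / rate, by = 1 / rate)
  vals <- rep(c(0.9, 1.1), 25)
  a <- make_accel(t, 0 * t, 0 * t, vals, rate = rate, span = 2)
  m <- compute_msda(a)
  expect_equal(nrow(m$windows), 1)
  expect_equal(m$windows$msda, naive_sd(vals))
})

test_that("msda is invariant to collinear offsets and scales linearly", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      n <- 50
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      amp <- abs(rnorm(n, 1, 0.2))
      t <- seq(0, 2 - 1 / 25, by = 1 / 25)
      base <- make_accel(t, amp * u[1], amp * u[2], amp * u[3], 25, span = 2)
      c0 <- runif(1, 0, 3)
      shifted <- make_accel(t, (amp + c0) * u[1], (amp + c0) * u[2],
                            (amp + c0) * u[3], 25, span = 2)
      k <- runif(1, 0.5, 4)
      scaled <- make_accel(t, k * amp * u[1], k * amp * u[2], k * amp * u[3],
                           25, span = 2)
      m0 <- compute_msda(base)$windows$msda
      expect_equal(compute_msda(shifted)$windows$msda, m0, tolerance = 1e-10)
      expect_equal(compute_msda(scaled)$windows$msda, k * m0, tolerance = 1e-10)
    }
  })
})

test_that("windows intersecting declared gaps are dropped; gap machinery is inert when unused", {
  rate <- 25
  t_all <- seq(0, 10 - 1 / rate, by = 1 / rate)
  keep <- t_all < 3 | t_all >= 5
  withr::with_seed(4, z <- rnorm(sum(keep), 1, 0.05))
  gaps <- tibble::tibble(start = 3, end = 5)
  a <- make_accel(t_all[keep], 0 * z, 0 * z, z, rate, gaps = gaps, span = 10)
  m <- compute_msda(a)
  expect_setequal(m$windows$start, c(0, 6, 8))  # windows [2,4) and [4,6) dropped

  # same data without the gap declaration and without the missing stretch
  t2 <- seq(0, 6 - 1 / rate, by = 1 / rate)
  withr::with_seed(4, z2 <- rnorm(length(t2), 1, 0.05))
  a_null <- make_accel(t2, 0 * z2, 0 * z2, z2, rate, gaps = NULL, span = 6)
  a_empty <- make_accel(t2, 0 * z2, 0 * z2, z2, rate,
                        gaps = tibble::tibble(start = numeric(0), end = numeric(0)),
                        span = 6)
  expect_identical(compute_msda(a_null)$windows, compute_msda(a_empty)$windows)
  expect_identical(classify_posture(a_null)$epochs, classify_posture(a_empty)$epochs)
})

test_that("resting heart rate is the night lying median, masked by posture", {
  # constant heart rate all night
  hr1 <- hr_series(tibble::tibble(time = 0:17999, hr = rep(60, 18000)),
                   rate = 1, start_time = T0, span = 18000)
  lying_all <- posture_series(tibble::tibble(start = 0, end = 18000, label = "lying"))
  expect_equal(resting_hr(hr1, lying_all), 60)

  # hand fixture: one sample taken during an upright toilet break is masked
  hr2 <- hr_series(tibble::tibble(time = c(600, 1200, 1800, 2400, 3000),
                                  hr = c(55, 57, 58, 60, 90)),
                   rate = 1 / 600, start_time = T0, span = 18000)
  post2 <- posture_series(tibble::tibble(
    start = c(0, 2900, 3100), end = c(2900, 3100, 18000),
    label = c("lying", "sitting_standing", "lying")))
  expect_equal(resting_hr(hr2, post2, min_minutes = 0.001), 57.5)

  # insufficient lying night data fails loudly, naming the session
  hr3 <- hr_series(tibble::tibble(time = 0:99, hr = rep(70, 100)), rate = 1,
                   start_time = T0, span = 86400,
                   patient_id = "P09", session = "4W")
  expect_error(resting_hr(hr3, lying_all), "P09",
               class = "wearrehab_error_data")
})

test_that("resting heart rate is recovered from a synthetic session", {
  sh <- shared_session()
  s <- sh$session
  post <- classify_posture(s$accel, refine_walking = FALSE)
  expect_lt(abs(resting_hr(s$hr, post) - sh$profile$hr_rest_true), 1.5)
})

test_that("maximum heart rate uses the measurement when present, else the age formula", {
  expect_equal(max_hr(list(age = 65))$hr_max, 155)
  expect_equal(max_hr(list(age = 20))$hr_max, 200)
  m <- max_hr(list(age = 65, hr_max_measured = 162))
  expect_equal(m$hr_max, 162)
  expect_equal(m$source_max, "measured")
  expect_equal(max_hr(list(age = 65), formula = "tanaka")$hr_max, 208 - 0.7 * 65)
})

test_that("%HRR is the anchored affine transform and inverts exactly", {
  p <- hrr_params(hr_rest = 60, hr_max = 160)
  hr <- hr_series(tibble::tibble(time = 0:3, hr = c(60, 160, 85, 50)),
                  rate = 1, start_time = T0, span = 4)
  h <- percent_hrr(hr, p)
  expect_equal(h$data$hrr, c(0, 100, 25, -10))
  expect_equal(hrr_to_hr(h$data$hrr, p), hr$data$hr, tolerance = 1e-15)
  # invalid anchors fail with both values reported
  expect_error(hrr_params(hr_rest = 90, hr_max = 80), "90",
               class = "wearrehab_error_input")
})

test_that("mean heart rate by posture splits on the epoch labels", {
  hr <- hr_series(tibble::tibble(time = 0:9, hr = c(rep(55, 5), rep(80, 5))),
                  rate = 1, start_time = T0, span = 10)
  post <- posture_series(tibble::tibble(start = c(0, 5), end = c(5, 10),
                                        label = c("lying", "sitting_standing")))
  tab <- hr_by_posture(hr, post)
  expect_equal(tab$mean_hr[tab$label == "lying"], 55)
  expect_equal(tab$mean_hr[tab$label == "sitting_standing"], 80)
})

test_that("lying-night msda converges to the configured activity level", {
  sh <- shared_session()
  s <- sh$session
  m <- compute_msda(s$accel)
  night <- m$windows$start < 5 * 3600
  sigma <- sh$config$posture_noise_sd[["lying"]]
  expect_lt(abs(mean(m$windows$msda[night]) - sigma) / sigma, 0.05)
})
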