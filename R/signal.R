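#' Moving SD of acceleration (MSDA)
#'
#' Quantifies body movement without step counting: the session is cut into
#' consecutive non-overlapping windows `[k*w, (k+1)*w)` aligned to session
#' start, and each window's value is the sample standard deviation
#' (denominator n - 1) of the Euclidean norm of the tri-axial signal within
#' the window. Windows intersecting a declared gap are dropped, as are
#' windows with fewer than 2 samples.
#'
#' @param accel An [accel_series()].
#' @param window_length Window length in seconds (default 2).
#' @return An [msda_series()].
#' @export
compute_msda <- function(accel, window_length = 2) {
  stopifnot(inherits(accel, "accel_series"))
  w <- window_length
  if (w * accel$rate < 2) {
    abort("window_length * rate must give at least 2 samples per window",
          class = "wearrehab_error_input")
  }
  d <- accel$data
  if (nrow(d) == 0) {
    return(msda_series(tibble(start = numeric(0), msda = numeric(0)), w))
  }
  nrm <- sqrt(d$ax^2 + d$ay^2 + d$az^2)
  wid <- as.integer(floor(d$time / w))
  cnt <- tabulate(wid + 1L)
  ids <- which(cnt > 0) - 1L  # sorted, matches rowsum's group order
  n_k <- cnt[cnt > 0]
  # shifted two-pass SD, vectorized by window: deviations are taken from the
  # window's first sample, so a constant window gives exactly zero
  pos <- findInterval(wid, ids)
  ref <- nrm[!duplicated(wid)]
  dev <- nrm - ref[pos]
  s1 <- rowsum(dev, wid)[, 1]
  s2 <- rowsum(dev * dev, wid)[, 1]
  keep <- n_k >= 2
  msda <- sqrt(pmax(s2[keep] - s1[keep]^2 / n_k[keep], 0) / (n_k[keep] - 1))
  start <- ids[keep] * w
  # drop windows that intersect any declared gap
  if (nrow(accel$gaps)) {
    hit <- rep(FALSE, length(start))
    for (i in seq_len(nrow(accel$gaps))) {
      hit <- hit | (start < accel$gaps$end[i] & start + w > accel$gaps$start[i])
    }
    start <- start[!hit]; msda <- msda[!hit]
  }
  msda_series(tibble(start = start, msda = unname(msda)), w)
}

#' Classify posture from the gravity vector
#'
#' Per epoch (default 5 s), the gravity direction is estimated as the epoch
#' mean of the moving-median (2-s kernel) low-pass acceleration; the epoch is
#' labelled `lying` when the angle between gravity and the device's
#' longitudinal (trunk) axis exceeds the supine threshold (default 50 degrees
#' from vertical), else upright. Upright epochs are refined to `walking` by
#' [detect_walking()] unless `refine_walking = FALSE`. Epochs with fewer than
#' `min_valid_frac` of their expected samples are labelled `gap`.
#'
#' @param accel An [accel_series()].
#' @param epoch_length Epoch length in seconds (>= the 2-s gravity kernel).
#' @param supine_threshold_deg Angle from vertical (degrees) beyond which an
#'   epoch is lying.
#' @param longitudinal_axis Which device axis runs along the trunk
#'   (`"x"`, `"y"` or `"z"`).
#' @param median_kernel Moving-median kernel length in seconds.
#' @param min_valid_frac Minimum fraction of expected samples for a valid
#'   epoch.
#' @param refine_walking Refine upright epochs with [detect_walking()]?
#' @param ... Passed to [detect_walking()].
#' @return A [posture_series()].
#' @export
classify_posture <- function(accel, epoch_length = 5,
                             supine_threshold_deg = 50,
                             longitudinal_axis = c("z", "x", "y"),
                             median_kernel = 2,
                             min_valid_frac = 0.5,
                             refine_walking = TRUE, ...) {
  stopifnot(inherits(accel, "accel_series"))
  axis <- match.arg(longitudinal_axis)
  if (epoch_length < median_kernel) {
    abort("epoch_length must be >= the gravity kernel length",
          class = "wearrehab_error_input")
  }
  d <- accel$data
  span <- accel$span
  n_ep <- ceiling(span / epoch_length)
  ep_start <- (seq_len(n_ep) - 1) * epoch_length
  ep_end <- pmin(span, ep_start + epoch_length)
  if (nrow(d) == 0) {
    return(posture_series(merge_posture_epochs(ep_start, ep_end,
                                               rep("gap", n_ep)),
                          epoch_length))
  }
  k <- max(3L, round(median_kernel * accel$rate))
  if (k %% 2 == 0) k <- k + 1L
  smooth1 <- function(x) {
    if (length(x) <= k) rep(median(x), length(x)) else runmed(x, k, endrule = "median")
  }
  gx <- smooth1(d$ax); gy <- smooth1(d$ay); gz <- smooth1(d$az)
  eid <- floor(d$time / epoch_length) + 1
  cnt <- tabulate(eid, nbins = n_ep)
  gsum <- rowsum(cbind(gx, gy, gz), eid)
  gm <- matrix(0, n_ep, 3)
  gm[as.numeric(rownames(gsum)), ] <- gsum
  gm <- gm / pmax(cnt, 1)
  gl <- switch(axis, x = gm[, 1], y = gm[, 2], z = gm[, 3])
  gn <- sqrt(rowSums(gm^2))
  ang <- acos(pmin(1, abs(gl) / pmax(gn, 1e-12))) * 180 / pi
  expected <- (ep_end - ep_start) * accel$rate
  valid <- cnt >= min_valid_frac * expected
  labels <- ifelse(!valid, "gap",
                   ifelse(ang > supine_threshold_deg, "lying", "sitting_standing"))
  out <- posture_series(merge_posture_epochs(ep_start, ep_end, labels),
                        epoch_length)
  if (refine_walking) out <- detect_walking(accel, out, ...)
  out
}

merge_posture_epochs <- function(start, end, label) {
  x <- tibble(start = start, end = end, label = label)
  if (nrow(x) < 2) return(x)
  new_run <- c(TRUE, label[-1] != label[-length(label)])
  run <- cumsum(new_run)
  out <- x[!duplicated(run), , drop = FALSE]
  out$end <- as.numeric(tapply(x$end, run, max))
  out
}

#' Refine upright epochs to walking
#'
#' An upright (`sitting_standing`) epoch is relabelled `walking` when both
#' (a) its mean MSDA is at least `activity_threshold` and (b) the dominant
#' spectral peak of the (mean-removed) acceleration-norm signal over the
#' epoch lies inside the gait cadence band. Postural sway and sensor noise
#' concentrate power at low frequency, so the cadence peak separates gait
#' from stationary movement.
#'
#' @param accel The [accel_series()] the posture series was computed from.
#' @param posture A [posture_series()] with a known `epoch_length`.
#' @param msda Optional precomputed [msda_series()]; computed (2-s windows)
#'   when `NULL`.
#' @param activity_threshold Minimum mean MSDA (g) for walking.
#' @param cadence_band Frequency band (Hz) the dominant peak must fall in.
#' @return A [posture_series()] with labels from the full set.
#' @export
detect_walking <- function(accel, posture, msda = NULL,
                           activity_threshold = 0.05,
                           cadence_band = c(1, 3)) {
  stopifnot(inherits(accel, "accel_series"), inherits(posture, "posture_series"))
  ep <- posture$epoch_length
  if (!is.finite(ep)) {
    abort("posture series lacks an epoch_length; recompute with classify_posture()",
          class = "wearrehab_error_input")
  }
  span <- accel$span
  n_ep <- ceiling(span / ep)
  ep_start <- (seq_len(n_ep) - 1) * ep
  ep_end <- pmin(span, ep_start + ep)
  iv <- posture$epochs
  lab <- iv$label[findInterval(ep_start, iv$start)]

  if (is.null(msda)) msda <- compute_msda(accel)
  mw <- msda$windows
  mean_msda <- rep(NA_real_, n_ep)
  if (nrow(mw)) {
    weid <- as.integer(floor(mw$start / ep)) + 1L
    scnt <- tabulate(weid, nbins = n_ep)
    ssum <- rowsum(mw$msda, weid)[, 1]
    mean_msda[which(scnt > 0)] <- ssum / scnt[scnt > 0]
  }

  d <- accel$data
  nyq <- accel$rate / 2
  band <- c(max(cadence_band[1], 0), min(cadence_band[2], nyq))
  cadence_ok <- rep(FALSE, n_ep)
  if (nrow(d)) {
    nrm <- sqrt(d$ax^2 + d$ay^2 + d$az^2)
    eid <- floor(d$time / ep) + 1
    cnt <- tabulate(eid, nbins = n_ep)
    full_n <- round(ep * accel$rate)
    target <- which(lab == "sitting_standing" & cnt == full_n)
    if (length(target)) {
      sel <- eid %in% target
      m <- matrix(nrm[sel], nrow = full_n)
      m <- sweep(m, 2, colMeans(m))
      pw <- Mod(mvfft(m))^2
      nbin <- floor(full_n / 2)
      freqs <- (seq_len(nbin)) * accel$rate / full_n
      pw <- pw[1 + seq_len(nbin), , drop = FALSE]
      dom <- freqs[max.col(t(pw), ties.method = "first")]
      cadence_ok[target] <- dom >= band[1] & dom <= band[2]
    }
  }
  walk <- lab == "sitting_standing" & !is.na(mean_msda) &
    mean_msda >= activity_threshold & cadence_ok
  lab[walk] <- "walking"
  posture_series(merge_posture_epochs(ep_start, ep_end, lab), ep)
}

#' Resting heart rate from night lying data
#'
#' The median of all heart-rate samples that fall simultaneously inside the
#' night clock window (default 00:00-05:00, half-open) and inside
#' lying-labelled posture epochs, pooled over every night of the session.
#'
#' @param hr An [hr_series()].
#' @param posture A [posture_series()] for the same session.
#' @param night_window Clock window `c(start, end)` as `"HH:MM"` strings.
#' @param min_minutes Minimum minutes of qualifying samples; below this the
#'   function fails loudly (no silent fallback).
#' @return Resting heart rate in beats/min.
#' @export
resting_hr <- function(hr, posture, night_window = c("00:00", "05:00"),
                       min_minutes = 30) {
  stopifnot(inherits(hr, "hr_series"), inherits(posture, "posture_series"))
  nw <- clock_seconds(night_window)
  clock <- (seconds_of_day(hr$start_time) + hr$data$time) %% 86400
  in_night <- clock >= nw[1] & clock < nw[2]
  lying <- posture$epochs[posture$epochs$label == "lying", c("start", "end")]
  in_lying <- in_intervals(hr$data$time, lying)
  sel <- in_night & in_lying
  minutes <- sum(sel) / hr$rate / 60
  if (minutes < min_minutes) {
    abort(sprintf(paste0("insufficient lying night heart-rate data (%.1f min < %g min) ",
                         "for patient %s session %s"),
                  minutes, min_minutes, hr$patient_id, hr$session),
          class = "wearrehab_error_data")
  }
  median(hr$data$hr[sel])
}

#' Maximum heart rate: measured or estimated from age
#'
#' Uses the measured maximum heart rate when present, otherwise an
#' age-predicted value: `220 - age` (default) or `208 - 0.7 * age`.
#'
#' @param profile A one-row data frame or list with `age` and optionally
#'   `hr_max_measured`.
#' @param formula `"fox"` or `"tanaka"` age formula.
#' @return A list with `hr_max` (beats/min) and `source_max`.
#' @export
max_hr <- function(profile, formula = c("fox", "tanaka")) {
  formula <- match.arg(formula)
  measured <- profile$hr_max_measured %||% NA_real_
  if (length(measured) && is.finite(measured)) {
    return(list(hr_max = as.numeric(measured), source_max = "measured"))
  }
  age <- profile$age
  if (is.null(age) || !is.finite(age)) {
    abort("age is required to estimate maximum heart rate",
          class = "wearrehab_error_input")
  }
  hr_max <- switch(formula, fox = 220 - age, tanaka = 208 - 0.7 * age)
  list(hr_max = as.numeric(hr_max), source_max = "age_estimated")
}

#' Combine resting and maximum heart rate into %HRR anchors
#'
#' @param hr,posture Passed to [resting_hr()].
#' @param profile Passed to [max_hr()].
#' @param formula,night_window,min_minutes See [max_hr()] and [resting_hr()].
#' @return An [hrr_params()] object.
#' @export
session_hrr_params <- function(hr, posture, profile,
                               formula = c("fox", "tanaka"),
                               night_window = c("00:00", "05:00"),
                               min_minutes = 30) {
  rest <- resting_hr(hr, posture, night_window, min_minutes)
  mx <- max_hr(profile, formula)
  hrr_params(hr_rest = rest, hr_max = mx$hr_max, source_max = mx$source_max)
}

#' Percent heart rate reserve series
#'
#' The pointwise transform `100 * (HR - HRrest) / (HRmax - HRrest)` applied
#' to every heart-rate sample. Values below 0 (sub-resting heart rate) and
#' above 100 are kept; gaps propagate unchanged.
#'
#' @param hr An [hr_series()].
#' @param params An [hrr_params()] object.
#' @return An object of class `hrr_series` whose `data` has columns `time`
#'   and `hrr` (percent).
#' @export
percent_hrr <- function(hr, params) {
  stopifnot(inherits(hr, "hr_series"), inherits(params, "hrr_params"))
  hrr <- 100 * (hr$data$hr - params$hr_rest) / (params$hr_max - params$hr_rest)
  structure(
    list(data = tibble(time = hr$data$time, hrr = hrr),
         rate = hr$rate, start_time = hr$start_time, gaps = hr$gaps,
         span = hr$span, params = params,
         patient_id = hr$patient_id, session = hr$session),
    class = "hrr_series"
  )
}

#' Invert the %HRR transform
#'
#' @param hrr %HRR values (percent).
#' @param params An [hrr_params()] object.
#' @return Heart rate in beats/min.
#' @export
hrr_to_hr <- function(hrr, params) {
  params$hr_rest + hrr / 100 * (params$hr_max - params$hr_rest)
}

#' Mean heart rate by posture
#'
#' @param hr An [hr_series()].
#' @param posture A [posture_series()].
#' @return A tibble with `label`, `mean_hr` and `minutes` per posture label.
#' @export
hr_by_posture <- function(hr, posture) {
  iv <- posture$epochs
  lab <- iv$label[findInterval(hr$data$time, iv$start)]
  mh <- tapply(hr$data$hr, lab, mean)
  mins <- tapply(lab, lab, length)
  tibble(label = names(mh), mean_hr = as.numeric(mh),
         minutes = as.numeric(mins) / hr$rate / 60)
}
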