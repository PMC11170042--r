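# Shared fixtures and independent oracles, all built in code.

T0 <- as.POSIXct("2024-03-04 00:00:00", tz = "UTC")

# Quick accel series from explicit samples
make_accel <- function(time, ax, ay, az, rate, gaps = NULL, span = NULL,
                       start_time = T0) {
  accel_series(tibble::tibble(time = time, ax = ax, ay = ay, az = az),
               rate = rate, start_time = start_time, gaps = gaps, span = span)
}

# Constant-orientation series of `duration` seconds
const_accel <- function(vec, duration = 60, rate = 25, start_time = T0) {
  t <- seq(0, duration - 1 / rate, by = 1 / rate)
  make_accel(t, rep(vec[1], length(t)), rep(vec[2], length(t)),
             rep(vec[3], length(t)), rate = rate, span = duration,
             start_time = start_time)
}

# Reduced-scale scenario used across test files
fast_config <- function(...) {
  args <- list(n_patients = 2, session_hours = 24, accel_rate = 5,
               rng_seed = 42)
  over <- list(...)
  args[names(over)] <- over
  do.call(scenario_config, args)
}

# Posture series straight from a ground-truth annotation
truth_posture <- function(truth) {
  posture_series(truth[, c("start", "end")] |>
                   tibble::add_column(label = truth$posture),
                 epoch_length = NA_real_)
}

# Independent two-pass sample SD oracle
naive_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# Brute-force exact two-sided signed-rank p by explicit enumeration of all
# sign patterns (independent of the package's subset-sum path).
naive_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  eps <- 1e-9
  min(1, 2 * min(sum(w_all <= w_obs + eps), sum(w_all >= w_obs - eps)) / 2^n)
}

# Closed-form Spearman coefficient for tie-free data
spearman_closed_form <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Plain O(n^2) DFT magnitude at frequency f (Hz) for a signal at `rate`
naive_dft_mag <- function(x, f, rate) {
  t <- (seq_along(x) - 1) / rate
  sqrt(sum(x * cos(2 * pi * f * t))^2 + sum(x * sin(2 * pi * f * t))^2)
}

# One generated 24-h session (5 Hz) shared across test files; built lazily
# and cached in the helper environment.
shared_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- fast_config(n_patients = 1, rng_seed = 9)
      prof <- generate_profiles(cfg)
      cache <<- list(config = cfg, profile = prof[1, ],
                     session = generate_session(prof[1, ], cfg, "0W"))
    }
    cache
  }
})
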