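null_effects <- function() {
  source_effect_config(
    theta_alpha = list(band = c(2, 12), window = c(0, 0.4), amplitude = 0,
                       sources = "pre_sma"),
    gamma_complexity = list(band = c(55, 90), amplitude = 0,
                            sources = "pre_sma"),
    beta_post = list(band = c(15, 25), window = c(0.2, 1), amps = c(
      stop_success = 0, stop_fail = 0, change_success = 0, change_fail = 0),
      sources = "pre_sma"),
    motor_beta = list(band = c(15, 25), amplitude = 0, depth = 0,
                      window = c(-0.2, 0.4), sources = "m1"))
}

bandpass_fft <- function(x, sfreq, band) {
  n <- length(x)
  sp <- stats::fft(x)
  f <- seq(0, sfreq, length.out = n + 1)[seq_len(n)]
  f <- pmin(f, sfreq - f)
  sp[!(f >= band[1] & f <= band[2])] <- 0
  Re(stats::fft(sp, inverse = TRUE)) / n
}

test_that("all-zero effects leave only the 1/f background", {
  s <- quick_session(50, seed = 4)
  src <- simulate_source_signals(s, null_effects(), sfreq = 200, seed = 4)
  expect_equal(src$series["pre_sma", ],
               src$ground_truth$pre_sma$background, tolerance = 1e-12)
  # stop-locked alpha-band power equals baseline within sampling error
  x <- bandpass_fft(src$series["pre_sma", ], 200, c(8, 12))
  onsets <- src$events$onset[src$events$type == "signal"]
  idx_at <- function(lag) round((onsets + lag) * 200) + 1L
  post <- mean(x[idx_at(0.2)]^2)
  pre <- mean(x[idx_at(-0.2)]^2)
  expect_lt(abs(post - pre) / pre, 1)
})

test_that("burst injection is exactly linear in the configured amplitude", {
  s <- quick_session(50, seed = 6)
  fx1 <- source_effect_config()
  fx2 <- fx1
  fx2$theta_alpha$amplitude <- 2 * fx1$theta_alpha$amplitude
  a <- simulate_source_signals(s, fx1, sfreq = 200, seed = 6)
  b <- simulate_source_signals(s, fx2, sfreq = 200, seed = 6)
  expect_equal(b$ground_truth$pre_sma$theta_alpha,
               2 * a$ground_truth$pre_sma$theta_alpha, tolerance = 1e-12)
  expect_equal(b$ground_truth$pre_sma$background,
               a$ground_truth$pre_sma$background, tolerance = 1e-12)
})

test_that("stop-locked theta/alpha variance increase matches the injected envelopes", {
  s <- quick_session(400, seed = 8)
  fx <- source_effect_config()
  src <- simulate_source_signals(s, fx, sfreq = 200, seed = 8)
  sfreq <- 200
  x <- bandpass_fft(src$series["r_ifg", ], sfreq, c(2, 12))
  onsets <- src$events$onset[src$events$type == "signal"]
  lags <- seq(-0.45, 0.7, by = 1 / sfreq)
  trig_var <- vapply(lags, function(lag) {
    mean(x[round((onsets + lag) * sfreq) + 1L]^2)
  }, numeric(1))
  base <- mean(trig_var[lags < -0.15])
  measured <- sum(trig_var - base) / sfreq # integrated variance increase
  # oracle: integral of the squared injected Hanning envelope
  amp <- fx$theta_alpha$amplitude
  h <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = round(0.4 * sfreq)))
  oracle <- amp^2 * sum(h^2) / sfreq
  expect_lt(abs(measured - oracle) / oracle, 0.2)
})

test_that("sensor projection is exact linear mixing with optional noise", {
  s <- quick_session(20, seed = 10)
  src <- simulate_source_signals(s, source_effect_config(), sfreq = 200,
                                 seed = 10)
  g <- small_geometry()
  lf <- build_spherical_leadfield(g$channel_positions, g$source_positions,
                                  channel_names = g$channel_names,
                                  source_labels = g$source_labels)
  ors <- t(sapply(lf$gains, function(gm) svd(gm)$v[, 1]))
  # noiseless: each channel is the weighted sum of the sources
  rec <- project_to_sensors(src, ors, lf, noise_sd = 0)
  gains <- sapply(1:3, function(i) lf$gains[[i]] %*% ors[i, ])
  expect_equal(unname(rec$data), unname(gains %*% src$series),
               tolerance = 1e-10)
  # zero sources, unit noise: mean channel variance near 1
  rec0 <- project_to_sensors(matrix(0, 3, 20000), ors, lf, noise_sd = 1,
                             seed = 2)
  expect_equal(mean(apply(rec0$data, 1, stats::var)), 1, tolerance = 0.05)
  expect_error(project_to_sensors(src$series[1:2, ], ors, lf),
               "disagree")
})

test_that("sensor covariance matches the mixing-model prediction", {
  g <- small_geometry()
  lf <- build_spherical_leadfield(g$channel_positions, g$source_positions,
                                  channel_names = g$channel_names)
  ors <- t(sapply(lf$gains, function(gm) svd(gm)$v[, 1]))
  n <- 200000
  set.seed(31)
  x <- rbind(stats::rnorm(n, sd = 1), stats::rnorm(n, sd = 2),
             stats::rnorm(n, sd = 0.5))
  rec <- project_to_sensors(x, ors, lf, noise_sd = 0.3, seed = 3)
  emp <- stats::cov(t(rec$data))
  gains <- sapply(1:3, function(i) lf$gains[[i]] %*% ors[i, ])
  pred <- gains %*% diag(c(1, 4, 0.25)) %*% t(gains) +
    diag(0.09, nrow(gains))
  expect_lt(max(abs(emp - pred)) / max(abs(pred)), 0.03)
})

test_that("out-of-range injection bands are rejected", {
  expect_error(
    source_effect_config(theta_alpha = list(band = c(1, 12),
                                            window = c(0, 0.4),
                                            amplitude = 1,
                                            sources = "pre_sma")),
    "band")
  expect_error(
    source_effect_config(gamma_complexity = list(band = c(55, 95),
                                                 amplitude = 1,
                                                 sources = "pre_sma")),
    "band")
})
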