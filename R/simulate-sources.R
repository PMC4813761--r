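#' Oscillatory effect recipe for simulated sources
#'
#' Describes, per source, the background activity and the event-locked
#' band-limited effects the study design predicts:
#'
#' * a theta/alpha (2-12 Hz) burst locked to the stop/change signal;
#' * sustained gamma (>= 55 Hz) from trial onset whose amplitude scales with
#'   the contextual complexity of the session;
#' * post-signal beta (15-25 Hz) whose amplitude depends on success and
#'   response mode (largest after a successful stop);
#' * a motor beta desynchronisation around button presses, realised as a
#'   multiplicative gate on a sustained background beta rhythm.
#'
#' All burst amplitudes are in units of the 1/f background RMS (which is 1).
#' The default recipe places the complexity-scaled gamma at `pre_sma` only,
#' the signal-locked theta/alpha burst at `pre_sma` and `r_ifg`, success
#' dependent beta at `pre_sma` and `r_ifg`, and the press-locked beta
#' desynchronisation at `m1`.
#'
#' @param sources Character vector of source labels.
#' @param theta_alpha Named list: `band`, `window` (relative to the signal
#'   onset), `amplitude`, `sources`.
#' @param gamma_complexity Named list: `band`, `amplitude` (per complexity
#'   level), `sources`; sustained over the whole trial.
#' @param beta_post Named list: `band`, `window`, `amps` (amplitudes named
#'   `stop_success`, `stop_fail`, `change_success`, `change_fail`),
#'   `sources`.
#' @param motor_beta Named list: `band`, `amplitude` (background rhythm
#'   RMS), `depth` (fractional suppression at presses), `window`, `sources`.
#' @param background_amp RMS of the 1/f background (default 1).
#' @return An object of class `source_effect_config`.
#' @export
source_effect_config <- function(sources = c("pre_sma", "r_ifg", "m1"),
                                 theta_alpha = list(
                                   band = c(2, 12), window = c(0, 0.4),
                                   amplitude = 2.6,
                                   sources = c("pre_sma", "r_ifg")),
                                 gamma_complexity = list(
                                   band = c(55, 90), amplitude = 0.8,
                                   sources = "pre_sma"),
                                 beta_post = list(
                                   band = c(15, 25), window = c(0.2, 1.0),
                                   amps = c(stop_success = 0.7,
                                            stop_fail = 0.15,
                                            change_success = 0.35,
                                            change_fail = 0.3),
                                   sources = c("pre_sma", "r_ifg")),
                                 motor_beta = list(
                                   band = c(15, 25), amplitude = 0.6,
                                   depth = 0.7, window = c(-0.2, 0.4),
                                   sources = "m1"),
                                 background_amp = 1) {
  for (b in list(theta_alpha$band, gamma_complexity$band, beta_post$band,
                 motor_beta$band)) {
    check_band(b)
  }
  amps <- c(theta_alpha$amplitude, gamma_complexity$amplitude,
            beta_post$amps, motor_beta$amplitude, background_amp)
  if (any(amps < 0)) stop_invalid("effect amplitudes must be non-negative")
  structure(list(
    sources = sources,
    theta_alpha = theta_alpha,
    gamma_complexity = gamma_complexity,
    beta_post = beta_post,
    motor_beta = motor_beta,
    background_amp = background_amp
  ), class = "source_effect_config")
}

check_band <- function(band) {
  # lower limit 2 Hz admits the 2-12 Hz theta/alpha band whose analysed
  # portion starts at the 2.5 Hz analysis floor
  if (length(band) != 2L || band[1] < 2 || band[2] > 90 || diff(band) <= 0) {
    stop_invalid("bands must lie within the 2-90 Hz injection range")
  }
  invisible(band)
}

# Band-limited unit-RMS noise via Fourier masking of white noise.
band_noise <- function(n, sfreq, band) {
  x <- stats::rnorm(n)
  sp <- stats::fft(x)
  f <- seq(0, sfreq, length.out = n + 1)[seq_len(n)]
  f <- pmin(f, sfreq - f) # two-sided frequency axis
  mask <- f >= band[1] & f <= band[2]
  sp[!mask] <- 0
  y <- Re(stats::fft(sp, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s < 1e-12) return(rep(0, n))
  y / s
}

# 1/f-flavoured background noise, unit RMS.
pink_noise <- function(n, sfreq, f_floor = 1) {
  x <- stats::rnorm(n)
  sp <- stats::fft(x)
  f <- seq(0, sfreq, length.out = n + 1)[seq_len(n)]
  f <- pmin(f, sfreq - f)
  g <- 1 / sqrt(pmax(f, f_floor))
  g[1] <- 0
  y <- Re(stats::fft(sp * g, inverse = TRUE)) / n
  y / stats::sd(y)
}

# Hanning-windowed envelope train: one window per event, clipped to the
# recording. Returns the summed envelope (values in [0, ~1] per event).
envelope_train <- function(n, sfreq, onsets, window) {
  env <- numeric(n)
  len <- max(2L, round((window[2] - window[1]) * sfreq))
  h <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = len))
  for (on in onsets) {
    i0 <- round((on + window[1]) * sfreq) + 1L
    idx <- i0:(i0 + len - 1L)
    keep <- idx >= 1L & idx <= n
    if (any(keep)) env[idx[keep]] <- env[idx[keep]] + h[keep]
  }
  env
}

#' Simulate source-level activity for one session
#'
#' Every source is 1/f background plus the configured band-limited,
#' Hanning-enveloped bursts at its event locks, with amplitudes modulated by
#' trial metadata (complexity of the session, success and response mode).
#' Injection is linear: scaling a configured amplitude by k scales that
#' component of the output by exactly k under the same seed.
#'
#' @param session A `session_behavior`.
#' @param effects A [source_effect_config()].
#' @param sfreq Sampling rate in Hz (default 200).
#' @param seed Integer seed.
#' @return An object of class `source_set`: `series` (sources x samples
#'   matrix), `labels`, `sfreq`, `events` (the session event table),
#'   `session`, and `ground_truth` (per source, the injected component of
#'   each effect and the background).
#' @export
simulate_source_signals <- function(session, effects = source_effect_config(),
                                    sfreq = 200, seed = 1L) {
  stopifnot(inherits(session, "session_behavior"),
            inherits(effects, "source_effect_config"))
  if (sfreq / 2 < 90) {
    stop_invalid("sfreq must be at least 180 Hz to carry the 2.5-90 Hz range")
  }
  ev <- session_events(session)
  dur <- session_duration(session)
  n <- round(dur * sfreq)
  if (max(ev$onset) > dur) stop_invalid("events exceed requested duration")
  labels <- effects$sources
  complexity <- session$config$complexity
  mode <- session$config$response_mode

  series <- matrix(0, nrow = length(labels), ncol = n,
                   dimnames = list(labels, NULL))
  ground_truth <- stats::setNames(vector("list", length(labels)), labels)

  with_seed(derive_seed(seed, paste0("sources/", session$subject_id, "/",
                                     session$session_id)), {
    for (s in seq_along(labels)) {
      lab <- labels[s]
      comp <- list()
      comp$background <- effects$background_amp * pink_noise(n, sfreq)

      # sustained motor-band rhythm with press-locked desynchronisation
      mb <- effects$motor_beta
      if (lab %in% mb$sources && mb$amplitude > 0) {
        rhythm <- mb$amplitude * band_noise(n, sfreq, mb$band)
        presses <- ev$onset[ev$type %in% c("press_L", "press_R")]
        gate <- 1 - mb$depth *
          pmin(envelope_train(n, sfreq, presses, mb$window), 1)
        comp$motor_beta <- rhythm * gate
      }

      ta <- effects$theta_alpha
      if (lab %in% ta$sources && ta$amplitude > 0) {
        onsets <- ev$onset[ev$type == "signal"]
        env <- envelope_train(n, sfreq, onsets, ta$window)
        comp$theta_alpha <- ta$amplitude * env * band_noise(n, sfreq, ta$band)
      }

      gc <- effects$gamma_complexity
      if (lab %in% gc$sources && gc$amplitude > 0) {
        # sustained from trial onset (fixation) to end of response window
        tr <- session$trials
        env <- envelope_train(n, sfreq, tr$onset_fixation,
                              c(0, session$config$response_window +
                                  session$config$pause +
                                  mean(session$config$fixation_range)))
        comp$gamma <- gc$amplitude * complexity * pmin(env, 1) *
          band_noise(n, sfreq, gc$band)
      }

      bp <- effects$beta_post
      if (lab %in% bp$sources && any(bp$amps > 0)) {
        sig_ev <- ev[ev$type == "signal", , drop = FALSE]
        env <- numeric(n)
        for (k in seq_len(nrow(sig_ev))) {
          out <- sig_ev$outcome[k]
          if (!out %in% c("signal_success", "signal_fail")) next
          key <- paste0(mode, "_", sub("signal_", "", out))
          a <- bp$amps[[key]] %||% 0
          env <- env + a * envelope_train(n, sfreq, sig_ev$onset[k], bp$window)
        }
        comp$beta_post <- env * band_noise(n, sfreq, bp$band)
      }

      series[s, ] <- Reduce(`+`, comp)
      ground_truth[[lab]] <- comp
    }
  })
  structure(list(
    series = series,
    labels = labels,
    sfreq = sfreq,
    times = (seq_len(n) - 1L) / sfreq,
    events = ev,
    session = session,
    ground_truth = ground_truth
  ), class = "source_set")
}

#' @export
print.source_set <- function(x, ...) {
  cat(sprintf("<source_set> %d sources x %d samples @ %g Hz\n",
              nrow(x$series), ncol(x$series), x$sfreq))
  invisible(x)
}

#' Project source activity to sensors
#'
#' Linear instantaneous mixing: `data = sum_s (L_s u_s) x_s(t) + noise`,
#' with white Gaussian sensor noise of SD `noise_sd`. Session events are
#' carried along on the recording.
#'
#' @param sources A `source_set` (or a sources x samples matrix).
#' @param orientations Sources x 3 matrix of unit dipole orientations.
#' @param leadfield A [build_spherical_leadfield()] result covering the same
#'   sources.
#' @param noise_sd Sensor noise SD (same arbitrary field units as the
#'   gains).
#' @param seed Integer seed for the noise stream.
#' @return An object of class `sensor_recording`: `data` (channels x
#'   samples), `sfreq`, `channel_names`, `channel_positions`, `events`, and
#'   a `ground_truth` echo of the sources and orientations.
#' @export
project_to_sensors <- function(sources, orientations, leadfield,
                               noise_sd = 0, seed = 1L) {
  stopifnot(inherits(leadfield, "leadfield"))
  x <- if (inherits(sources, "source_set")) sources$series else as.matrix(sources)
  orientations <- matrix(orientations, ncol = 3)
  if (nrow(x) != length(leadfield$gains) ||
      nrow(orientations) != nrow(x)) {
    stop_invalid("sources, orientations and leadfield disagree in source count")
  }
  norms <- sqrt(rowSums(orientations^2))
  if (any(abs(norms - 1) > 1e-6)) {
    orientations <- orientations / norms
  }
  gains <- vapply(seq_len(nrow(x)), function(s) {
    leadfield$gains[[s]] %*% orientations[s, ]
  }, numeric(nrow(leadfield$channel_positions)))
  data <- gains %*% x
  if (noise_sd > 0) {
    data <- data + with_seed(derive_seed(seed, "sensor-noise"), {
      matrix(stats::rnorm(length(data), 0, noise_sd), nrow = nrow(data))
    })
  }
  dimnames(data) <- list(leadfield$channel_names, NULL)
  structure(list(
    data = data,
    sfreq = if (inherits(sources, "source_set")) sources$sfreq else NA_real_,
    channel_names = leadfield$channel_names,
    channel_positions = leadfield$channel_positions,
    events = if (inherits(sources, "source_set")) sources$events else NULL,
    ground_truth = list(
      sources = if (inherits(sources, "source_set")) sources else x,
      orientations = orientations,
      oriented_gains = gains,
      noise_sd = noise_sd
    )
  ), class = "sensor_recording")
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf("<sensor_recording> %d channels x %d samples @ %g Hz\n",
              nrow(x$data), ncol(x$data), x$sfreq))
  invisible(x)
}
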