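#' Frequency-dependent spectral half-bandwidth
#'
#' The piecewise resolution rule of the time-frequency decomposition: the
#' inverse of the 0.4 s window (2.5 Hz) up to 25 Hz, 0.1 times the
#' frequency between 25 and 50 Hz, and a constant 5 Hz above 50 Hz.
#'
#' @param f Frequency in Hz, within the 2.5-90 Hz analysis range.
#' @return Half-bandwidth in Hz (vectorised).
#' @export
#' @examples
#' bandwidth_for_frequency(c(10, 40, 60)) # 2.5, 4, 5
bandwidth_for_frequency <- function(f) {
  if (any(f < 2.5 | f > 90)) {
    stop_invalid("frequency outside the 2.5-90 Hz analysis range")
  }
  ifelse(f <= 25, 2.5, ifelse(f <= 50, 0.1 * f, 5))
}

#' Time-frequency configuration
#'
#' @param window Analysis window length, seconds (default 0.4).
#' @param step Window step, seconds (default 0.05).
#' @param freqs Analysis frequencies in Hz (default 2.5-90 in steps of 2.5).
#' @return An object of class `tf_config`.
#' @export
tf_config <- function(window = 0.4, step = 0.05,
                      freqs = seq(2.5, 90, by = 2.5)) {
  if (step > window) stop_invalid("step must not exceed the window length")
  if (is.unsorted(freqs) || any(freqs <= 0)) {
    stop_invalid("freqs must be sorted and positive")
  }
  structure(list(window = window, step = step, freqs = freqs),
            class = "tf_config")
}

# Discrete prolate spheroidal (Slepian) tapers via the classic symmetric
# tridiagonal eigenproblem; n samples, normalized half-bandwidth w = W/fs.
# Returns an n x k matrix of unit-energy tapers.
dpss_tapers <- function(n, w, k) {
  t_idx <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * t_idx) / 2)^2 * cos(2 * pi * w)
  diag_off <- t_idx[-1] * (n - t_idx[-1]) / 2
  m <- diag(diag_main)
  for (i in seq_len(n - 1)) {
    m[i, i + 1] <- diag_off[i]
    m[i + 1, i] <- diag_off[i]
  }
  eg <- eigen(m, symmetric = TRUE)
  h <- eg$vectors[, seq_len(k), drop = FALSE]
  # sign convention: positive mean (first taper) / positive first lobe
  for (j in seq_len(k)) {
    s <- sum(h[, j])
    if (abs(s) < 1e-9) s <- h[which.max(abs(h[, j])), j]
    if (s < 0) h[, j] <- -h[, j]
    h[, j] <- h[, j] / sqrt(sum(h[, j]^2))
  }
  h
}

# Taper count for time-half-bandwidth product TW: the standard Slepian
# concentration heuristic K = max(1, floor(2 TW) - 1).
taper_count <- function(window, half_bandwidth) {
  max(1L, as.integer(floor(2 * window * half_bandwidth)) - 1L)
}

#' Multitaper RMS time-frequency decomposition
#'
#' Sliding-window multitaper spectral estimation over a whole block with the
#' frequency-dependent bandwidth rule of [bandwidth_for_frequency()] (or a
#' custom rule). At each frequency, DPSS tapers with time-half-bandwidth
#' `window * W` are applied (taper count `max(1, floor(2*window*W) - 1)`),
#' power is averaged over tapers, and the square root is taken so that the
#' returned values are RMS amplitudes, linear in the signal amplitude.
#' Windows are evaluated only where they fit entirely inside the block, so
#' the first usable center sits half a window after the block start.
#'
#' @param ts A `source_time_series` (or numeric vector plus `sfreq`).
#' @param cfg A [tf_config()].
#' @param sfreq Sampling rate when `ts` is a bare vector.
#' @param t_start Time of the first sample on the session clock (default 0).
#' @param bandwidth_rule Function mapping frequency to half-bandwidth in Hz.
#' @return An object of class `tf_image`: `times` (window centers, s),
#'   `freqs` (Hz), `values` (freqs x times RMS amplitude), `sfreq`, `label`.
#' @export
multitaper_rms <- function(ts, cfg = tf_config(), sfreq = NULL, t_start = 0,
                           bandwidth_rule = bandwidth_for_frequency) {
  if (inherits(ts, "source_time_series")) {
    x <- ts$values
    sfreq <- ts$sfreq
    label <- ts$label
  } else {
    x <- as.numeric(ts)
    if (is.null(sfreq)) stop_invalid("sfreq required for a bare vector")
    label <- "series"
  }
  n <- length(x)
  n_win <- round(cfg$window * sfreq)
  if (n < n_win) stop_invalid("signal shorter than one analysis window")
  hop <- cfg$step * sfreq
  if (abs(hop - round(hop)) > 1e-6) {
    stop_invalid("step must be an integer number of samples at %g Hz", sfreq)
  }
  hop <- round(hop)
  starts <- seq(1L, n - n_win + 1L, by = hop)
  centers <- t_start + (starts - 1L + (n_win - 1) / 2) / sfreq

  # windows matrix: n_win x n_windows
  wm <- vapply(starts, function(s) x[s:(s + n_win - 1L)], numeric(n_win))
  wm <- matrix(wm, nrow = n_win)

  freqs <- cfg$freqs
  values <- matrix(NA_real_, nrow = length(freqs), ncol = length(starts),
                   dimnames = list(freqs, NULL))
  half_bw <- bandwidth_rule(freqs)
  taper_cache <- new.env(parent = emptyenv())
  t_rel <- 0:(n_win - 1)
  for (i in seq_along(freqs)) {
    w_norm <- half_bw[i] / sfreq
    key <- format(w_norm, digits = 12)
    if (is.null(taper_cache[[key]])) {
      k <- taper_count(cfg$window, half_bw[i])
      taper_cache[[key]] <- dpss_tapers(n_win, w_norm, k)
    }
    h <- taper_cache[[key]]
    carrier <- exp(-2i * pi * freqs[i] * t_rel / sfreq)
    tc <- Conj(t(h * carrier))            # k x n_win complex
    spec <- tc %*% wm                     # k x n_windows
    values[i, ] <- sqrt(colMeans(Mod(spec)^2))
  }
  structure(list(
    times = centers,
    freqs = freqs,
    values = values,
    sfreq = sfreq,
    step = cfg$step,
    window = cfg$window,
    label = label
  ), class = "tf_image")
}

#' @export
print.tf_image <- function(x, ...) {
  cat(sprintf("<tf_image> %s: %d freqs (%g-%g Hz) x %d times (%.2f-%.2f s)\n",
              x$label, length(x$freqs), min(x$freqs), max(x$freqs),
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}
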