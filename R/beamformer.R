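#' Regularized sensor covariance
#'
#' Sample covariance over all samples of a recording block, ridge
#' regularized by adding the identity scaled by 0.01% of the mean diagonal
#' element.
#'
#' @param rec A `sensor_recording` or a channels x samples matrix.
#' @param reg_coefficient Ridge fraction of the mean diagonal (default
#'   `1e-4`, i.e. 0.01%).
#' @return An object of class `reg_covariance`: `matrix`, `lambda`,
#'   `n_samples`, `channel_names`, `singular` flag.
#' @export
compute_covariance <- function(rec, reg_coefficient = 1e-4) {
  x <- if (inherits(rec, "sensor_recording")) rec$data else as.matrix(rec)
  if (!all(is.finite(x))) stop_invalid("non-finite values in sensor data")
  n <- ncol(x)
  if (n < nrow(x)) {
    warning("fewer samples than channels: covariance will be rank deficient")
  }
  xc <- x - rowMeans(x)
  c_raw <- tcrossprod(xc) / max(n - 1L, 1L)
  lambda <- reg_coefficient * mean(diag(c_raw))
  c_reg <- c_raw + diag(lambda, nrow(c_raw))
  structure(list(
    matrix = c_reg,
    lambda = lambda,
    n_samples = n,
    channel_names = rownames(x) %||% sprintf("ch%03d", seq_len(nrow(x))),
    singular = lambda <= 0 || !all(is.finite(1 / diag(c_reg)))
  ), class = "reg_covariance")
}

#' LCMV spatial filter for one source
#'
#' The linearly constrained minimum-variance beamformer passes the source's
#' oriented lead field with unit gain while minimizing output variance:
#' `w = C^-1 l / (l' C^-1 l)`. The source orientation is chosen in the
#' direction of maximum power, the dominant eigenvector of
#' `(L' C^-1 L)^-1` (equivalently the minimum-eigenvalue eigenvector of
#' `L' C^-1 L`).
#'
#' @param gain Channels x 3 lead-field matrix of one source (gains of unit
#'   dipoles along x, y, z).
#' @param cov A `reg_covariance`.
#' @param source_label Label carried on the filter.
#' @return An object of class `spatial_filter`: `weights` (per channel),
#'   `orientation` (unit 3-vector), `oriented_gain`, `label`. The unit-gain
#'   identity `sum(weights * oriented_gain) == 1` holds to 1e-9 relative.
#' @export
lcmv_filter <- function(gain, cov, source_label = "src") {
  stopifnot(inherits(cov, "reg_covariance"))
  gain <- as.matrix(gain)
  if (nrow(gain) != nrow(cov$matrix)) {
    stop_invalid("gain/covariance channel mismatch")
  }
  # Restrict to the magnetically effective subspace first: in a spherical
  # conductor the radial dipole orientation is exactly silent, and the
  # max-power criterion must not select it.
  sv <- svd(gain)
  keep <- sv$d > 1e-8 * sv$d[1]
  if (sum(keep) < 1L) stop_invalid("degenerate source: all orientations silent")
  vk <- sv$v[, keep, drop = FALSE]
  ci_gain <- solve(cov$matrix, gain)
  m <- crossprod(gain, ci_gain) # L' C^-1 L, 3x3
  mk <- crossprod(vk, m %*% vk)
  eg <- eigen(mk, symmetric = TRUE)
  if (min(eg$values) <= 0 || !all(is.finite(eg$values))) {
    stop_invalid("degenerate source: L' C^-1 L is not positive definite")
  }
  # maximum power = minimum eigenvalue of L' C^-1 L within the subspace
  u <- drop(vk %*% eg$vectors[, which.min(eg$values)])
  u <- u / sqrt(sum(u^2))
  l <- drop(gain %*% u)
  if (u[which.max(abs(u))] < 0) {
    u <- -u
    l <- -l
  }
  ci_l <- solve(cov$matrix, l)
  denom <- sum(l * ci_l)
  if (!is.finite(denom) || denom <= 0) {
    stop_invalid("degenerate source: oriented lead field has no power")
  }
  w <- ci_l / denom
  structure(list(
    weights = stats::setNames(w, cov$channel_names),
    orientation = u,
    oriented_gain = l,
    label = source_label
  ), class = "spatial_filter")
}

#' Extract source time series with a set of spatial filters
#'
#' Applies each filter's weights to the sensor data (aligned by channel
#' name when names are available).
#'
#' @param rec A `sensor_recording` or channels x samples matrix.
#' @param filters A list of `spatial_filter`s (or a single one).
#' @return A list of `source_time_series` objects (values, sfreq, label).
#' @export
extract_sources <- function(rec, filters) {
  x <- if (inherits(rec, "sensor_recording")) rec$data else as.matrix(rec)
  if (inherits(filters, "spatial_filter")) filters <- list(filters)
  lapply(filters, function(f) {
    w <- f$weights
    if (!is.null(names(w)) && !is.null(rownames(x))) {
      if (!all(names(w) %in% rownames(x))) {
        stop_invalid("filter/recording channel mismatch for source %s", f$label)
      }
      xw <- x[names(w), , drop = FALSE]
    } else {
      if (length(w) != nrow(x)) {
        stop_invalid("filter/recording channel count mismatch")
      }
      xw <- x
    }
    structure(list(
      values = drop(crossprod(matrix(w, ncol = 1), xw)),
      sfreq = if (inherits(rec, "sensor_recording")) rec$sfreq else NA_real_,
      label = f$label,
      standardized = FALSE,
      moments = NULL
    ), class = "source_time_series")
  })
}

#' @export
print.source_time_series <- function(x, ...) {
  cat(sprintf("<source_time_series> %s: %d samples @ %g Hz%s\n", x$label,
              length(x$values), x$sfreq,
              if (isTRUE(x$standardized)) " (standardized)" else ""))
  invisible(x)
}

#' Pairwise similarity of beamformer filters
#'
#' Squared Pearson correlation between the raw weight vectors of every pair
#' of filters: the fraction of variance at one location that could be
#' explained at another purely through the filters (a leakage diagnostic).
#'
#' @param filters List of `spatial_filter`s.
#' @return Symmetric matrix of squared correlations with unit diagonal.
#' @export
filter_similarity <- function(filters) {
  if (length(filters) < 2L) stop_invalid("need at least 2 filters")
  w <- sapply(filters, function(f) as.numeric(f$weights))
  sds <- apply(w, 2, stats::sd)
  if (any(sds < 1e-15)) {
    warning("constant weight vector: correlation undefined, returning NA")
  }
  r2 <- suppressWarnings(stats::cor(w)^2)
  diag(r2) <- 1
  dimnames(r2) <- rep(list(vapply(filters, `[[`, "", "label")), 2)
  r2
}

#' Robust standardization of a source time series
#'
#' First- and second-moment estimates robust to brief artifacts: medians of
#' the raw and squared signal are computed over non-overlapping segments
#' (default 10 s) and averaged; the series is then centered and scaled by
#' the implied robust SD.
#'
#' @param ts A `source_time_series` (or numeric vector plus `sfreq`).
#' @param segment Segment length in seconds (default 10).
#' @param sfreq Sampling rate; taken from `ts` when it is a
#'   `source_time_series`.
#' @param eps Variance floor below which the signal is deemed flat.
#' @return The standardized `source_time_series` with `moments = c(m1, m2)`.
#' @export
robust_standardize <- function(ts, segment = 10, sfreq = NULL, eps = 1e-12) {
  if (inherits(ts, "source_time_series")) {
    x <- ts$values
    sfreq <- ts$sfreq
  } else {
    x <- as.numeric(ts)
    if (is.null(sfreq)) stop_invalid("sfreq required for a bare vector")
  }
  seg_len <- round(segment * sfreq)
  n_seg <- length(x) %/% seg_len
  if (n_seg < 1L) stop_invalid("signal shorter than one %g s segment", segment)
  idx <- seq_len(n_seg * seg_len)
  grp <- rep(seq_len(n_seg), each = seg_len)
  m1 <- mean(tapply(x[idx], grp, stats::median))
  m2 <- mean(tapply(x[idx]^2, grp, stats::median))
  v <- m2 - m1^2
  if (v <= eps) stop_invalid("flat signal: robust variance is %g", v)
  out <- (x - m1) / sqrt(v)
  if (inherits(ts, "source_time_series")) {
    ts$values <- out
    ts$standardized <- TRUE
    ts$moments <- c(m1 = m1, m2 = m2)
    ts
  } else {
    structure(list(values = out, sfreq = sfreq, label = "series",
                   standardized = TRUE, moments = c(m1 = m1, m2 = m2)),
              class = "source_time_series")
  }
}

#' Optional preprocessing chain for real sensor recordings
#'
#' Downsampling, 0.1 Hz high-pass and 50/100 Hz notch filters (fifth-order
#' zero-phase Butterworth), for use on acquired data; synthetic recordings
#' generated at the analysis rate skip this stage. Requires the `signal`
#' package.
#'
#' @param rec A `sensor_recording`.
#' @param target_sfreq Output rate (default 300 Hz).
#' @param highpass High-pass cutoff in Hz.
#' @param notch Frequencies to notch out, Hz.
#' @return The filtered `sensor_recording`.
#' @export
preprocess_sensor <- function(rec, target_sfreq = 300, highpass = 0.1,
                              notch = c(50, 100)) {
  stopifnot(inherits(rec, "sensor_recording"))
  if (!requireNamespace("signal", quietly = TRUE)) {
    stop_invalid("preprocess_sensor requires the 'signal' package")
  }
  dec <- max(1L, round(rec$sfreq / target_sfreq))
  x <- rec$data
  if (dec > 1L) {
    x <- t(apply(x, 1, function(v) signal::decimate(v, dec)))
    rec$sfreq <- rec$sfreq / dec
  }
  ny <- rec$sfreq / 2
  hp <- signal::butter(5, highpass / ny, type = "high")
  x <- t(apply(x, 1, function(v) signal::filtfilt(hp, v)))
  for (f0 in notch) {
    if (f0 >= ny) next
    bs <- signal::butter(5, c(f0 - 1, f0 + 1) / ny, type = "stop")
    x <- t(apply(x, 1, function(v) signal::filtfilt(bs, v)))
  }
  rec$data <- x
  rec
}
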