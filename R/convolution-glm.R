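#' Fourier basis over the peristimulus window
#'
#' A constant plus `order` sine/cosine pairs sampled on the peristimulus
#' grid (default -0.5 to +1.5 s in 0.05 s steps). Harmonics have period
#' `n_points * step`, i.e. one cycle of the first harmonic per sampled
#' window, which makes the columns exactly orthogonal on the grid.
#'
#' @param window Two seconds, start and end of the peristimulus window.
#' @param order Number of sine/cosine pairs (default 11).
#' @param step Grid step in seconds (default 0.05, the TF step).
#' @return An object of class `basis_set`: `tau` (grid times), `matrix`
#'   (grid x (2*order+1)), `order`, `step`.
#' @export
#' @examples
#' b <- fourier_basis(order = 1)
#' dim(b$matrix) # 41 x 3
fourier_basis <- function(window = c(-0.5, 1.5), order = 11L, step = 0.05) {
  if (order < 1L) stop_invalid("order must be >= 1")
  n_step <- (window[2] - window[1]) / step
  if (abs(n_step - round(n_step)) > 1e-6) {
    stop_invalid("window length must be divisible by step")
  }
  tau <- seq(window[1], window[2], by = step)
  n <- length(tau)
  if (2L * order + 1L > n) {
    stop_invalid("order %d aliases on a %d-point grid (2*order+1 > points)",
                 order, n)
  }
  phase <- 2 * pi * (seq_len(n) - 1L) / n
  cols <- list(rep(1, n))
  labels <- "const"
  for (k in seq_len(order)) {
    cols <- c(cols, list(sin(k * phase), cos(k * phase)))
    labels <- c(labels, sprintf("sin%d", k), sprintf("cos%d", k))
  }
  m <- do.call(cbind, cols)
  colnames(m) <- labels
  structure(list(tau = tau, matrix = m, order = order, step = step,
                 window = window), class = "basis_set")
}

#' Convolution design matrix for induced-response estimation
#'
#' Each event is an impulse at the nearest TF sample, convolved with every
#' basis column; each parametric modulator adds a parallel set of columns
#' built from the impulse train weighted by the modulator value
#' (mean-centered within its event type, so the unmodulated columns keep
#' the mean response). Events outside the TF time span are dropped with a
#' warning.
#'
#' @param events Data frame with columns `onset` and `type` (see
#'   [session_events()]).
#' @param basis A [fourier_basis()].
#' @param tf_times Time axis of the TF image the design will be fitted to.
#' @param modulators Optional named list: for each entry, `event_type` and
#'   `values` (one per event of that type, in event order).
#' @return An object of class `design_matrix`: `matrix` (times x columns),
#'   `columns` (data frame with `regressor` and `basis` labels),
#'   `tf_times`, `basis`, plus the count of dropped events.
#' @export
build_design <- function(events, basis, tf_times, modulators = NULL) {
  stopifnot(inherits(basis, "basis_set"))
  step <- stats::median(diff(tf_times))
  if (abs(step - basis$step) > 1e-9) {
    stop_invalid("TF step (%g) and basis step (%g) disagree", step, basis$step)
  }
  n_t <- length(tf_times)
  offsets <- round(basis$tau / step)
  nearest_idx <- function(onset) round((onset - tf_times[1]) / step) + 1L
  types <- unique(events$type)

  cols <- list()
  labels <- list()
  dropped <- 0L
  place <- function(idx_weights) {
    # idx_weights: data frame of impulse sample indices and weights
    block <- matrix(0, nrow = n_t, ncol = ncol(basis$matrix))
    for (r in seq_len(nrow(idx_weights))) {
      i0 <- idx_weights$idx[r]
      rows <- i0 + offsets
      keep <- rows >= 1L & rows <= n_t
      block[rows[keep], ] <- block[rows[keep], ] +
        idx_weights$w[r] * basis$matrix[keep, , drop = FALSE]
    }
    block
  }
  for (ty in types) {
    ev <- events[events$type == ty, , drop = FALSE]
    idx <- nearest_idx(ev$onset)
    ok <- idx >= 1L & idx <= n_t
    dropped <- dropped + sum(!ok)
    iw <- data.frame(idx = idx[ok], w = 1)
    if (!nrow(iw)) {
      warning(sprintf("event type '%s' has no events inside the TF span", ty))
      next
    }
    cols[[length(cols) + 1L]] <- place(iw)
    labels[[length(labels) + 1L]] <-
      data.frame(regressor = ty, basis = colnames(basis$matrix))
  }
  if (dropped > 0L) {
    warning(sprintf("%d events outside the TF span were dropped", dropped))
  }
  for (mname in names(modulators)) {
    mod <- modulators[[mname]]
    ev <- events[events$type == mod$event_type, , drop = FALSE]
    if (nrow(ev) != length(mod$values)) {
      stop_invalid("modulator '%s': %d values for %d '%s' events",
                   mname, length(mod$values), nrow(ev), mod$event_type)
    }
    if (!all(is.finite(mod$values))) {
      stop_invalid("modulator '%s' has non-finite values", mname)
    }
    idx <- nearest_idx(ev$onset)
    ok <- idx >= 1L & idx <= n_t
    w <- mod$values[ok] - mean(mod$values[ok]) # centered within type
    iw <- data.frame(idx = idx[ok], w = w)
    cols[[length(cols) + 1L]] <- place(iw)
    labels[[length(labels) + 1L]] <-
      data.frame(regressor = paste0(mod$event_type, ":", mname),
                 basis = colnames(basis$matrix))
  }
  x <- do.call(cbind, cols)
  columns <- do.call(rbind, labels)
  colnames(x) <- paste(columns$regressor, columns$basis, sep = "|")
  structure(list(
    matrix = x,
    columns = columns,
    tf_times = tf_times,
    basis = basis,
    dropped = dropped
  ), class = "design_matrix")
}

#' Remove slow components below a cutoff from data or design
#'
#' Projects out the discrete-cosine subspace spanning frequencies below the
#' cutoff (including the constant), applied identically to data rows and
#' design columns so the GLM stays consistent. Blocks shorter than one
#' cutoff period are returned unfiltered with a warning.
#'
#' @param x Numeric vector or matrix; filtering acts along rows of time
#'   (i.e. on each column when `x` is a matrix of time x series).
#' @param step Sampling step of the time axis in seconds (default 0.05).
#' @param cutoff Cutoff frequency in Hz (default 0.25).
#' @return Same shape as `x`, with sub-cutoff components removed.
#' @export
highpass_below <- function(x, step = 0.05, cutoff = 0.25) {
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, ncol = 1) else as.matrix(x)
  n <- nrow(m)
  if (n * step < 1 / cutoff) {
    warning("block shorter than one cutoff period: filtering skipped")
    return(x)
  }
  # DCT-II columns with frequency k / (2 n step); keep those below cutoff
  k_max <- floor(2 * n * step * cutoff)
  k <- 0:k_max
  t_idx <- (0:(n - 1)) + 0.5
  d <- vapply(k, function(kk) cos(pi * kk * t_idx / n), numeric(n))
  d <- qr.Q(qr(d)) # orthonormalize
  out <- m - d %*% crossprod(d, m)
  if (vec) drop(out) else out
}

#' Fit the mass-univariate convolution GLM
#'
#' Ordinary least squares of each frequency row of the TF image on the
#' design matrix, treating frequencies separately. A rank-deficient design
#' triggers a warning and a minimum-norm (pseudo-inverse) solution.
#'
#' @param tf A `tf_image` (or a freqs x times matrix).
#' @param design A [build_design()] result (or a times x columns matrix).
#' @param highpass If `TRUE` (default), apply [highpass_below()] to both
#'   the data and the design before fitting.
#' @return An object of class `tf_glm`: `coefficients` (columns x freqs),
#'   `columns`, `rank`, `condition_number`, `freqs`, `basis`.
#' @export
fit_tf_glm <- function(tf, design, highpass = TRUE) {
  y <- if (inherits(tf, "tf_image")) t(tf$values) else t(as.matrix(tf))
  x <- if (inherits(design, "design_matrix")) design$matrix else as.matrix(design)
  if (nrow(y) != nrow(x)) {
    stop_invalid("TF image (%d times) and design (%d rows) disagree",
                 nrow(y), nrow(x))
  }
  if (highpass) {
    step <- if (inherits(design, "design_matrix")) {
      stats::median(diff(design$tf_times))
    } else {
      0.05
    }
    x <- highpass_below(x, step = step)
    y <- highpass_below(y, step = step)
  }
  sv <- svd(x)
  tol <- max(dim(x)) * .Machine$double.eps * sv$d[1]
  rank <- sum(sv$d > tol)
  if (rank < ncol(x)) {
    warning(sprintf("rank-deficient design (rank %d of %d): minimum-norm fit",
                    rank, ncol(x)))
  }
  d_inv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  beta <- sv$v %*% (d_inv * crossprod(sv$u, y))
  rownames(beta) <- colnames(x)
  structure(list(
    coefficients = beta,
    columns = if (inherits(design, "design_matrix")) design$columns else NULL,
    rank = rank,
    condition_number = sv$d[1] / max(sv$d[min(dim(x))], tol),
    freqs = if (inherits(tf, "tf_image")) tf$freqs else seq_len(ncol(y)),
    basis = if (inherits(design, "design_matrix")) design$basis else NULL
  ), class = "tf_glm")
}

#' Reconstruct the induced response of one event type
#'
#' Multiplies the basis functions with the fitted coefficients of the event
#' type's columns, yielding the peristimulus time-frequency response in RMS
#' amplitude units.
#'
#' @param fit A [fit_tf_glm()] result.
#' @param event_type Regressor label to reconstruct (an `events$type` value
#'   or `"type:modulator"`).
#' @param basis Basis set; defaults to the one recorded in the fit.
#' @return An object of class `induced_response`: `times` (peristimulus,
#'   s), `freqs`, `values` (freqs x times), `event_type`.
#' @export
reconstruct_induced <- function(fit, event_type, basis = NULL) {
  stopifnot(inherits(fit, "tf_glm"))
  basis <- basis %||% fit$basis
  if (is.null(fit$columns)) stop_invalid("fit carries no column labels")
  rows <- fit$columns$regressor == event_type
  if (!any(rows)) stop_invalid("unknown event type '%s'", event_type)
  beta <- fit$coefficients[rows, , drop = FALSE]
  values <- t(basis$matrix %*% beta) # freqs x times
  dimnames(values) <- list(fit$freqs, NULL)
  structure(list(
    times = basis$tau,
    freqs = fit$freqs,
    values = values,
    event_type = event_type
  ), class = "induced_response")
}

#' @export
print.induced_response <- function(x, ...) {
  cat(sprintf("<induced_response> %s: %d freqs x %d peristimulus times\n",
              x$event_type, length(x$freqs), length(x$times)))
  invisible(x)
}

#' Event-triggered average of a TF image
#'
#' The naive alternative to the convolution GLM: averages TF segments
#' centered on each event over the peristimulus window. Equivalent to the
#' GLM reconstruction when events are isolated, but biased when responses
#' overlap.
#'
#' @param tf A `tf_image`.
#' @param onsets Event onsets in seconds (session clock).
#' @param window Peristimulus window, seconds (default `c(-0.5, 1.5)`).
#' @param baseline If `TRUE`, subtract the mean over the whole block from
#'   each frequency row first (the GLM's constant columns absorb the same
#'   mean).
#' @return An `induced_response`.
#' @export
triggered_average_tf <- function(tf, onsets, window = c(-0.5, 1.5),
                                 baseline = TRUE) {
  stopifnot(inherits(tf, "tf_image"))
  step <- tf$step
  offsets <- round(seq(window[1], window[2], by = step) / step)
  vals <- tf$values
  if (baseline) vals <- vals - rowMeans(vals)
  acc <- matrix(0, nrow = nrow(vals), ncol = length(offsets))
  count <- 0L
  for (on in onsets) {
    i0 <- round((on - tf$times[1]) / step) + 1L
    idx <- i0 + offsets
    if (any(idx < 1L | idx > ncol(vals))) next
    acc <- acc + vals[, idx, drop = FALSE]
    count <- count + 1L
  }
  if (count == 0L) stop_invalid("no events with a complete window")
  structure(list(
    times = offsets * step,
    freqs = tf$freqs,
    values = acc / count,
    event_type = "triggered_average"
  ), class = "induced_response")
}
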