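#' Estimate the slow drift of go RT over a session
#'
#' Subjects tend to wait for the stop/change signal, so go RT drifts upward
#' over a session. The drift curve is a cubic smoothing spline of go-only RT
#' against trial index, with smoothing chosen by generalized cross
#' validation; with fewer than 30 points a straight line is fitted instead.
#'
#' The fitted level is re-anchored so that residuals have zero *median*
#' rather than zero mean: the predictor then tracks the running median go
#' RT, which is the quantity the race model relates to the inhibition
#' function midpoint (at the midpoint, the go process outlasts the stop
#' process on exactly half the trials).
#'
#' @param ct A `classified_trials`.
#' @param min_spline Minimum number of go-only trials for the spline fit
#'   (default 30); below it a linear fit is used.
#' @return An object of class `drift_model` with a `predict(index)`
#'   function, the fitted values, the method used, the linear slope of the
#'   fitted curve, and the residual scale.
#' @export
estimate_rt_drift <- function(ct, min_spline = 30L) {
  stopifnot(inherits(ct, "classified_trials"))
  tr <- ct$trials
  go <- tr$class == "go_only" & !is.na(tr$rt)
  x <- tr$index[go]
  y <- tr$rt[go]
  if (length(x) < 10L) {
    stop_invalid("insufficient data: %d go-only trials (need >= 10)", length(x))
  }
  if (length(x) >= min_spline && length(unique(x)) >= 10L) {
    fit <- stats::smooth.spline(x, y, cv = FALSE) # GCV smoothing
    predict_raw <- function(idx) stats::predict(fit, as.numeric(idx))$y
    method <- "spline"
  } else {
    fit <- stats::lm(y ~ x)
    predict_raw <- function(idx) {
      unname(stats::predict(fit, data.frame(x = as.numeric(idx))))
    }
    method <- "linear"
  }
  # median re-anchoring (see Details)
  offset <- stats::median(y - predict_raw(x))
  predict_fun <- function(idx) predict_raw(idx) + offset
  fitted_all <- predict_fun(tr$index)
  resid <- y - predict_fun(x)
  slope <- unname(stats::coef(stats::lm(fitted_all ~ tr$index))[2])
  structure(list(
    predict = predict_fun,
    fitted = fitted_all,
    index = tr$index,
    method = method,
    slope = slope,
    residual_scale = stats::mad(resid)
  ), class = "drift_model")
}

#' @export
print.drift_model <- function(x, ...) {
  cat(sprintf("<drift_model> %s fit, slope %.2e s/trial, residual scale %.3f s\n",
              x$method, x$slope, x$residual_scale))
  invisible(x)
}
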