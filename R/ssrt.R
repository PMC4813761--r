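#' Average-difference SSRT estimate
#'
#' The classic mean method: mean go-only RT minus the mean SOA over all
#' classified signal trials. With a staircase holding stopping success at
#' 50%, the mean SOA settles near the median go RT minus the SSRT, so this
#' estimator carries a small positive bias equal to the mean-median gap of
#' the go RT distribution.
#'
#' @param ct A `classified_trials`.
#' @return SSRT estimate in seconds.
#' @export
ssrt_average_difference <- function(ct) {
  stopifnot(inherits(ct, "classified_trials"))
  tr <- ct$trials
  go <- tr$rt[tr$class == "go_only"]
  soa <- tr$soa[tr$class %in% c("signal_success", "signal_fail")]
  if (!length(go) || !length(soa)) {
    stop_invalid("insufficient data: need go-only and signal trials")
  }
  mean(go) - mean(soa)
}

#' Integration-method SSRT estimate
#'
#' The p-th quantile of the go-only RT distribution (p equal to the overall
#' probability of responding on a signal trial, i.e. the fail fraction)
#' minus the mean SOA over signal trials. The quantile uses the classic
#' convention: the sorted go RT at 1-based index `ceiling(p * n)`.
#'
#' @param ct A `classified_trials`.
#' @return SSRT estimate in seconds.
#' @export
ssrt_integration <- function(ct) {
  stopifnot(inherits(ct, "classified_trials"))
  tr <- ct$trials
  go <- sort(tr$rt[tr$class == "go_only"])
  soa <- tr$soa[tr$class %in% c("signal_success", "signal_fail")]
  if (!length(go) || !length(soa)) {
    stop_invalid("insufficient data: need go-only and signal trials")
  }
  p <- ct$fail_fraction
  if (is.na(p) || p <= 0 || p >= 1) {
    stop_invalid("degenerate performance: fail fraction is %s", format(p))
  }
  q <- go[ceiling(p * length(go))]
  q - mean(soa)
}

#' All SSRT estimates for a session
#'
#' Computes the two traditional estimators, their mean (`ssrt_av`), and the
#' MCMC inhibition-function midpoint with RT-drift correction
#' (`ssrt_mcmc`).
#'
#' @param ct A `classified_trials`.
#' @param drift Optional [estimate_rt_drift()] model; fitted from `ct` when
#'   `NULL`.
#' @param mcmc Options passed to [fit_inhibition_function()].
#' @return A list of class `ssrt_estimates` with elements `ssrt_avgdiff`,
#'   `ssrt_integration`, `ssrt_av`, `ssrt_mcmc` and the full `fit`.
#' @export
ssrt_estimates <- function(ct, drift = NULL, mcmc = list()) {
  avgdiff <- ssrt_average_difference(ct)
  integ <- ssrt_integration(ct)
  av <- (avgdiff + integ) / 2
  if (is.null(drift)) drift <- estimate_rt_drift(ct)
  fit <- do.call(fit_inhibition_function,
                 c(list(ct = ct, drift = drift, prior_center = av), mcmc))
  structure(list(
    ssrt_avgdiff = avgdiff,
    ssrt_integration = integ,
    ssrt_av = av,
    ssrt_mcmc = fit$alpha,
    fit = fit
  ), class = "ssrt_estimates")
}

#' @export
print.ssrt_estimates <- function(x, ...) {
  cat(sprintf(
    "<ssrt_estimates> avgdiff %.3f, integration %.3f, av %.3f, mcmc %.3f s\n",
    x$ssrt_avgdiff, x$ssrt_integration, x$ssrt_av, x$ssrt_mcmc))
  invisible(x)
}
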