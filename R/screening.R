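#' Screen a session against the three behavioral admission rules
#'
#' A session is retained only if (1) the median SOA of failed signal trials
#' is at least that of successful ones (a horse-race prediction), (2) the
#' fail fraction is at least 0.28 (subjects who wait excessively fail too
#' rarely), and (3) the inhibition-function deviance does not exceed 7.5.
#' The deviance rule is only evaluated when both earlier rules pass: a
#' psychometric function is not derived for sessions already discarded.
#'
#' @param ct A `classified_trials`.
#' @param medians Optional list with `go_rt`, `fail_rt`, `success_soa`,
#'   `fail_soa`; computed from `ct` when `NULL`.
#' @param fit Optional `inhibition_fit` supplying the deviance.
#' @param fail_fraction_threshold Minimum admissible fail fraction
#'   (default 0.28).
#' @param deviance_threshold Maximum admissible deviance (default 7.5).
#' @return An object of class `screening_report` with per-rule outcomes
#'   (`"pass"`, `"fail"` or `"not_evaluated"`) and the overall `retained`
#'   flag.
#' @export
screen_session <- function(ct, medians = NULL, fit = NULL,
                           fail_fraction_threshold = 0.28,
                           deviance_threshold = 7.5) {
  stopifnot(inherits(ct, "classified_trials"))
  if (is.null(medians)) medians <- session_medians(ct)

  rule_soa <- if (is.na(medians$fail_soa) || is.na(medians$success_soa)) {
    "fail" # not evaluable: conservative fail
  } else if (medians$success_soa > medians$fail_soa) {
    "fail"
  } else {
    "pass"
  }
  ff <- ct$fail_fraction
  rule_ff <- if (is.na(ff)) "fail" else if (ff < fail_fraction_threshold) "fail" else "pass"

  rule_dev <- "not_evaluated"
  deviance <- NA_real_
  if (rule_soa == "pass" && rule_ff == "pass" && !is.null(fit)) {
    deviance <- if (inherits(fit, "inhibition_fit")) fit$deviance else as.numeric(fit)
    if (!is.na(deviance)) {
      rule_dev <- if (deviance > deviance_threshold) "fail" else "pass"
    }
  }
  evaluated <- c(rule_soa, rule_ff,
                 if (rule_dev != "not_evaluated") rule_dev)
  structure(list(
    rule_soa_ordering = rule_soa,
    rule_fail_fraction = rule_ff,
    rule_deviance = rule_dev,
    fail_fraction = ff,
    deviance = deviance,
    medians = medians,
    retained = all(evaluated == "pass")
  ), class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf(
    "<screening_report> soa:%s fail_fraction:%s deviance:%s -> %s\n",
    x$rule_soa_ordering, x$rule_fail_fraction, x$rule_deviance,
    if (x$retained) "retained" else "excluded"))
  invisible(x)
}
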