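#' Classify trials into the three key classes
#'
#' Re-derives trial classes from the logged responses: go trials with a
#' correct-direction single press are `go_only`; signal trials with no
#' emitted go response are `signal_success` (in change mode a press of the
#' opposite button is additionally required), signal trials where the planned
#' go press escaped are `signal_fail`. Wrong-direction presses, double
#' presses and lapses are `unclassified` and are discarded from all
#' downstream estimates.
#'
#' @param session A `session_behavior`.
#' @return An object of class `classified_trials`: the trial table augmented
#'   with a `class` column, per-class counts, `presented`, `classified`,
#'   `change_fraction` (classified signal trials / classified trials) and
#'   `fail_fraction` (failed signal trials / classified signal trials;
#'   `NA` when no signal trial was classified).
#' @export
classify_trials <- function(session) {
  stopifnot(inherits(session, "session_behavior"))
  tr <- session$trials
  if (nrow(tr) == 0L) stop_invalid("empty session: no trials to classify")
  mode <- session$config$response_mode
  press <- tr$press_direction
  opp <- ifelse(tr$go_direction == "L", "R", "L")
  matched <- !is.na(press) & press == tr$go_direction
  reversed <- !is.na(press) & press == opp
  cls <- rep("unclassified", nrow(tr))
  go <- !tr$is_signal_trial
  cls[go & matched] <- "go_only"
  if (mode == "stop") {
    cls[!go & is.na(press)] <- "signal_success"
    cls[!go & matched] <- "signal_fail"
  } else { # change mode: no press at all is an unclassified lapse
    cls[!go & reversed] <- "signal_success"
    cls[!go & matched] <- "signal_fail"
  }
  cls[tr$double_press] <- "unclassified"
  tr$class <- cls
  counts <- c(
    go_only = sum(cls == "go_only"),
    signal_success = sum(cls == "signal_success"),
    signal_fail = sum(cls == "signal_fail"),
    unclassified = sum(cls == "unclassified")
  )
  n_signal <- counts[["signal_success"]] + counts[["signal_fail"]]
  classified <- sum(counts[c("go_only", "signal_success", "signal_fail")])
  structure(list(
    trials = tr,
    counts = counts,
    presented = nrow(tr),
    classified = classified,
    change_fraction = if (classified > 0) n_signal / classified else NA_real_,
    fail_fraction = if (n_signal > 0) {
      counts[["signal_fail"]] / n_signal
    } else {
      NA_real_
    },
    response_mode = mode,
    signal_stimulus = session$config$signal_stimulus,
    subject_id = session$subject_id,
    session_id = session$session_id
  ), class = "classified_trials")
}

#' @export
print.classified_trials <- function(x, ...) {
  cat("<classified_trials>", x$presented, "presented;",
      paste(names(x$counts), x$counts, collapse = ", "),
      sprintf("; fail fraction %.3f\n", x$fail_fraction))
  invisible(x)
}

#' Median go-only RT with edge trimming
#'
#' The first and last `trim` trials of the session are removed before taking
#' the median, partially counteracting slow RT drift.
#'
#' @param ct A `classified_trials`.
#' @param trim Number of trials removed at each end of the session
#'   (default 15).
#' @return Median RT in seconds.
#' @export
median_go_rt <- function(ct, trim = 15L) {
  stopifnot(inherits(ct, "classified_trials"))
  tr <- ct$trials
  n <- nrow(tr)
  if (n <= 2L * trim + 1L) {
    stop_invalid("insufficient data: %d trials with trim %d", n, trim)
  }
  keep <- tr$class == "go_only" & tr$index > trim & tr$index <= n - trim
  if (!any(keep)) stop_invalid("insufficient data: no go-only trials retained")
  stats::median(tr$rt[keep])
}

#' Medians of the quantities used by the screening rules
#'
#' @param ct A `classified_trials`.
#' @param trim Edge trim passed to [median_go_rt()].
#' @return A list with `go_rt`, `fail_rt`, `success_rt`, `fail_soa`,
#'   `success_soa` (seconds; `NA` where a class is empty).
#' @export
session_medians <- function(ct, trim = 15L) {
  tr <- ct$trials
  med <- function(x) if (length(x)) stats::median(x) else NA_real_
  list(
    go_rt = tryCatch(median_go_rt(ct, trim), error = function(e) {
      med(tr$rt[tr$class == "go_only"])
    }),
    fail_rt = med(tr$rt[tr$class == "signal_fail"]),
    success_rt = med(tr$rt[tr$class == "signal_success"]),
    fail_soa = med(tr$soa[tr$class == "signal_fail"]),
    success_soa = med(tr$soa[tr$class == "signal_success"])
  )
}
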