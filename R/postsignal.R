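#' Drift-corrected post-signal go RT changes
#'
#' For each go-only trial preceded by one or more signal trials whose
#' outcomes all agree, the corrected RT is the current go RT minus the RT of
#' the most recent preceding go-only trial. Differencing against the
#' neighbouring go trial removes slow RT drift exactly, isolating the
#' strategic slowing (or speeding) that follows a stop/change signal. Runs
#' of signal trials with mixed outcomes, and runs interrupted by
#' unclassified trials, are skipped.
#'
#' @param ct A `classified_trials`.
#' @return A data frame with one row per qualifying go trial: columns
#'   `previous_outcome` (`"signal_success"` or `"signal_fail"`),
#'   `response_mode`, `corrected_rt` (seconds), `trial_index`,
#'   `run_length`. May be empty.
#' @export
corrected_post_signal_rt <- function(ct) {
  stopifnot(inherits(ct, "classified_trials"))
  tr <- ct$trials[order(ct$trials$index), ]
  cls <- tr$class
  out <- list()
  for (i in seq_along(cls)) {
    if (cls[i] != "go_only") next
    # walk back over the immediately preceding run of signal trials
    j <- i - 1L
    run <- character(0)
    while (j >= 1L && cls[j] %in% c("signal_success", "signal_fail")) {
      run <- c(cls[j], run)
      j <- j - 1L
    }
    if (!length(run) || j < 1L) next
    if (cls[j] != "go_only") next           # run must be bracketed by go trials
    if (length(unique(run)) != 1L) next     # outcomes must agree
    out[[length(out) + 1L]] <- data.frame(
      previous_outcome = run[1],
      response_mode = ct$response_mode,
      corrected_rt = tr$rt[i] - tr$rt[j],
      trial_index = tr$index[i],
      run_length = length(run),
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(previous_outcome = character(0),
                      response_mode = character(0),
                      corrected_rt = numeric(0),
                      trial_index = integer(0),
                      run_length = integer(0)))
  }
  do.call(rbind, out)
}

#' Contextual-complexity interaction contrast on go RT
#'
#' The complexity of the stop/change rule is reversed between stop and
#' change variants (a bar makes stopping simple but changing complex), so
#' the complexity effect appears as the stimulus-by-response interaction on
#' median go RT. Per subject the interaction contrast
#' `(bar,stop - arrow,stop) - (bar,change - arrow,change)` is computed on
#' cell means; significance comes from permuting the four cell labels within
#' each subject.
#'
#' @param summaries Data frame with columns `subject`, `stimulus`
#'   (`"bar"`/`"arrow"`), `response` (`"stop"`/`"change"`) and `value`
#'   (e.g. median go RT, seconds). Rows sharing a subject-by-cell label
#'   (e.g. previous-trial strata) are averaged first.
#' @param n_perm Number of label permutations (default 10000).
#' @param seed Integer seed.
#' @return An object of class `stat_result` with the mean interaction
#'   contrast, the per-subject contrasts, and the two-tailed permutation p
#'   value. The complexity effect (complex minus simple) is the negative of
#'   the interaction contrast.
#' @export
complexity_contrast <- function(summaries, n_perm = 10000L, seed = 1L) {
  need <- c("subject", "stimulus", "response", "value")
  if (!all(need %in% names(summaries))) {
    stop_invalid("summaries must have columns %s", paste(need, collapse = ", "))
  }
  cells <- stats::aggregate(value ~ subject + stimulus + response,
                            data = summaries, FUN = mean)
  subjects <- unique(cells$subject)
  get_cell <- function(s, st, re) {
    v <- cells$value[cells$subject == s & cells$stimulus == st &
                       cells$response == re]
    if (length(v) != 1L) NA_real_ else v
  }
  mat <- t(vapply(subjects, function(s) {
    c(get_cell(s, "bar", "stop"), get_cell(s, "arrow", "stop"),
      get_cell(s, "bar", "change"), get_cell(s, "arrow", "change"))
  }, numeric(4)))
  if (anyNA(mat) || length(subjects) < 2L) {
    stop_invalid("insufficient design: need all four cells for >= 2 subjects")
  }
  contrast_of <- function(m) mean((m[, 1] - m[, 2]) - (m[, 3] - m[, 4]))
  obs <- contrast_of(mat)
  perms <- with_seed(derive_seed(seed, "complexity-contrast"), {
    vapply(seq_len(n_perm), function(p) {
      pm <- t(apply(mat, 1, function(r) r[sample.int(4)]))
      contrast_of(pm)
    }, numeric(1))
  })
  pval <- (1 + sum(abs(perms) >= abs(obs))) / (1 + n_perm)
  structure(list(
    effect = "stimulus_by_response_interaction",
    estimate = obs,
    complexity_effect = -obs,
    per_subject = (mat[, 1] - mat[, 2]) - (mat[, 3] - mat[, 4]),
    statistic = obs,
    p_value = pval,
    n_perm = n_perm
  ), class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s: estimate %.4g, p = %.4g (%s)\n",
              x$effect, x$estimate, x$p_value,
              if (!is.null(x$n_perm)) paste(x$n_perm, "permutations")
              else paste("df", x$df %||% NA)))
  invisible(x)
}
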