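#' Update one adaptive staircase thread
#'
#' The SOA staircase increases by one step after a successful stop/change
#' (making the next stop harder) and decreases by one step after a failure,
#' asymptoting at the floor.
#'
#' @param soa Current SOA of the thread, seconds.
#' @param outcome `"success"` or `"fail"`.
#' @param step Step size, seconds (positive).
#' @param floor Lowest admissible SOA (default 0).
#' @return Updated SOA in seconds.
#' @export
#' @examples
#' update_staircase(0.3, "success", 0.05) # 0.35
#' update_staircase(0, "fail", 0.05)      # stays at the floor
update_staircase <- function(soa, outcome = c("success", "fail"),
                             step = 0.05, floor = 0) {
  outcome <- match.arg(outcome)
  if (step <= 0) stop_invalid("staircase step must be positive")
  if (soa < floor) stop_invalid("soa (%g) below floor (%g)", soa, floor)
  if (outcome == "success") soa + step else max(soa - step, floor)
}

# One ex-Gaussian draw per trial, vectorised.
rexgauss <- function(n, mu, sigma, tau) {
  stats::rnorm(n, mu, sigma) + stats::rexp(n, rate = 1 / tau)
}

#' Simulate one behavioral session of the stop/change task
#'
#' Runs the horse-race model trial by trial under the adaptive dual-thread
#' staircase. Each trial draws a fixation duration, a go direction, and an
#' ex-Gaussian go finishing time (plus linear drift). On signal trials one of
#' the two staircase threads is sampled uniformly; the stop process of
#' duration `ssrt` races the go process and the faster one determines the
#' outcome. In change mode a successful stop is followed by a press of the
#' opposite button `change_extra` seconds after the stop process finishes.
#' Lapses are realised as unclassifiable responses (wrong-direction press on
#' go trials, double press on signal trials).
#'
#' The raw go finishing time of every trial is logged (`go_finish`), so
#' outcome classification is a deterministic function of the logged draws.
#'
#' @param config A [task_config()].
#' @param params A [race_params()].
#' @param seed Integer seed; the behavioral stream is derived from it.
#' @param subject_id,session_id Labels carried through to summaries.
#' @return An object of class `session_behavior`: a list with `trials`
#'   (one row per trial), `config`, `params`, the final staircase state, and
#'   the id labels.
#' @export
#' @examples
#' s <- simulate_behavior_session(task_config(n_trials_per_block = 30,
#'                                            n_blocks = 1),
#'                                race_params(), seed = 1)
#' table(s$trials$outcome)
simulate_behavior_session <- function(config = task_config(),
                                      params = race_params(),
                                      seed = 1L,
                                      subject_id = "s01",
                                      session_id = "r01") {
  stopifnot(inherits(config, "task_config"), inherits(params, "race_params"))
  n <- config$n_trials_per_block * config$n_blocks
  with_seed(derive_seed(seed, paste0("behavior/", subject_id, "/", session_id)), {
    threads <- config$staircase_starts
    fix_dur <- stats::runif(n, config$fixation_range[1], config$fixation_range[2])
    go_dir <- sample(c("L", "R"), n, replace = TRUE)
    ex <- rexgauss(n, params$go_mu, params$go_sigma, params$go_tau)
    is_signal <- stats::runif(n) < config$signal_probability
    is_lapse <- stats::runif(n) < params$lapse_prob
    thread_pick <- sample(1:2, n, replace = TRUE)
    ssrt_draw <- if (params$ssrt_sd > 0) {
      pmax(stats::rnorm(n, params$ssrt_true, params$ssrt_sd), 1e-3)
    } else {
      rep(params$ssrt_true, n)
    }
    go_finish <- ex + params$drift_slope * (seq_len(n) - 1L)
    iti <- stats::runif(n, config$iti_range[1], config$iti_range[2])
    trial_len <- fix_dur + config$pause + config$response_window + iti
    onset_fix <- c(0, cumsum(trial_len))[seq_len(n)]
    onset_go <- onset_fix + fix_dur + config$pause
    opposite <- ifelse(go_dir == "L", "R", "L")

    # sequential part: only the staircase state
    soa <- rep(NA_real_, n)
    stop_wins <- rep(NA, n)
    for (i in which(is_signal)) {
      thr <- thread_pick[i]
      soa[i] <- threads[thr]
      stop_wins[i] <- go_finish[i] > soa[i] + ssrt_draw[i]
      # The staircase reacts to whether the planned go response was emitted.
      threads[thr] <- update_staircase(
        threads[thr], if (stop_wins[i]) "success" else "fail",
        config$staircase_step, config$soa_floor)
    }

    outcome <- ifelse(is_lapse, "unclassified",
                      ifelse(!is_signal, "go_correct",
                             ifelse(stop_wins, "signal_success",
                                    "signal_fail")))
    rt <- go_finish
    press_dir <- ifelse(is_lapse & !is_signal, opposite, go_dir)
    success <- !is_lapse & is_signal & stop_wins
    if (config$response_mode == "stop") {
      rt[success] <- NA_real_
      press_dir[success] <- NA_character_
    } else {
      rt[success] <- soa[success] + ssrt_draw[success] + params$change_extra
      press_dir[success] <- opposite[success]
    }
    structure(list(
      trials = data.frame(
        index = seq_len(n),
        block = (seq_len(n) - 1L) %/% config$n_trials_per_block + 1L,
        go_direction = go_dir,
        is_signal_trial = is_signal,
        staircase_thread = ifelse(is_signal, thread_pick, NA_integer_),
        soa = soa,
        go_finish = go_finish,
        outcome = outcome,
        rt = rt,
        press_direction = press_dir,
        double_press = is_lapse & is_signal,
        onset_fixation = onset_fix,
        onset_go = onset_go,
        onset_signal = onset_go + soa,
        onset_press = onset_go + rt,
        stringsAsFactors = FALSE
      ),
      config = config,
      params = params,
      staircase_final = threads,
      subject_id = subject_id,
      session_id = session_id
    ), class = "session_behavior")
  })
}

#' @export
print.session_behavior <- function(x, ...) {
  cat(sprintf(
    "<session_behavior> %s/%s: %d trials (%s/%s), %d signal trials\n",
    x$subject_id, x$session_id, nrow(x$trials),
    x$config$signal_stimulus, x$config$response_mode,
    sum(x$trials$is_signal_trial)
  ))
  invisible(x)
}

#' Total duration in seconds spanned by a session's events
#' @param session A `session_behavior`.
#' @param margin Seconds appended after the final go onset.
#' @return Duration in seconds.
#' @export
session_duration <- function(session, margin = 2) {
  max(session$trials$onset_go) + margin
}

#' Write session events as tab-separated text
#'
#' One row per event (`fixation`, `go`, `signal`, `press_L`, `press_R`) with
#' onset, duration, trial metadata, SOA and RT; empty fields mark absent
#' values. A header row is always written.
#'
#' @param session A `session_behavior`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_events_tsv <- function(session, path) {
  ev <- session_events(session)
  df <- data.frame(
    onset_s = ev$onset, duration_s = ev$duration, event_type = ev$type,
    trial_index = ev$trial_index,
    condition = paste0(session$config$signal_stimulus, "_",
                       session$config$response_mode),
    outcome = ev$outcome, soa_s = ev$soa, rt_s = ev$rt,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Event list of a session
#'
#' Long-format event table used both by the sensor simulator and by the
#' convolution GLM.
#'
#' @param session A `session_behavior`.
#' @return A data frame with columns `onset`, `duration`, `type`,
#'   `trial_index`, `outcome`, `soa`, `rt`.
#' @export
session_events <- function(session) {
  tr <- session$trials
  ev <- list()
  add <- function(onset, type, dur = 0) {
    keep <- !is.na(onset)
    data.frame(onset = onset[keep], duration = dur, type = type,
               trial_index = tr$index[keep], outcome = tr$outcome[keep],
               soa = tr$soa[keep], rt = tr$rt[keep], stringsAsFactors = FALSE)
  }
  ev[["fixation"]] <- add(tr$onset_fixation, "fixation")
  ev[["go"]] <- add(tr$onset_go, "go")
  ev[["signal"]] <- add(tr$onset_signal, "signal")
  press <- !is.na(tr$onset_press)
  if (any(press)) {
    ev[["press"]] <- data.frame(
      onset = tr$onset_press[press], duration = 0,
      type = paste0("press_", tr$press_direction[press]),
      trial_index = tr$index[press], outcome = tr$outcome[press],
      soa = tr$soa[press], rt = tr$rt[press], stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, ev)
  out <- out[order(out$onset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read an events TSV written by [write_events_tsv()]
#' @param path File path.
#' @return A data frame of events.
#' @export
read_events_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", na.strings = "",
                    stringsAsFactors = FALSE)
}
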