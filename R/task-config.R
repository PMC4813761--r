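#' Task configuration for a stop/change-signal session
#'
#' Describes one block-design session of the stop/change task: a fixation
#' cross of uniformly drawn duration, a short blank pause, then a lateralised
#' go arrow; on a random half of trials a stop/change signal follows at the
#' current staircase SOA. Two independent staircase threads (sampled at random
#' on each signal trial) step the SOA by +/- one step depending on outcome,
#' asymptoting at `soa_floor`.
#'
#' @param n_trials_per_block Trials per block (default 155).
#' @param n_blocks Number of blocks per session (default 2).
#' @param signal_probability Probability that a trial carries a stop/change
#'   signal (default 0.5).
#' @param fixation_range Two ordered seconds: uniform range of the fixation
#'   duration (default `c(1.3, 1.5)`).
#' @param pause Blank pause between fixation offset and go onset, seconds.
#' @param staircase_starts Starting SOAs of the two staircase threads,
#'   seconds (default `c(0, 0.3)`).
#' @param staircase_step Staircase step size, seconds (default 0.05).
#' @param soa_floor Lowest SOA the staircase may reach (default 0).
#' @param response_window Seconds after go onset allotted for responding.
#' @param iti_range Two ordered seconds: uniform range of the inter-trial
#'   gap appended after the response window. The jitter decorrelates the
#'   event trains of consecutive trials, which conditions the convolution
#'   GLM (default `c(0.1, 0.9)`).
#' @param signal_stimulus `"bar"` or `"arrow"`: morphology of the
#'   stop/change cue.
#' @param response_mode `"stop"` or `"change"`: whether the signal requires
#'   withholding the response or pressing the opposite button.
#'
#' @return An object of class `task_config`.
#' @export
#' @examples
#' cfg <- task_config(n_trials_per_block = 20, n_blocks = 1)
#' cfg$complexity
task_config <- function(n_trials_per_block = 155L,
                        n_blocks = 2L,
                        signal_probability = 0.5,
                        fixation_range = c(1.3, 1.5),
                        pause = 0.2,
                        staircase_starts = c(0, 0.3),
                        staircase_step = 0.05,
                        soa_floor = 0,
                        response_window = 1.0,
                        iti_range = c(0.1, 0.9),
                        signal_stimulus = c("bar", "arrow"),
                        response_mode = c("stop", "change")) {
  signal_stimulus <- match.arg(signal_stimulus)
  response_mode <- match.arg(response_mode)
  if (signal_probability <= 0 || signal_probability >= 1) {
    stop_invalid("signal_probability must lie strictly between 0 and 1")
  }
  if (staircase_step <= 0) stop_invalid("staircase_step must be positive")
  if (length(fixation_range) != 2L || diff(fixation_range) < 0) {
    stop_invalid("fixation_range must be an ordered pair of seconds")
  }
  if (soa_floor < 0) stop_invalid("soa_floor must be non-negative")
  if (length(iti_range) != 2L || diff(iti_range) < 0 || iti_range[1] < 0) {
    stop_invalid("iti_range must be an ordered pair of non-negative seconds")
  }
  structure(list(
    n_trials_per_block = as.integer(n_trials_per_block),
    n_blocks = as.integer(n_blocks),
    signal_probability = signal_probability,
    fixation_range = fixation_range,
    pause = pause,
    staircase_starts = staircase_starts,
    staircase_step = staircase_step,
    soa_floor = soa_floor,
    response_window = response_window,
    iti_range = iti_range,
    signal_stimulus = signal_stimulus,
    response_mode = response_mode,
    # Contextual complexity: minimal number of informative cue elements that
    # must be combined to act. A bar cue makes stopping simple but changing
    # complex; an arrow cue the reverse.
    complexity = complexity_level(signal_stimulus, response_mode)
  ), class = "task_config")
}

#' Contextual complexity level of a task variant
#'
#' The stop variant cued by a vertical bar and the change variant cued by a
#' directional arrow need one informative cue element (level 1); the other
#' two variants need the go and signal cues to be combined (level 2).
#'
#' @param signal_stimulus `"bar"` or `"arrow"`.
#' @param response_mode `"stop"` or `"change"`.
#' @return Integer complexity level, 1 (simple) or 2 (complex).
#' @export
complexity_level <- function(signal_stimulus, response_mode) {
  simple <- (response_mode == "stop" & signal_stimulus == "bar") |
    (response_mode == "change" & signal_stimulus == "arrow")
  ifelse(simple, 1L, 2L)
}

#' Race-model parameters for the go and stop processes
#'
#' The go process finishing time is ex-Gaussian (normal plus exponential);
#' the stop process has a fixed duration `ssrt_true` (optionally jittered
#' across trials). A linear drift in go finishing time models the slowing
#' that accumulates when subjects wait for the signal.
#'
#' Defaults give a median go RT of about 0.51 s and a mean-median gap of
#' about 0.009 s, so the traditional average-difference SSRT estimator and
#' the inhibition-function midpoint differ by roughly the gap observed
#' between the two estimators in real stop-signal sessions.
#'
#' @param go_mu,go_sigma Gaussian component mean and SD, seconds.
#' @param go_tau Exponential component mean, seconds.
#' @param ssrt_true Stop-process duration, seconds.
#' @param ssrt_sd Trial-to-trial SD of the stop duration (default 0, in which
#'   case the inhibition-function midpoint equals `ssrt_true`).
#' @param drift_slope Linear increase in go finishing time per trial,
#'   seconds/trial (default 0).
#' @param change_extra Added latency of the second (opposite) press after the
#'   stop process wins in change mode, seconds.
#' @param lapse_prob Probability of an unclassifiable error trial (wrong or
#'   double press).
#' @return An object of class `race_params`.
#' @export
race_params <- function(go_mu = 0.455,
                        go_sigma = 0.05,
                        go_tau = 0.06,
                        ssrt_true = 0.2,
                        ssrt_sd = 0,
                        drift_slope = 0,
                        change_extra = 0.35,
                        lapse_prob = 0) {
  if (go_sigma < 0) stop_invalid("go_sigma must be non-negative")
  if (go_tau <= 0) stop_invalid("go_tau must be positive")
  if (ssrt_true <= 0) stop_invalid("ssrt_true must be positive")
  if (ssrt_sd < 0) stop_invalid("ssrt_sd must be non-negative")
  if (lapse_prob < 0 || lapse_prob >= 1) {
    stop_invalid("lapse_prob must lie in [0, 1)")
  }
  structure(list(
    go_mu = go_mu, go_sigma = go_sigma, go_tau = go_tau,
    ssrt_true = ssrt_true, ssrt_sd = ssrt_sd,
    drift_slope = drift_slope, change_extra = change_extra,
    lapse_prob = lapse_prob
  ), class = "race_params")
}

#' Literature MNI coordinates of the regions of interest
#'
#' Shipped for provenance only; synthetic geometries used by the simulator
#' are arbitrary and do not attempt head-realistic placement.
#'
#' @return A data frame of region labels and MNI x, y, z coordinates (mm).
#' @export
roi_coordinates <- function() {
  data.frame(
    label = c("pre_sma", "r_ifg", "l_ifg", "sma", "r_m1", "l_m1"),
    x = c(2, 42, -42, -2, 37, -37),
    y = c(30, 26, 26, -10, -25, -25),
    z = c(48, 14, 14, 59, 62, 62)
  )
}
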