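# Shared fixture builders. Everything is generated in code; no stored data.

quick_session <- function(n = 200, seed = 1, mode = "stop", ...) {
  simulate_behavior_session(
    task_config(n_trials_per_block = n, n_blocks = 1L, response_mode = mode),
    race_params(...), seed = seed)
}

# Minimal classified_trials object built directly from a trial table, for
# tests that feed handcrafted data to the estimators.
make_ct <- function(trials, mode = "stop") {
  counts <- c(
    go_only = sum(trials$class == "go_only"),
    signal_success = sum(trials$class == "signal_success"),
    signal_fail = sum(trials$class == "signal_fail"),
    unclassified = sum(trials$class == "unclassified")
  )
  n_signal <- counts[["signal_success"]] + counts[["signal_fail"]]
  classified <- sum(counts[c("go_only", "signal_success", "signal_fail")])
  structure(list(
    trials = trials, counts = counts, presented = nrow(trials),
    classified = classified,
    change_fraction = if (classified > 0) n_signal / classified else NA_real_,
    fail_fraction = if (n_signal > 0) counts[["signal_fail"]] / n_signal else NA_real_,
    response_mode = mode, signal_stimulus = "bar",
    subject_id = "t", session_id = "t"
  ), class = "classified_trials")
}

# Drift model stub predicting a constant go RT.
flat_drift <- function(level = 0.5) {
  structure(list(predict = function(idx) rep(level, length(idx)),
                 method = "stub", slope = 0, residual_scale = 0),
            class = "drift_model")
}

# A tf_image wrapper around a plain matrix (freqs x times).
as_tf_image <- function(values, times, freqs, step = 0.05) {
  structure(list(times = times, freqs = freqs, values = values,
                 sfreq = 1 / step, step = step, window = 0.4, label = "fix"),
            class = "tf_image")
}

small_geometry <- function(n_channels = 24, n_sources = 3) {
  meg_geometry(n_channels, n_sources,
               source_labels = c("pre_sma", "r_ifg", "m1")[seq_len(n_sources)])
}
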