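#' Configuration of the end-to-end synthetic study
#'
#' Bundles every stage's parameters for [run_pipeline()]. The defaults
#' define a desk-scale synthetic study: 10 subjects each performing the four
#' task variants (bar/arrow stimulus x stop/change response) in one short
#' block, with three simulated cortical sources (complexity-scaled gamma at
#' `pre_sma`, signal-locked theta/alpha at `pre_sma` and `r_ifg`,
#' press-locked beta desynchronisation at `m1`) projected to a spherical
#' sensor array.
#'
#' @param seed Global integer seed; every stage derives its own stream.
#' @param n_subjects Number of simulated subjects (default 10).
#' @param n_trials_per_block,n_blocks Trials per block and blocks per
#'   condition (defaults 24 and 1: desk scale).
#' @param sfreq Sampling rate of the simulated recordings, Hz (default 200;
#'   Nyquist comfortably above the 90 Hz analysis ceiling).
#' @param n_channels Number of sensors (default 28).
#' @param race Baseline [race_params()].
#' @param complexity_rt_effect Seconds added to the go-process mean per
#'   complexity level above 1 (default 0.03: complex variants slow going).
#' @param subject_sd List of between-subject SDs: `go_mu` (s), `ssrt` (s),
#'   `amp` (lognormal sigma of effect amplitudes).
#' @param effects A [source_effect_config()].
#' @param sensor_snr Amplitude ratio of projected source signal RMS to
#'   sensor noise SD (default 2).
#' @param tf A [tf_config()].
#' @param glm_order Fourier basis order of the convolution GLM (default 11).
#' @param stats List: `alpha`, `n_perm` for the sign-flip FWE maps.
#' @param stages Character subset of `c("behavior", "meg", "stats")`.
#' @param out_dir Output directory, or `NULL` to keep results in memory.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            n_subjects = 10L,
                            n_trials_per_block = 24L,
                            n_blocks = 1L,
                            sfreq = 200,
                            n_channels = 28L,
                            race = race_params(),
                            complexity_rt_effect = 0.03,
                            subject_sd = list(go_mu = 0.03, ssrt = 0.02,
                                              amp = 0.2),
                            effects = source_effect_config(),
                            sensor_snr = 2,
                            tf = tf_config(),
                            glm_order = 11L,
                            stats = list(alpha = 0.05, n_perm = 500L),
                            stages = c("behavior", "meg", "stats"),
                            out_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

conditions_grid <- function() {
  data.frame(
    condition = 1:4,
    signal_stimulus = c("bar", "arrow", "bar", "arrow"),
    response_mode = c("stop", "stop", "change", "change"),
    stringsAsFactors = FALSE
  )
}

#' Run the full synthetic study pipeline
#'
#' Stages, in order: behavioral simulation of every subject x condition
#' session with classification, screening and SSRT estimation; simulation
#' of source activity and its projection to sensors, LCMV beamforming,
#' robust standardization and multitaper time-frequency decomposition;
#' convolution-GLM estimation of the induced responses per event type; and
#' group statistics (mean stop/change-signal response and the contextual
#' complexity interaction on the go response, both as sign-flip FWE maps
#' per source, plus the theta/alpha peak rate of rise per session and
#' source). The run is deterministic given `cfg$seed`. When `cfg$out_dir`
#' is set, summary tables, per-session event files and a manifest of output
#' hashes are written there.
#'
#' @param cfg A [pipeline_config()].
#' @return A list of class `pipeline_result` with elements `behavior`,
#'   `responses`, `stats`, `config`, and `manifest` (when files were
#'   written).
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  grid <- conditions_grid()
  res <- list(config = cfg)
  subjects <- sprintf("s%02d", seq_len(cfg$n_subjects))

  sessions <- list()
  for (si in seq_along(subjects)) {
    subj_seed <- derive_seed(cfg$seed, paste0("subject/", subjects[si]))
    subj_fx <- with_seed(subj_seed, list(
      go_mu = stats::rnorm(1, 0, cfg$subject_sd$go_mu),
      ssrt = stats::rnorm(1, 0, cfg$subject_sd$ssrt),
      amp = exp(stats::rnorm(1, 0, cfg$subject_sd$amp))
    ))
    for (ci in seq_len(nrow(grid))) {
      tcfg <- task_config(
        n_trials_per_block = cfg$n_trials_per_block,
        n_blocks = cfg$n_blocks,
        signal_stimulus = grid$signal_stimulus[ci],
        response_mode = grid$response_mode[ci]
      )
      rp <- cfg$race
      rp$go_mu <- rp$go_mu + subj_fx$go_mu +
        cfg$complexity_rt_effect * (tcfg$complexity - 1)
      rp$ssrt_true <- max(rp$ssrt_true + subj_fx$ssrt, 0.05)
      sessions[[paste(subjects[si], ci, sep = "_")]] <- list(
        subject = subjects[si], condition = ci,
        amp_gain = subj_fx$amp,
        session = simulate_behavior_session(
          tcfg, rp, seed = cfg$seed,
          subject_id = subjects[si], session_id = sprintf("c%d", ci))
      )
    }
  }

  if ("behavior" %in% cfg$stages) {
    res$behavior <- analyze_behavior_stage(sessions, cfg)
  }
  if ("meg" %in% cfg$stages) {
    res$responses <- meg_stage(sessions, cfg)
  }
  if ("stats" %in% cfg$stages && !is.null(res$responses)) {
    res$stats <- stats_stage(res$responses, res$behavior, cfg)
  }
  if (!is.null(cfg$out_dir)) {
    res$manifest <- write_pipeline_outputs(res, sessions, cfg)
  }
  class(res) <- "pipeline_result"
  invisible(res)
}

analyze_behavior_stage <- function(sessions, cfg) {
  rows <- list()
  for (key in names(sessions)) {
    it <- sessions[[key]]
    ct <- classify_trials(it$session)
    med <- session_medians(ct, trim = min(15L, nrow(it$session$trials) %/% 4L))
    est <- tryCatch(
      ssrt_estimates(ct, mcmc = list(n_chains = 2L, n_iter = 2000L,
                                     seed = cfg$seed)),
      error = function(e) NULL)
    scr <- screen_session(ct, med, fit = est$fit)
    rows[[key]] <- data.frame(
      subject = it$subject, condition = it$condition,
      stimulus = it$session$config$signal_stimulus,
      response = it$session$config$response_mode,
      presented = ct$presented,
      unclassified = ct$counts[["unclassified"]],
      classified = ct$classified,
      change_fraction = ct$change_fraction,
      fail_fraction = ct$fail_fraction,
      go_rt = med$go_rt, fail_rt = med$fail_rt, success_rt = med$success_rt,
      fail_soa = med$fail_soa, success_soa = med$success_soa,
      ssrt_av = est$ssrt_av %||% NA_real_,
      ssrt_mcmc = est$ssrt_mcmc %||% NA_real_,
      deviance = if (is.null(est)) NA_real_ else est$fit$deviance,
      retained = scr$retained,
      stringsAsFactors = FALSE
    )
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  cx <- tryCatch(
    complexity_contrast(data.frame(subject = summary$subject,
                                   stimulus = summary$stimulus,
                                   response = summary$response,
                                   value = summary$go_rt),
                        n_perm = 2000L, seed = cfg$seed),
    error = function(e) NULL)
  list(summary = summary, complexity = cx)
}

meg_stage <- function(sessions, cfg) {
  geom <- meg_geometry(cfg$n_channels, length(cfg$effects$sources),
                       source_labels = cfg$effects$sources)
  lf <- build_spherical_leadfield(geom$channel_positions,
                                  geom$source_positions,
                                  channel_names = geom$channel_names,
                                  source_labels = geom$source_labels)
  orientations <- source_orientations(lf, cfg$seed)
  basis <- fourier_basis(order = cfg$glm_order, step = cfg$tf$step)
  responses <- list()
  for (key in names(sessions)) {
    it <- sessions[[key]]
    fx <- scale_effects(cfg$effects, it$amp_gain)
    src <- simulate_source_signals(it$session, fx, sfreq = cfg$sfreq,
                                   seed = cfg$seed)
    clean_rms <- stats::sd(as.numeric(
      project_to_sensors(src, orientations, lf, noise_sd = 0)$data))
    rec <- project_to_sensors(src, orientations, lf,
                              noise_sd = clean_rms / cfg$sensor_snr,
                              seed = derive_seed(cfg$seed, key))
    cov <- compute_covariance(rec)
    filters <- lapply(seq_along(lf$gains), function(s) {
      lcmv_filter(lf$gains[[s]], cov, source_label = lf$source_labels[s])
    })
    extracted <- extract_sources(rec, filters)
    ev <- rec$events
    ev$type[ev$type == "signal"] <-
      paste0("signal_", sub("signal_", "", ev$outcome[ev$type == "signal"]))
    per_source <- list()
    for (s in seq_along(extracted)) {
      ts <- robust_standardize(extracted[[s]],
                               segment = min(10, floor(length(
                                 extracted[[s]]$values) / cfg$sfreq / 3)))
      tf <- multitaper_rms(ts, cfg$tf)
      design <- suppressWarnings(
        build_design(ev[ev$type != "signal_unclassified", , drop = FALSE],
                     basis, tf$times))
      fit <- suppressWarnings(fit_tf_glm(tf, design))
      # sustained "set" effects span the whole trial and split unstably
      # between the quasi-collinear fixation/go/press regressors, so the
      # trial-locked response is estimated by its own single-regressor
      # deconvolution (equivalent to a triggered average here because the
      # jittered inter-trial interval isolates the trial windows)
      trial_design <- suppressWarnings(
        build_design(ev[ev$type == "fixation", , drop = FALSE],
                     basis, tf$times))
      trial_fit <- suppressWarnings(fit_tf_glm(tf, trial_design))
      per_source[[lf$source_labels[s]]] <- list(
        go = tryCatch(reconstruct_induced(fit, "go"), error = function(e) NULL),
        fixation = tryCatch(reconstruct_induced(fit, "fixation"),
                            error = function(e) NULL),
        signal_success = tryCatch(reconstruct_induced(fit, "signal_success"),
                                  error = function(e) NULL),
        signal_fail = tryCatch(reconstruct_induced(fit, "signal_fail"),
                               error = function(e) NULL),
        trial = tryCatch(reconstruct_induced(trial_fit, "fixation"),
                         error = function(e) NULL)
      )
    }
    responses[[key]] <- list(subject = it$subject, condition = it$condition,
                             sources = per_source,
                             filter_similarity = filter_similarity(filters))
  }
  attr(responses, "basis") <- basis
  attr(responses, "source_labels") <- lf$source_labels
  responses
}

# Deterministic tangential orientations for the simulated sources.
source_orientations <- function(lf, seed) {
  t(vapply(seq_along(lf$gains), function(s) {
    # strongest effective orientation of the gain matrix itself
    sv <- svd(lf$gains[[s]])
    sv$v[, 1]
  }, numeric(3)))
}

scale_effects <- function(effects, gain) {
  effects$theta_alpha$amplitude <- effects$theta_alpha$amplitude * gain
  effects$gamma_complexity$amplitude <- effects$gamma_complexity$amplitude * gain
  effects$beta_post$amps <- effects$beta_post$amps * gain
  effects
}

stats_stage <- function(responses, behavior, cfg) {
  sources <- attr(responses, "source_labels")
  subjects <- unique(vapply(responses, `[[`, "", "subject"))
  out <- list(theta_map = list(), complexity_map = list())
  # per subject x source mean stop/change-signal response, and the
  # complexity interaction on the go-locked response
  for (src in sources) {
    theta_imgs <- list()
    cx_imgs <- list()
    for (subj in subjects) {
      keys <- names(responses)[vapply(responses, function(r) {
        r$subject == subj
      }, logical(1))]
      sig <- list()
      go_by_cond <- list()
      for (k in keys) {
        r <- responses[[k]]$sources[[src]]
        for (nm in c("signal_success", "signal_fail")) {
          if (!is.null(r[[nm]])) sig[[length(sig) + 1L]] <- r[[nm]]$values
        }
        if (!is.null(r$trial)) {
          go_by_cond[[as.character(responses[[k]]$condition)]] <- r$trial$values
        }
      }
      if (length(sig)) {
        theta_imgs[[subj]] <- Reduce(`+`, sig) / length(sig)
      }
      if (length(go_by_cond) == 4L) {
        # complexity (complex - simple): conditions 2 (arrow/stop) and
        # 3 (bar/change) are complex; 1 and 4 simple
        cx_imgs[[subj]] <- (go_by_cond[["2"]] + go_by_cond[["3"]] -
                              go_by_cond[["1"]] - go_by_cond[["4"]]) / 2
      }
    }
    if (length(theta_imgs) >= 5L) {
      out$theta_map[[src]] <- permutation_fwe(
        theta_imgs, alpha = cfg$stats$alpha, n_perm = cfg$stats$n_perm,
        seed = derive_seed(cfg$seed, paste0("fwe-theta-", src)))
    }
    if (length(cx_imgs) >= 5L) {
      out$complexity_map[[src]] <- permutation_fwe(
        cx_imgs, alpha = cfg$stats$alpha, n_perm = cfg$stats$n_perm,
        seed = derive_seed(cfg$seed, paste0("fwe-cx-", src)))
    }
  }
  # theta/alpha peak rate of rise per session and source
  basis <- attr(responses, "basis")
  rates <- list()
  for (k in names(responses)) {
    for (src in sources) {
      r <- responses[[k]]$sources[[src]]
      if (is.null(r$signal_success) || is.null(r$signal_fail)) next
      course <- average_courses(band_course(r$signal_success, c(2, 12)),
                                band_course(r$signal_fail, c(2, 12)))
      rates[[length(rates) + 1L]] <- data.frame(
        session = k, subject = responses[[k]]$subject,
        condition = responses[[k]]$condition, source = src,
        rate = peak_rate_of_rise(course), stringsAsFactors = FALSE)
    }
  }
  out$rates <- if (length(rates)) do.call(rbind, rates) else NULL
  if (!is.null(out$rates) && !is.null(behavior$summary$ssrt_av)) {
    ssrt_map <- behavior$summary$ssrt_av
    names(ssrt_map) <- paste(behavior$summary$subject,
                             behavior$summary$condition, sep = "_")
    sr <- ssrt_map[out$rates$session]
    if (sum(!is.na(sr)) >= 4L) {
      keep <- !is.na(sr)
      df <- out$rates[keep, ]
      df$group <- ssrt_median_split(sr[keep])
      out$rate_anova <- tryCatch(
        rate_by_ssrt_anova(df, n_perm = min(cfg$stats$n_perm, 1000L),
                           seed = cfg$seed),
        error = function(e) NULL)
    }
  }
  # grand-average TF images (freq x peristimulus time), frequency axis
  # taken from the TF configuration
  out$freqs <- cfg$tf$freqs
  out$peri_times <- basis$tau
  out
}

#' Test a stat map for a significant increase inside a band/time window
#'
#' @param map A `stat_map` from [permutation_fwe()].
#' @param freqs,times Axes of the map (Hz, s).
#' @param band Two Hz values delimiting the frequency window.
#' @param window Two seconds delimiting the peristimulus window.
#' @param sign `+1` to look for increases (default), `-1` for decreases.
#' @return `TRUE` when any pixel in the window is significant with the
#'   requested sign.
#' @export
detect_in_window <- function(map, freqs, times, band, window, sign = 1) {
  stopifnot(inherits(map, "stat_map"))
  fi <- freqs >= band[1] & freqs <= band[2]
  ti <- times >= window[1] & times <= window[2]
  any(map$mask[fi, ti] == sign)
}

write_pipeline_outputs <- function(res, sessions, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  log_line <- function(...) {
    cat(sprintf(...), "\n", file = file.path(cfg$out_dir, "pipeline.log"),
        append = TRUE)
  }
  cat("", file = file.path(cfg$out_dir, "pipeline.log"))
  log_line("pipeline seed %d: %d subjects x 4 conditions, stages: %s",
           cfg$seed, cfg$n_subjects, paste(cfg$stages, collapse = ","))
  ev_dir <- file.path(cfg$out_dir, "events")
  dir.create(ev_dir, showWarnings = FALSE)
  for (key in names(sessions)) {
    p <- file.path(ev_dir, paste0(key, ".tsv"))
    write_events_tsv(sessions[[key]]$session, p)
    paths <- c(paths, p)
  }
  if (!is.null(res$behavior)) {
    p <- file.path(cfg$out_dir, "behavior_summary.tsv")
    utils::write.table(res$behavior$summary, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    paths <- c(paths, p)
    log_line("behavior: %d sessions, %d retained",
             nrow(res$behavior$summary), sum(res$behavior$summary$retained))
  }
  if (!is.null(res$stats)) {
    p <- file.path(cfg$out_dir, "stat_maps.rds")
    saveRDS(res$stats, p)
    paths <- c(paths, p)
    rep_path <- file.path(cfg$out_dir, "stat_report.txt")
    con <- file(rep_path, "w")
    for (nm in names(res$stats$theta_map)) {
      m <- res$stats$theta_map[[nm]]
      writeLines(sprintf(
        "theta map %s: threshold %.2f, %d significant pixels",
        nm, m$threshold, sum(m$mask != 0)), con)
    }
    for (nm in names(res$stats$complexity_map)) {
      m <- res$stats$complexity_map[[nm]]
      writeLines(sprintf(
        "complexity map %s: threshold %.2f, %d significant pixels",
        nm, m$threshold, sum(m$mask != 0)), con)
    }
    close(con)
    paths <- c(paths, rep_path)
  }
  manifest <- data.frame(
    file = sub(paste0("^", cfg$out_dir, "/?"), "", paths),
    md5 = unname(tools::md5sum(paths)),
    stringsAsFactors = FALSE
  )
  mp <- file.path(cfg$out_dir, "manifest.tsv")
  utils::write.table(manifest, mp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  if (!is.null(x$behavior)) {
    cat(sprintf("  behavior: %d sessions, %d retained\n",
                nrow(x$behavior$summary), sum(x$behavior$summary$retained)))
  }
  if (!is.null(x$stats)) {
    cat(sprintf("  stat maps: theta at %s; complexity at %s\n",
                paste(names(x$stats$theta_map), collapse = "/"),
                paste(names(x$stats$complexity_map), collapse = "/")))
  }
  invisible(x)
}
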