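#' Per-subject contrast of induced responses
#'
#' Weighted sum of condition images within each subject. The contextual
#' complexity contrast uses weights `(+1, -1, -1, +1)` over the stimulus x
#' response cells (bar/stop, arrow/stop, bar/change, arrow/change), which
#' cancels any condition-independent component exactly.
#'
#' @param responses List (one element per subject) of named lists mapping
#'   condition labels to `induced_response`s (or plain matrices).
#' @param weights Named numeric vector of condition weights.
#' @return List of per-subject contrast matrices (freqs x times).
#' @export
tf_contrast <- function(responses, weights) {
  lapply(responses, function(subj) {
    if (!all(names(weights) %in% names(subj))) {
      stop_invalid("insufficient design: subject lacks conditions %s",
                   paste(setdiff(names(weights), names(subj)), collapse = ", "))
    }
    mats <- lapply(names(weights), function(cond) {
      r <- subj[[cond]]
      if (inherits(r, "induced_response")) r$values else as.matrix(r)
    })
    Reduce(`+`, Map(`*`, mats, as.list(unname(weights))))
  })
}

#' Sign-flip permutation test with max-statistic FWE control
#'
#' One-sample t image across subjects, with the familywise error of the
#' whole image controlled by the permutation distribution of the maximum
#' absolute t under random sign flips of the subject images (exact under
#' symmetric errors, no smoothness assumptions). Two-tailed.
#'
#' @param contrast_images List of per-subject matrices (same dimensions).
#' @param alpha Familywise alpha (default 0.05).
#' @param n_perm Number of sign-flip permutations (default 2000; fewer than
#'   100 is refused as the tail estimate is unstable).
#' @param seed Integer seed.
#' @return An object of class `stat_map`: `t` (observed t image),
#'   `threshold`, `mask` (+1 significant increase, -1 decrease, 0
#'   otherwise), `alpha`, `n_perm`, `max_t_null`.
#' @export
permutation_fwe <- function(contrast_images, alpha = 0.05, n_perm = 2000L,
                            seed = 1L) {
  n <- length(contrast_images)
  if (n < 5L) stop_invalid("need >= 5 subjects for sign-flip inference")
  if (n_perm < 100L) stop_invalid("n_perm < 100 gives an unstable tail")
  if (alpha <= 0 || alpha > 1) stop_invalid("alpha must lie in (0, 1]")
  dims <- dim(contrast_images[[1]])
  x <- t(vapply(contrast_images, as.numeric, numeric(prod(dims))))
  ss <- colSums(x^2)
  t_of <- function(m) {
    v <- pmax((ss - n * m^2) / (n - 1), 0)
    m / sqrt(v / n + 1e-300)
  }
  t_obs <- t_of(colMeans(x))
  max_null <- with_seed(derive_seed(seed, "permutation-fwe"), {
    vapply(seq_len(n_perm), function(p) {
      s <- sample(c(-1, 1), n, replace = TRUE)
      max(abs(t_of(colSums(s * x) / n)))
    }, numeric(1))
  })
  threshold <- if (alpha >= 1) 0 else {
    sort(max_null)[ceiling((1 - alpha) * n_perm)]
  }
  mask <- sign(t_obs) * (abs(t_obs) >= threshold)
  structure(list(
    t = matrix(t_obs, nrow = dims[1], ncol = dims[2]),
    threshold = threshold,
    mask = matrix(mask, nrow = dims[1], ncol = dims[2]),
    alpha = alpha,
    n_perm = n_perm,
    max_t_null = max_null,
    n_subjects = n
  ), class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf(
    "<stat_map> %d subjects, FWE alpha %.3g, |t| threshold %.2f, %d/%d pixels significant\n",
    x$n_subjects, x$alpha, x$threshold, sum(x$mask != 0), length(x$mask)))
  invisible(x)
}

#' Band-averaged peristimulus course of an induced response
#'
#' @param resp An `induced_response` (or `stat_map`-like list with `freqs`
#'   available via `freqs`).
#' @param band Two Hz values, e.g. `c(2, 12)` for theta/alpha or
#'   `c(15, 25)` for beta.
#' @return An object of class `band_course`: `times`, `values`, `band`,
#'   `label`.
#' @export
band_course <- function(resp, band) {
  stopifnot(inherits(resp, "induced_response"))
  rows <- resp$freqs >= band[1] & resp$freqs <= band[2]
  if (!any(rows)) stop_invalid("no analysis frequencies inside the band")
  structure(list(
    times = resp$times,
    values = colMeans(resp$values[rows, , drop = FALSE]),
    band = band,
    label = resp$event_type
  ), class = "band_course")
}

#' Average several band courses
#'
#' Used to combine the successful and unsuccessful stop/change courses
#' before the rate-of-rise measurement.
#'
#' @param ... `band_course` objects on the same time axis.
#' @return A `band_course`.
#' @export
average_courses <- function(...) {
  cs <- list(...)
  if (length(cs) == 1L && is.list(cs[[1]]) && !inherits(cs[[1]], "band_course")) {
    cs <- cs[[1]]
  }
  out <- cs[[1]]
  out$values <- Reduce(`+`, lapply(cs, `[[`, "values")) / length(cs)
  out$label <- "averaged"
  out
}

#' Peak rate of rise of a band course
#'
#' Maximum of the centered first difference of the course (divided by the
#' time step) inside the given peristimulus window, by default -0.2 to
#' +0.5 s around the stop/change signal.
#'
#' @param course A `band_course` (averaged over success conditions by the
#'   caller where required).
#' @param window Two seconds delimiting the search window.
#' @return Peak rate of rise in amplitude units per second.
#' @export
peak_rate_of_rise <- function(course, window = c(-0.2, 0.5)) {
  stopifnot(inherits(course, "band_course"))
  t <- course$times
  if (window[1] < min(t) || window[2] > max(t)) {
    stop_invalid("window outside the course span")
  }
  v <- course$values
  h <- stats::median(diff(t))
  inner <- 2:(length(t) - 1L)
  deriv <- (v[inner + 1L] - v[inner - 1L]) / (2 * h)
  keep <- t[inner] >= window[1] & t[inner] <= window[2]
  if (!any(keep)) stop_invalid("window contains no interior samples")
  max(deriv[keep])
}

#' Median split of sessions into short and long SSRT groups
#'
#' @param ssrt Numeric vector of session SSRTs.
#' @return Factor with levels `"short"` and `"long"` (values at the median
#'   fall in the short group).
#' @export
ssrt_median_split <- function(ssrt) {
  factor(ifelse(ssrt <= stats::median(ssrt), "short", "long"),
         levels = c("short", "long"))
}

#' Permutation ANOVA of theta/alpha rise rates by source and SSRT group
#'
#' Two-factor (source x SSRT group) analysis of the peak rate of rise, with
#' p values from label permutations: the group factor (and the interaction)
#' permute the session-to-group assignment, the source factor permutes
#' source labels within sessions. When the interaction is significant at
#' `posthoc_alpha`, per-source two-sample permutation tests localise the
#' group difference.
#'
#' @param rates Data frame with columns `session`, `source`, `group`
#'   (factor, 2 levels), `rate`.
#' @param n_perm Number of permutations (default 2000).
#' @param seed Integer seed.
#' @param posthoc_alpha Threshold on the interaction p for running post hoc
#'   tests (default 0.05).
#' @return A list of `stat_result`s: `source`, `group`, `interaction`, and
#'   (when run) one `posthoc` entry per source.
#' @export
rate_by_ssrt_anova <- function(rates, n_perm = 2000L, seed = 1L,
                               posthoc_alpha = 0.05) {
  need <- c("session", "source", "group", "rate")
  if (!all(need %in% names(rates))) {
    stop_invalid("rates must have columns %s", paste(need, collapse = ", "))
  }
  rates$group <- factor(rates$group)
  rates$source <- factor(rates$source)
  if (nlevels(rates$group) != 2L) {
    stop_invalid("insufficient design: need exactly 2 SSRT groups")
  }
  f_stats <- function(df) {
    a <- stats::anova(stats::lm(rate ~ source * group, data = df))
    stats::setNames(a[["F value"]][1:3], c("source", "group", "interaction"))
  }
  obs <- f_stats(rates)
  sessions <- unique(rates$session)
  sess_group <- rates$group[match(sessions, rates$session)]
  perm <- with_seed(derive_seed(seed, "rate-anova"), {
    t(vapply(seq_len(n_perm), function(p) {
      df <- rates
      # group/interaction null: reassign sessions to groups
      new_group <- sample(sess_group)
      df$group <- new_group[match(df$session, sessions)]
      # source null: shuffle source labels within each session
      for (s in sessions) {
        i <- which(df$session == s)
        df$source[i] <- df$source[i][sample.int(length(i))]
      }
      f_stats(df)
    }, numeric(3)))
  })
  pvals <- vapply(1:3, function(j) {
    (1 + sum(perm[, j] >= obs[j])) / (1 + n_perm)
  }, numeric(1))
  out <- list()
  for (j in seq_along(obs)) {
    out[[names(obs)[j]]] <- structure(list(
      effect = names(obs)[j], estimate = NA_real_, statistic = obs[[j]],
      p_value = pvals[j], n_perm = n_perm
    ), class = "stat_result")
  }
  if (pvals[3] < posthoc_alpha) {
    out$posthoc <- lapply(split(rates, rates$source), function(df) {
      permutation_t2(df$rate, df$group, n_perm = n_perm, seed = seed)
    })
  }
  out
}

# Two-sample permutation test on a mean difference.
permutation_t2 <- function(x, g, n_perm = 2000L, seed = 1L) {
  g <- factor(g)
  obs <- mean(x[g == levels(g)[1]]) - mean(x[g == levels(g)[2]])
  perm <- with_seed(derive_seed(seed, "perm-t2"), {
    vapply(seq_len(n_perm), function(p) {
      gp <- sample(g)
      mean(x[gp == levels(g)[1]]) - mean(x[gp == levels(g)[2]])
    }, numeric(1))
  })
  structure(list(
    effect = "group_difference",
    estimate = obs,
    statistic = obs,
    p_value = (1 + sum(abs(perm) >= abs(obs))) / (1 + n_perm),
    n_perm = n_perm
  ), class = "stat_result")
}
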