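#' Bayesian MCMC fit of the inhibition function
#'
#' Models the probability of successful stopping as a function of the
#' RT-corrected SOA, z = predicted go RT (from the drift model, at that
#' trial) - SOA. Under the race model, stopping succeeds when the go process
#' outlasts the stop process, so P(success) rises with z and crosses 0.5
#' where z equals the stop-process duration: the psychometric midpoint
#' `alpha` is the SSRT.
#'
#' Likelihood per signal trial: Bernoulli with
#' `P(success | z) = lambda/2 + (1 - lambda) * plogis(beta * (z - alpha))`.
#' Priors: `alpha ~ Normal(prior_center, 0.05 s)`; `log(beta)` uniform on
#' a wide range; `lambda ~ Beta(1, 19)` truncated to `[0, 0.1]`. Sampling is
#' random-walk Metropolis, several chains with half of each discarded as
#' burn-in; posterior means are reported. Convergence is monitored with the
#' split R-hat of each parameter (warning flagged above 1.1).
#'
#' Goodness of fit is a binned deviance: trials are grouped into quintiles
#' of z (sparse tail bins merged so every bin holds at least `min_bin`
#' trials) and deviance = 2 * (saturated binomial log-likelihood - model
#' log-likelihood) over the bins. Five bins against three fitted parameters
#' leave about two residual degrees of freedom, so well-fitting sessions
#' score about 2 and the screening threshold of 7.5 flags only clear
#' misfits, matching the scale of the published per-session deviances.
#'
#' @param ct A `classified_trials`.
#' @param drift A `drift_model` from [estimate_rt_drift()].
#' @param prior_center Center of the Gaussian prior on the midpoint,
#'   seconds (typically the average of the two traditional SSRT estimates).
#' @param n_chains,n_iter Chains and iterations per chain (default 4 x 5000,
#'   first half discarded).
#' @param proposal_sd Random-walk SDs for `(alpha, log beta, lambda)`.
#' @param seed Integer seed.
#' @param min_bin Minimum trials per deviance bin (default 5).
#' @return An object of class `inhibition_fit`: posterior means `alpha`
#'   (seconds), `beta` (1/seconds), `lambda`; posterior `samples`;
#'   `deviance`; `rhat`; `converged`; `prior_center`; and the binned data.
#' @export
fit_inhibition_function <- function(ct, drift, prior_center,
                                    n_chains = 4L, n_iter = 5000L,
                                    proposal_sd = c(0.01, 0.25, 0.01),
                                    seed = 1L, min_bin = 5L) {
  stopifnot(inherits(ct, "classified_trials"), inherits(drift, "drift_model"))
  tr <- ct$trials
  sig <- tr$class %in% c("signal_success", "signal_fail")
  if (sum(sig) < 20L) {
    stop_invalid("insufficient data: %d classified signal trials (need >= 20)",
                 sum(sig))
  }
  z <- drift$predict(tr$index[sig]) - tr$soa[sig]
  y <- as.integer(tr$class[sig] == "signal_success")
  if (length(unique(round(z, 6))) < 3L) {
    stop_invalid("insufficient data: need >= 3 distinct corrected-SOA values")
  }

  log_beta_range <- log(c(0.5, 2000))
  lambda_max <- 0.1
  log_post <- function(th) {
    alpha <- th[1]; beta <- exp(th[2]); lambda <- th[3]
    if (th[2] < log_beta_range[1] || th[2] > log_beta_range[2] ||
        lambda < 0 || lambda > lambda_max) {
      return(-Inf)
    }
    p <- lambda / 2 + (1 - lambda) * stats::plogis(beta * (z - alpha))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    sum(y * log(p) + (1 - y) * log(1 - p)) +
      stats::dnorm(alpha, prior_center, 0.05, log = TRUE) +
      stats::dbeta(lambda, 1, 19, log = TRUE)
  }

  keep <- n_iter %/% 2L
  draws <- array(NA_real_, c(keep, n_chains, 3L))
  with_seed(derive_seed(seed, "inhibition-mcmc"), {
    for (ch in seq_len(n_chains)) {
      th <- c(prior_center + stats::rnorm(1, 0, 0.02),
              log(20) + stats::rnorm(1, 0, 0.3),
              stats::runif(1, 0.001, 0.05))
      lp <- log_post(th)
      for (it in seq_len(n_iter)) {
        prop <- th + stats::rnorm(3, 0, proposal_sd)
        lp_prop <- log_post(prop)
        if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
          th <- prop
          lp <- lp_prop
        }
        if (it > n_iter - keep) draws[it - (n_iter - keep), ch, ] <- th
      }
    }
  })

  rhat <- vapply(1:3, function(j) split_rhat(draws[, , j]), numeric(1))
  names(rhat) <- c("alpha", "log_beta", "lambda")
  flat <- apply(draws, 3L, c)
  alpha <- mean(flat[, 1])
  beta <- mean(exp(flat[, 2]))
  lambda <- mean(flat[, 3])

  dev <- binned_deviance(z, y, alpha, beta, lambda, min_bin = min_bin)
  converged <- all(rhat < 1.1)
  if (!converged) {
    warning("inhibition-function chains may not have converged (split R-hat > 1.1)")
  }
  structure(list(
    alpha = alpha, beta = beta, lambda = lambda,
    samples = data.frame(alpha = flat[, 1], beta = exp(flat[, 2]),
                         lambda = flat[, 3]),
    deviance = dev$deviance, bins = dev$bins,
    rhat = rhat, converged = converged,
    prior_center = prior_center, n = length(y)
  ), class = "inhibition_fit")
}

# Split R-hat over a (iterations x chains) matrix of draws.
split_rhat <- function(m) {
  half <- nrow(m) %/% 2L
  if (half < 2L) return(NA_real_)
  chains <- cbind(m[seq_len(half), , drop = FALSE],
                  m[half + seq_len(half), , drop = FALSE])
  mns <- colMeans(chains)
  vars <- apply(chains, 2, stats::var)
  n <- nrow(chains)
  w <- mean(vars)
  b <- n * stats::var(mns)
  if (w <= 0) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

# Binomial deviance over quintile bins of z, sparse tails merged.
binned_deviance <- function(z, y, alpha, beta, lambda, min_bin = 5L) {
  p_model <- lambda / 2 + (1 - lambda) * stats::plogis(beta * (z - alpha))
  edges <- unique(stats::quantile(z, probs = seq(0, 1, 0.2), names = FALSE))
  if (length(edges) < 3L) edges <- range(z)
  bin <- findInterval(z, edges, rightmost.closed = TRUE, all.inside = TRUE)
  # merge bins holding fewer than min_bin trials into their left neighbour
  repeat {
    counts <- table(bin)
    small <- names(counts)[counts < min_bin]
    if (!length(small) || length(counts) == 1L) break
    b <- as.integer(small[1])
    ids <- sort(unique(bin))
    target <- if (b == ids[1]) ids[which(ids == b) + 1L] else ids[which(ids == b) - 1L]
    bin[bin == b] <- target
  }
  ll_bin <- function(k, n, p) {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    k * log(p) + (n - k) * log(1 - p)
  }
  ks <- tapply(y, bin, sum)
  ns <- tapply(y, bin, length)
  ps <- tapply(p_model, bin, mean)
  obs <- ks / ns
  ll_model <- sum(ll_bin(ks, ns, ps))
  ll_sat <- sum(ll_bin(ks, ns, obs))
  list(
    deviance = max(2 * (ll_sat - ll_model), 0),
    bins = data.frame(n = as.vector(ns), successes = as.vector(ks),
                      observed = as.vector(obs), predicted = as.vector(ps),
                      mean_z = as.vector(tapply(z, bin, mean)))
  )
}

#' @export
print.inhibition_fit <- function(x, ...) {
  cat(sprintf(
    "<inhibition_fit> midpoint %.3f s, slope %.1f /s, lapse %.3f, deviance %.2f%s\n",
    x$alpha, x$beta, x$lambda, x$deviance,
    if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}
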