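test_that("classification counts, fractions and degenerate cases", {
  s <- quick_session(400, seed = 11)
  ct <- classify_trials(s)
  expect_equal(sum(ct$counts), ct$presented)
  expect_equal(ct$classified + ct$counts[["unclassified"]], ct$presented)
  expect_equal(ct$fail_fraction,
               ct$counts[["signal_fail"]] /
                 (ct$counts[["signal_fail"]] + ct$counts[["signal_success"]]))
  # wrong-direction press on a go trial is an unclassified error
  s2 <- quick_session(30, seed = 12)
  s2$trials$press_direction[!s2$trials$is_signal_trial][1] <-
    setdiff(c("L", "R"),
            s2$trials$go_direction[!s2$trials$is_signal_trial][1])
  ct2 <- classify_trials(s2)
  bad <- which(!s2$trials$is_signal_trial)[1]
  expect_equal(ct2$trials$class[bad], "unclassified")
  # all-unclassified session: fractions flagged undefined
  s3 <- quick_session(20, seed = 13)
  s3$trials$double_press <- TRUE
  ct3 <- classify_trials(s3)
  expect_equal(ct3$classified, 0)
  expect_true(is.na(ct3$fail_fraction))
})

test_that("median go RT trims session edges and guards small sessions", {
  s <- quick_session(100, seed = 14)
  ct <- classify_trials(s)
  ct$trials$rt[ct$trials$class == "go_only"] <- 0.5
  expect_equal(median_go_rt(ct), 0.5)
  # positive drift: trimming removes the extremes so the median cannot grow
  sdrift <- quick_session(300, seed = 15, drift_slope = 5e-4)
  ctd <- classify_trials(sdrift)
  expect_lte(median_go_rt(ctd, trim = 15L), median_go_rt(ctd, trim = 0L) + 0.02)
  s31 <- quick_session(31, seed = 16)
  expect_error(median_go_rt(classify_trials(s31), trim = 15L), "insufficient")
})

test_that("average-difference SSRT follows its defining arithmetic", {
  trials <- data.frame(
    index = 1:20,
    class = rep(c("go_only", "signal_fail"), each = 10),
    rt = c(rep(0.57, 10), rep(0.4, 10)),
    soa = c(rep(NA, 10), rep(0.357, 10))
  )
  expect_equal(ssrt_average_difference(make_ct(trials)), 0.213)
  trials$soa[11:20] <- 0
  expect_equal(ssrt_average_difference(make_ct(trials)), 0.57)
  only_go <- trials[1:10, ]
  expect_error(ssrt_average_difference(make_ct(only_go)), "insufficient")
})

test_that("integration SSRT uses the ceiling-index quantile convention", {
  trials <- data.frame(
    index = 1:10,
    class = c(rep("go_only", 5), rep("signal_fail", 2),
              rep("signal_success", 3)),
    rt = c(0.4, 0.5, 0.6, 0.7, 0.8, rep(NA, 5)),
    soa = c(rep(NA, 5), rep(0.3, 5))
  )
  # fail fraction 2/5 = 0.4 -> ceiling(0.4 * 5) = 2nd sorted RT = 0.5
  expect_equal(ssrt_integration(make_ct(trials)), 0.5 - 0.3)
  all_fail <- trials
  all_fail$class[all_fail$class == "signal_success"] <- "signal_fail"
  expect_error(ssrt_integration(make_ct(all_fail)), "degenerate")
})

test_that("SSRT estimators recover the simulated stop duration", {
  s <- quick_session(2000, seed = 17, ssrt_true = 0.2)
  ct <- classify_trials(s)
  expect_equal(ssrt_average_difference(ct), 0.2, tolerance = 0.1)
  expect_equal(ssrt_integration(ct), 0.2, tolerance = 0.1)
})

test_that("ssrt_av is exactly the mean of the two traditional estimates", {
  s <- quick_session(600, seed = 18)
  est <- suppressWarnings(
    ssrt_estimates(classify_trials(s),
                   mcmc = list(n_chains = 2L, n_iter = 600L, seed = 1)))
  expect_identical(est$ssrt_av,
                   (est$ssrt_avgdiff + est$ssrt_integration) / 2)
})

test_that("drift model reproduces noiseless linear drift and flags tiny input", {
  trials <- data.frame(index = 1:60, class = "go_only",
                       rt = 0.4 + 2e-4 * (1:60), soa = NA_real_)
  dm <- estimate_rt_drift(make_ct(trials))
  expect_equal(dm$predict(1:60), trials$rt, tolerance = 1e-6)
  expect_lt(dm$residual_scale, 1e-6)
  expect_equal(dm$slope, 2e-4, tolerance = 1e-6)
  small <- trials[1:5, ]
  expect_error(estimate_rt_drift(make_ct(small)), "insufficient")
})

test_that("drift recovery: null slope covered, injected slope recovered", {
  slopes0 <- slopes1 <- numeric(20)
  for (k in 1:20) {
    ct0 <- classify_trials(quick_session(300, seed = 100 + k))
    ct1 <- classify_trials(quick_session(300, seed = 200 + k,
                                         drift_slope = 2e-4))
    slopes0[k] <- estimate_rt_drift(ct0)$slope
    slopes1[k] <- estimate_rt_drift(ct1)$slope
  }
  ci0 <- mean(slopes0) + c(-2, 2) * stats::sd(slopes0) / sqrt(20)
  expect_true(ci0[1] < 0 && ci0[2] > 0)
  expect_equal(mean(slopes1), 2e-4, tolerance = 0.3)
})

test_that("screening applies the three rules in order", {
  meds <- list(go_rt = 0.57, fail_rt = 0.52, success_soa = 0.34,
               fail_soa = 0.39)
  base <- classify_trials(quick_session(200, seed = 19))
  # fail fraction below 0.28 excludes
  low_ff <- base; low_ff$fail_fraction <- 0.20
  r <- screen_session(low_ff, meds)
  expect_equal(r$rule_fail_fraction, "fail")
  expect_false(r$retained)
  expect_equal(r$rule_deviance, "not_evaluated")
  # deviance above 7.5 excludes when earlier rules pass
  ok <- base; ok$fail_fraction <- 0.33
  r2 <- screen_session(ok, meds, fit = 7.9)
  expect_equal(r2$rule_deviance, "fail")
  expect_false(r2$retained)
  # a session matching the published retained-mean profile passes
  ok$fail_fraction <- 0.39
  r3 <- screen_session(ok, meds, fit = 2.7)
  expect_true(r3$retained)
  # SOA ordering violation excludes and suppresses the deviance rule
  bad_soa <- list(go_rt = 0.58, fail_rt = 0.48, success_soa = 0.33,
                  fail_soa = 0.32)
  r4 <- screen_session(ok, bad_soa, fit = 1.0)
  expect_equal(r4$rule_soa_ordering, "fail")
  expect_equal(r4$rule_deviance, "not_evaluated")
  expect_false(r4$retained)
})

test_that("post-signal RT correction pairs go trials across uniform signal runs", {
  mk <- function(classes, rts) {
    data.frame(index = seq_along(classes), class = classes, rt = rts,
               soa = ifelse(grepl("signal", classes), 0.2, NA))
  }
  t1 <- make_ct(mk(c("go_only", "signal_fail", "go_only"),
                   c(0.50, 0.45, 0.56)))
  out1 <- corrected_post_signal_rt(t1)
  expect_equal(nrow(out1), 1L)
  expect_equal(out1$corrected_rt, 0.06)
  expect_equal(out1$previous_outcome, "signal_fail")
  # mixed-outcome runs are skipped
  t2 <- make_ct(mk(c("go_only", "signal_success", "signal_fail", "go_only"),
                   c(0.50, NA, 0.45, 0.56)))
  expect_equal(nrow(corrected_post_signal_rt(t2)), 0L)
  # uniform multi-signal runs are kept with their run length
  t3 <- make_ct(mk(c("go_only", "signal_success", "signal_success", "go_only"),
                   c(0.50, NA, NA, 0.47)))
  out3 <- corrected_post_signal_rt(t3)
  expect_equal(out3$run_length, 2L)
  expect_equal(out3$corrected_rt, -0.03)
})

test_that("post-signal correction is centered on drift-only simulations", {
  vals <- numeric(15)
  for (k in 1:15) {
    ct <- classify_trials(quick_session(300, seed = 300 + k,
                                        drift_slope = 3e-4))
    vals[k] <- mean(corrected_post_signal_rt(ct)$corrected_rt)
  }
  expect_equal(mean(vals), 0, tolerance = 0.01)
})

test_that("complexity interaction contrast behaves as a contrast", {
  grid <- expand.grid(subject = paste0("s", 1:6),
                      stimulus = c("bar", "arrow"),
                      response = c("stop", "change"))
  equal <- transform(grid, value = 0.5)
  r <- complexity_contrast(equal, n_perm = 200, seed = 1)
  expect_equal(r$estimate, 0)
  expect_gt(r$p_value, 0.5)
  # a common per-subject offset cancels exactly
  offs <- transform(grid, value = 0.5 + as.integer(factor(subject)) * 0.1)
  expect_equal(complexity_contrast(offs, n_perm = 200, seed = 1)$estimate, 0)
  # injected complexity effect is detected
  set.seed(20)
  eff <- transform(grid, value = 0.5 + 0.03 * (complexity_level(
    as.character(stimulus), as.character(response)) - 1) +
      stats::rnorm(nrow(grid), 0, 0.005))
  r2 <- complexity_contrast(eff, n_perm = 2000, seed = 2)
  expect_lt(r2$p_value, 0.05)
  expect_equal(r2$complexity_effect, 0.06, tolerance = 0.5)
  expect_error(complexity_contrast(eff[eff$stimulus == "bar", ]),
               "insufficient")
})
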