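test_that("covariance estimate matches the textbook formula plus ridge", {
  set.seed(1)
  x <- matrix(stats::rnorm(30 * 10000), nrow = 30)
  cv <- compute_covariance(x)
  oracle <- stats::cov(t(x))
  expect_equal(cv$lambda, 1e-4 * mean(diag(oracle)), tolerance = 1e-10)
  expect_equal(unname(cv$matrix),
               unname(oracle + diag(cv$lambda, 30)), tolerance = 1e-10)
  expect_equal(mean(diag(cv$matrix)), 1, tolerance = 0.05)
  expect_true(isSymmetric(cv$matrix))
  expect_true(all(eigen(cv$matrix, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
})

test_that("degenerate covariance inputs are flagged", {
  const <- matrix(1, nrow = 4, ncol = 100)
  cv <- compute_covariance(const)
  expect_true(cv$singular || all(cv$matrix == 0))
  bad <- matrix(stats::rnorm(40), 4); bad[2, 3] <- Inf
  expect_error(compute_covariance(bad), "non-finite")
  expect_warning(compute_covariance(matrix(stats::rnorm(40), 10, 4)),
                 "fewer samples")
})

test_that("LCMV filter satisfies the unit-gain constraint by construction", {
  g <- small_geometry()
  lf <- build_spherical_leadfield(g$channel_positions, g$source_positions,
                                  channel_names = g$channel_names)
  set.seed(2)
  x <- matrix(stats::rnorm(24 * 5000), nrow = 24,
              dimnames = list(g$channel_names, NULL))
  cv <- compute_covariance(x)
  for (s in 1:3) {
    f <- lcmv_filter(lf$gains[[s]], cv)
    expect_lt(abs(sum(f$weights * f$oriented_gain) - 1), 1e-9)
    expect_equal(sum(f$orientation^2), 1, tolerance = 1e-9)
  }
})

test_that("identity covariance gives the closed-form projection filter", {
  set.seed(3)
  gain <- matrix(stats::rnorm(18), nrow = 6)
  cv <- compute_covariance(diag(6) %*% matrix(stats::rnorm(6 * 50000), 6))
  # near-identity covariance: w approx l / (l'l)
  f <- lcmv_filter(gain, cv)
  l <- f$oriented_gain
  expect_equal(unname(f$weights), unname(l / sum(l^2)), tolerance = 0.05)
})

test_that("emitted weights solve the constrained minimum-variance problem", {
  # oracle: numerical optimization over the null space of the constraint
  set.seed(4)
  for (nch in c(5, 8)) {
    a <- matrix(stats::rnorm(nch * nch), nch)
    c_reg <- crossprod(a) + diag(0.1, nch)
    gain <- matrix(stats::rnorm(nch * 3), nch)
    cv <- structure(list(matrix = c_reg, lambda = 0, n_samples = 1000,
                         channel_names = sprintf("ch%d", 1:nch),
                         singular = FALSE), class = "reg_covariance")
    f <- lcmv_filter(gain, cv)
    l <- f$oriented_gain
    w0 <- l / sum(l^2)
    nullsp <- qr.Q(qr(cbind(l)), complete = TRUE)[, -1, drop = FALSE]
    obj <- function(v) {
      w <- w0 + nullsp %*% v
      drop(crossprod(w, c_reg %*% w))
    }
    opt <- stats::optim(rep(0, nch - 1), obj, method = "BFGS",
                        control = list(reltol = 1e-14, maxit = 1000))
    w_star <- w0 + nullsp %*% opt$par
    expect_lt(max(abs(unname(f$weights) - drop(w_star))), 1e-6)
  }
})

test_that("max-power orientation recovers a dominant source orientation", {
  g <- small_geometry()
  lf <- build_spherical_leadfield(g$channel_positions, g$source_positions,
                                  channel_names = g$channel_names)
  # a strong oscillating source with known tangential orientation
  sv <- svd(lf$gains[[1]])
  u_star <- sv$v[, 1]
  set.seed(5)
  n <- 60000
  src <- 5 * sin(2 * pi * 11 * (1:n) / 200) * stats::rnorm(n, 1, 0.1)
  data <- (lf$gains[[1]] %*% u_star) %*% t(src) +
    matrix(stats::rnorm(24 * n, sd = 0.5 * mean(abs(lf$gains[[1]]))), 24)
  cv <- compute_covariance(data)
  f <- lcmv_filter(lf$gains[[1]], cv)
  angle <- acos(min(abs(sum(f$orientation * u_star)), 1)) * 180 / pi
  expect_lt(angle, 10)
})

test_that("extraction is unit-gain on the filter's own source", {
  g <- small_geometry()
  lf <- build_spherical_leadfield(g$channel_positions, g$source_positions,
                                  channel_names = g$channel_names)
  set.seed(6)
  n <- 20000
  src <- stats::rnorm(n)
  u <- svd(lf$gains[[2]])$v[, 1]
  data <- (lf$gains[[2]] %*% u) %*% t(src)
  dimnames(data) <- list(g$channel_names, NULL)
  cv <- compute_covariance(data + matrix(stats::rnorm(length(data),
                                                      sd = 1e-6), 24))
  f <- lcmv_filter(lf$gains[[2]], cv, "own")
  out <- extract_sources(data, list(f))[[1]]
  expect_gt(abs(stats::cor(out$values, src)), 0.9999)
  # zero-weight filter gives a null series
  f0 <- f; f0$weights[] <- 0
  expect_true(all(extract_sources(data, list(f0))[[1]]$values == 0))
  # channel mismatch errors
  f_bad <- f; names(f_bad$weights)[1] <- "nonexistent"
  expect_error(extract_sources(data, list(f_bad)), "mismatch")
})

test_that("scaling sensor data scales raw outputs and leaves standardized ones", {
  g <- small_geometry()
  lf <- build_spherical_leadfield(g$channel_positions, g$source_positions,
                                  channel_names = g$channel_names)
  set.seed(7)
  data <- matrix(stats::rnorm(24 * 12000), 24,
                 dimnames = list(g$channel_names, NULL))
  cv <- compute_covariance(data)
  f <- lcmv_filter(lf$gains[[1]], cv)
  a <- extract_sources(data, list(f))[[1]]
  b <- extract_sources(3 * data, list(f))[[1]]
  expect_equal(b$values, 3 * a$values, tolerance = 1e-12)
  sa <- robust_standardize(a$values, segment = 10, sfreq = 200)
  sb <- robust_standardize(b$values, segment = 10, sfreq = 200)
  expect_equal(sa$values, sb$values, tolerance = 1e-10)
})

test_that("filter similarity is a squared correlation with unit diagonal", {
  f1 <- structure(list(weights = c(1, 2, 3, 4), label = "a"),
                  class = "spatial_filter")
  f2 <- structure(list(weights = c(1, 2, 3, 4), label = "b"),
                  class = "spatial_filter")
  f3 <- structure(list(weights = c(1, -1, 1, -1), label = "c"),
                  class = "spatial_filter")
  f4 <- structure(list(weights = c(-1, -1, 1, 1), label = "d"),
                  class = "spatial_filter")
  r2 <- filter_similarity(list(f1, f2))
  expect_equal(unname(r2[1, 2]), 1)
  r2b <- filter_similarity(list(f3, f4))
  expect_equal(unname(r2b[1, 2]), 0, tolerance = 1e-12)
  expect_error(filter_similarity(list(f1)), "at least 2")
  fconst <- structure(list(weights = rep(2, 4), label = "e"),
                      class = "spatial_filter")
  expect_warning(filter_similarity(list(f1, fconst)), "constant")
})

test_that("robust standardization matches its defining formula and resists artifacts", {
  set.seed(8)
  sfreq <- 100
  x <- stats::rnorm(60 * sfreq, sd = 2)
  out <- robust_standardize(x, segment = 10, sfreq = sfreq)
  # oracle: direct evaluation of the stated estimator
  grp <- rep(1:6, each = 10 * sfreq)
  m1 <- mean(tapply(x, grp, stats::median))
  m2 <- mean(tapply(x^2, grp, stats::median))
  expect_equal(out$moments[["m1"]], m1)
  expect_equal(out$moments[["m2"]], m2)
  expect_equal(out$values, (x - m1) / sqrt(m2 - m1^2), tolerance = 1e-12)
  expect_error(robust_standardize(rep(1, 2000), segment = 10, sfreq = 100),
               "flat")
  expect_error(robust_standardize(x[1:50], segment = 10, sfreq = 100),
               "shorter")
  # one extreme sample barely moves the robust moments
  x_art <- x; x_art[123] <- 1e4
  out_art <- robust_standardize(x_art, segment = 10, sfreq = sfreq)
  expect_lt(abs(out_art$moments[["m2"]] - out$moments[["m2"]]) /
              out$moments[["m2"]], 0.01)
  plain_shift <- abs(stats::sd(x_art) - stats::sd(x)) / stats::sd(x)
  expect_gt(plain_shift, 0.1)
})
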