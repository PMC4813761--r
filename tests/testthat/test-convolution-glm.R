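test_that("Fourier basis counts, orthogonality and aliasing bound", {
  b <- fourier_basis(order = 1)
  expect_equal(dim(b$matrix), c(41L, 3L))
  expect_equal(b$tau[c(1, 41)], c(-0.5, 1.5))
  b11 <- fourier_basis(order = 11)
  gram <- crossprod(b11$matrix)
  expect_lt(max(abs(gram - diag(diag(gram)))), 1e-6)
  expect_error(fourier_basis(order = 30), "aliases")
  expect_error(fourier_basis(order = 0), ">= 1")
})

test_that("a single far-from-edge event reproduces the translated basis", {
  basis <- fourier_basis(order = 3)
  tf_times <- seq(0, 60, by = 0.05)
  des <- build_design(data.frame(onset = 30, type = "A"), basis, tf_times)
  i0 <- which.min(abs(tf_times - 30))
  rows <- i0 + round(basis$tau / 0.05)
  block <- des$matrix[rows, ]
  expect_equal(unname(block), unname(basis$matrix), tolerance = 1e-12)
  outside <- des$matrix[-rows, ]
  expect_true(all(outside == 0))
})

test_that("temporally disjoint event types produce non-interacting columns", {
  basis <- fourier_basis(order = 2)
  tf_times <- seq(0, 100, by = 0.05)
  ev <- data.frame(onset = c(10, 20, 60, 70), type = c("A", "A", "B", "B"))
  des <- build_design(ev, basis, tf_times)
  a_cols <- des$matrix[, des$columns$regressor == "A"]
  b_cols <- des$matrix[, des$columns$regressor == "B"]
  expect_true(all(crossprod(a_cols, b_cols) == 0))
})

test_that("the design equals a brute-force shifted-basis construction", {
  basis <- fourier_basis(order = 5)
  tf_times <- seq(0, 80, by = 0.05)
  set.seed(10)
  onsets <- sort(stats::runif(50, 1, 79)) # heavily overlapping
  des <- build_design(data.frame(onset = onsets, type = "A"), basis, tf_times)
  oracle <- matrix(0, length(tf_times), ncol(basis$matrix))
  for (on in onsets) {
    i0 <- round((on - tf_times[1]) / 0.05) + 1
    for (j in seq_along(basis$tau)) {
      r <- i0 + round(basis$tau[j] / 0.05)
      if (r >= 1 && r <= length(tf_times)) {
        oracle[r, ] <- oracle[r, ] + basis$matrix[j, ]
      }
    }
  }
  expect_equal(unname(des$matrix), oracle, tolerance = 1e-12)
})

test_that("events outside the TF span are dropped with a warning", {
  basis <- fourier_basis(order = 2)
  tf_times <- seq(10, 20, by = 0.05)
  expect_warning(
    des <- build_design(data.frame(onset = c(15, 40), type = "A"),
                        basis, tf_times),
    "dropped")
  expect_equal(des$dropped, 1L)
})

test_that("modulator columns are mean-centered impulse weights", {
  basis <- fourier_basis(order = 1)
  tf_times <- seq(0, 40, by = 0.05)
  ev <- data.frame(onset = c(5, 15, 25), type = "go")
  des <- build_design(ev, basis, tf_times,
                      modulators = list(drift = list(event_type = "go",
                                                     values = c(1, 2, 3))))
  mod_cols <- des$matrix[, des$columns$regressor == "go:drift"]
  plain_cols <- des$matrix[, des$columns$regressor == "go"]
  # centered weights (-1, 0, 1): the middle event vanishes
  i2 <- round(15 / 0.05) + 1 + round(basis$tau / 0.05)
  expect_true(all(mod_cols[i2, ] == 0))
  expect_equal(colSums(mod_cols != 0), colSums(plain_cols != 0) * 2 / 3,
               tolerance = 0.2, ignore_attr = TRUE)
})

test_that("the sub-cutoff projector removes drift and passes the band", {
  n <- 400
  t <- (1:n) * 0.05
  expect_lt(max(abs(highpass_below(rep(7, n)))), 1e-10)
  one_hz <- sin(2 * pi * 1 * t)
  expect_equal(stats::sd(highpass_below(one_hz)) / stats::sd(one_hz), 1,
               tolerance = 0.05)
  slow <- sin(2 * pi * 0.1 * t)
  atten <- stats::sd(highpass_below(slow)) / stats::sd(slow)
  expect_lt(20 * log10(1 / atten), Inf)
  expect_lt(atten, 0.1) # >= 20 dB attenuation
  expect_warning(highpass_below(rep(1, 20)), "skipped")
})

test_that("noiseless OLS recovers coefficients and flags rank deficiency", {
  basis <- fourier_basis(order = 4)
  tf_times <- seq(0, 120, by = 0.05)
  set.seed(11)
  on_a <- sort(stats::runif(40, 2, 118))
  follow <- stats::runif(40) < 0.6
  ev <- rbind(data.frame(onset = on_a, type = "A"),
              data.frame(onset = c(on_a[follow] + 0.3,
                                   stats::runif(10, 2, 118)), type = "B"))
  des <- build_design(ev, basis, tf_times)
  beta <- matrix(stats::rnorm(ncol(des$matrix) * 3), ncol = 3)
  y <- t(des$matrix %*% beta) # 3 "frequencies"
  fit <- fit_tf_glm(y, des, highpass = FALSE)
  expect_lt(max(abs(fit$coefficients - beta)), 1e-8)
  expect_equal(fit$rank, ncol(des$matrix))
  # duplicated column: warning plus a minimum-norm solution
  dup <- cbind(des$matrix, des$matrix[, 1])
  expect_warning(fit2 <- fit_tf_glm(y, dup, highpass = FALSE),
                 "rank-deficient")
  expect_equal(unname(dup %*% fit2$coefficients), unname(t(y)),
               tolerance = 1e-6)
})

test_that("coefficient error grows linearly with the noise scale", {
  basis <- fourier_basis(order = 3)
  tf_times <- seq(0, 100, by = 0.05)
  set.seed(12)
  ev <- data.frame(onset = sort(stats::runif(40, 2, 98)), type = "A")
  des <- build_design(ev, basis, tf_times)
  beta <- stats::rnorm(ncol(des$matrix))
  clean <- des$matrix %*% beta
  err <- vapply(c(0.1, 0.4), function(s) {
    e <- replicate(8, {
      y <- clean + stats::rnorm(length(clean), 0, s)
      fit <- fit_tf_glm(matrix(y, nrow = 1), des, highpass = FALSE)
      sqrt(sum((fit$coefficients - beta)^2))
    })
    mean(e)
  }, numeric(1))
  expect_equal(err[2] / err[1], 4, tolerance = 0.4)
})

test_that("reconstruction equals triggered averaging for isolated events", {
  basis <- fourier_basis(order = 6)
  tf_times <- seq(0, 200, by = 0.05)
  set.seed(13)
  onsets <- seq(5, 195, by = 4) + stats::runif(48, 0, 0.4)
  des <- build_design(data.frame(onset = onsets, type = "A"),
                      basis, tf_times)
  beta <- matrix(stats::rnorm(ncol(des$matrix) * 2), ncol = 2)
  y <- t(des$matrix %*% beta)
  fit <- fit_tf_glm(y, des, highpass = FALSE)
  rec <- reconstruct_induced(fit, "A")
  ta <- triggered_average_tf(as_tf_image(y, tf_times, 1:2), onsets,
                             baseline = FALSE)
  rel <- sqrt(mean((rec$values - ta$values)^2)) /
    sqrt(mean(ta$values^2))
  expect_lt(rel, 0.02)
  # all-zero coefficients give an all-zero response
  fit0 <- fit
  fit0$coefficients[] <- 0
  expect_true(all(reconstruct_induced(fit0, "A")$values == 0))
  expect_error(reconstruct_induced(fit, "nope"), "unknown")
})

test_that("fitted coefficients are additive over summed datasets", {
  basis <- fourier_basis(order = 3)
  tf_times <- seq(0, 60, by = 0.05)
  set.seed(14)
  des <- build_design(data.frame(onset = sort(stats::runif(25, 2, 58)),
                                 type = "A"), basis, tf_times)
  b1 <- stats::rnorm(ncol(des$matrix)); b2 <- stats::rnorm(ncol(des$matrix))
  f1 <- fit_tf_glm(matrix(des$matrix %*% b1, nrow = 1), des, highpass = FALSE)
  f2 <- fit_tf_glm(matrix(des$matrix %*% b2, nrow = 1), des, highpass = FALSE)
  f12 <- fit_tf_glm(matrix(des$matrix %*% (b1 + b2), nrow = 1), des,
                    highpass = FALSE)
  expect_equal(f12$coefficients, f1$coefficients + f2$coefficients,
               tolerance = 1e-8)
})
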