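test_that("Gaussian smoothing is linear, mass-preserving and peak-centered", {
  m <- matrix(0, 200, 3) # time x units
  expect_true(all(smooth_rates(m, 10, dt_ms = 5) == 0))

  m[100, 2] <- 1 # single spike
  sm <- smooth_rates(m, 10, dt_ms = 5)
  expect_equal(which.max(sm[, 2]), 100)
  expect_equal(sum(sm[, 2]), 1, tolerance = 1e-6) # unit mass away from edges
  expect_true(all(sm[, c(1, 3)] == 0))

  # integral conserved within 1% for interior mass
  set.seed(1)
  m2 <- matrix(runif(200 * 2), 200, 2)
  sm2 <- smooth_rates(m2, 15, dt_ms = 5)
  expect_lt(abs(sum(sm2[20:180, 1]) - sum(m2[20:180, 1])) / sum(m2[20:180, 1]),
            0.01)

  # tensor input keeps shape and labels
  tens <- make_random_tensor(n_bins = 40)
  st <- smooth_rates(tens, 10, dt_ms = 50)
  expect_s3_class(st, "trajectory_tensor")
  expect_identical(st$labels, tens$labels)
})

test_that("binning averages within bins and is the identity at bin = dt", {
  tens <- make_random_tensor(n_bins = 12)
  tens$values[] <- 2.5
  b <- bin_rates(tens, 100) # dt here is 50 ms
  expect_true(all(b$values == 2.5))
  expect_equal(length(b$time_s), 6)

  # ramp 0..1 across one bin averages to the analytic mean of the samples
  tens2 <- make_random_tensor(n_per_cell = 1, n_units = 1, n_bins = 10)
  tens2$values[1, 1, ] <- seq(0, 1, length.out = 10)
  b2 <- bin_rates(tens2, 500)
  expect_equal(b2$values[1, 1, 1], mean(seq(0, 1, length.out = 10)))

  ident <- bin_rates(tens, 50)
  expect_equal(ident$values, tens$values)
  expect_error(bin_rates(tens, 75), "multiple")
})

test_that("decoding separates separable classes and not shuffled ones", {
  tens <- make_separable_tensor(n_per_class = 12, n_units = 8, n_bins = 3,
                                sep = 10)
  curve <- decode_sample(tens, seed = 2)
  expect_s3_class(curve, "decoding_curve")
  expect_equal(attr(curve, "chance"), 1 / 8)
  expect_true(all(curve$accuracy > 0.95))

  # label permutation oracle: chance within 3 SE at every bin
  shuf <- tens
  set.seed(3)
  shuf$labels$sample_id <- sample(shuf$labels$sample_id)
  curve_s <- decode_sample(shuf, seed = 2)
  n_test <- nrow(shuf$labels)
  se <- sqrt(0.125 * 0.875 / n_test)
  expect_true(all(abs(curve_s$accuracy - 0.125) < 3 * se + 0.05))

  # class below the fold count is named in the error
  small <- subset_tensor(tens, trials = c(1:4, 13:96))
  expect_error(decode_sample(small), "class 0")
})

test_that("unit subsampling restricts the feature set deterministically", {
  tens <- make_separable_tensor(n_per_class = 10, n_units = 20, n_bins = 2)
  c1 <- decode_sample(tens, subsample_frac = 0.25, seed = 9)
  c2 <- decode_sample(tens, subsample_frac = 0.25, seed = 9)
  expect_identical(c1$accuracy, c2$accuracy)
  expect_true(all(c1$accuracy > 0.6)) # still far above chance at 5 units
})

test_that("change-from-baseline decoding flags sustained departures only", {
  set.seed(4)
  n <- 40; nu <- 6; nb <- 16
  labels <- data.frame(sample_id = rep(0:1, each = n / 2),
                       distractor = FALSE, delay_s = 1, session = 1L)
  time_s <- seq(-0.375, by = 0.05, length.out = nb)  # spans t > 0
  # stationary tensor: nothing to detect
  vals <- array(rnorm(n * nu * nb), c(n, nu, nb))
  flat <- decode_vs_baseline(trajectory_tensor(vals, time_s, labels),
                             seed = 5)
  expect_equal(attr(flat, "chance"), 0.5)
  expect_lt(mean(flat$accuracy[time_s > 0]), 0.68)

  # strong sustained offset after t = 0
  vals2 <- vals
  vals2[, , time_s > 0] <- vals2[, , time_s > 0] + 6
  hot <- decode_vs_baseline(trajectory_tensor(vals2, time_s, labels),
                            seed = 5)
  expect_true(all(hot$accuracy[time_s > 0.05] > 0.95))
  expect_error(
    decode_vs_baseline(trajectory_tensor(vals, time_s + 10, labels)),
    "outside")
})

test_that("stimulus distance matches a brute-force pair loop", {
  # hand case: S = 2, one unit, constant trajectories at 0 and 3
  labels <- data.frame(sample_id = rep(0:1, each = 2), distractor = FALSE,
                       delay_s = 1, session = 1L)
  vals <- array(0, c(4, 1, 3))
  vals[3:4, 1, ] <- 3
  tens <- trajectory_tensor(vals, c(0.1, 0.2, 0.3), labels)
  expect_equal(stim_distance(tens)$distance, rep(3, 3))

  # identical class means -> zero
  vals0 <- array(1, c(4, 1, 3))
  expect_equal(stim_distance(trajectory_tensor(vals0, c(.1, .2, .3),
                                               labels))$distance,
               rep(0, 3))

  # random tensor vs independent double loop over pairs
  tens <- make_random_tensor(n_per_cell = 4, n_classes = 5, n_units = 5,
                             n_bins = 6, seed = 8)
  got <- stim_distance(tens)$distance
  keep <- !tens$labels$distractor
  S <- 5
  want <- numeric(6)
  for (tt in 1:6) {
    acc <- 0
    for (i in 0:(S - 2)) for (j in (i + 1):(S - 1)) {
      mi <- colMeans(tens$values[keep & tens$labels$sample_id == i, , tt,
                                 drop = FALSE][, , 1, drop = TRUE])
      mj <- colMeans(tens$values[keep & tens$labels$sample_id == j, , tt,
                                 drop = FALSE][, , 1, drop = TRUE])
      acc <- acc + sqrt(sum((mi - mj)^2))
    }
    want[tt] <- 2 / (S * (S - 1)) * acc
  }
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("distractor distance matches its brute-force oracle", {
  # single-unit hand example with means 1 and 4
  labels <- data.frame(sample_id = 0L, distractor = rep(c(FALSE, TRUE), 2),
                       delay_s = 1, session = 1L)
  vals <- array(0, c(4, 1, 2))
  vals[labels$distractor, 1, ] <- 4
  vals[!labels$distractor, 1, ] <- 1
  tens <- trajectory_tensor(vals, c(0.1, 0.2), labels)
  expect_equal(distractor_distance(tens)$distance, rep(3, 2))

  tens <- make_random_tensor(n_per_cell = 3, n_classes = 4, seed = 10)
  got <- distractor_distance(tens)$distance
  want <- numeric(length(tens$time_s))
  for (tt in seq_along(tens$time_s)) {
    acc <- 0
    for (s in 0:3) {
      m1 <- colMeans(tens$values[tens$labels$sample_id == s &
                                   tens$labels$distractor, , tt,
                                 drop = FALSE][, , 1, drop = TRUE])
      m0 <- colMeans(tens$values[tens$labels$sample_id == s &
                                   !tens$labels$distractor, , tt,
                                 drop = FALSE][, , 1, drop = TRUE])
      acc <- acc + sqrt(sum((m1 - m0)^2))
    }
    want[tt] <- acc / 4
  }
  expect_equal(got, want, tolerance = 1e-12)

  missing <- subset_tensor(tens, trials = which(!(tens$labels$sample_id == 2 &
                                                    tens$labels$distractor)))
  expect_error(distractor_distance(missing), "sample 2")
})

test_that("normalization sets the pre-stimulus mean to one", {
  tens <- make_random_tensor(n_bins = 8, seed = 11) # time starts at -0.1
  d <- stim_distance(tens, normalize = TRUE)
  pre <- tens$time_s < 0
  expect_equal(mean(d$distance[pre]), 1, tolerance = 1e-12)
  expect_true(all(d$distance >= 0))
})

test_that("the multi-level bootstrap is deterministic and degenerates
           correctly", {
  sessions <- lapply(1:4, function(s) matrix(5, 10, 1)) # zero variance
  stat <- function(ss) mean(vapply(ss, mean, numeric(1)))
  ci <- bootstrap_ci(sessions, stat, B = 200, seed = 1)
  expect_equal(ci$lower, 5)
  expect_equal(ci$upper, 5)

  set.seed(2)
  sessions <- lapply(1:5, function(s) matrix(rnorm(30, mean = s), 30, 1))
  c1 <- bootstrap_ci(sessions, stat, B = 300, seed = 7)
  c2 <- bootstrap_ci(sessions, stat, B = 300, seed = 7)
  expect_identical(c1$lower, c2$lower)
  expect_true(c1$lower <= stat(sessions) && stat(sessions) <= c1$upper)
  expect_warning(bootstrap_ci(sessions, stat, B = 50, seed = 1), "small")
  expect_error(bootstrap_ci(sessions[1], stat), "length")
})

test_that("exponential recovery fitting recovers known time constants", {
  t <- seq(0, 1.5, by = 0.02)
  # additive truth, additive model: exact recovery
  curve <- data.frame(time = t, distance = 2 * exp(-t / 0.2) + 0.3)
  fit <- fit_recovery_timeconstant(curve, window = c(0, 1.5),
                                   model = "additive")
  expect_equal(fit$tau_s, 0.2, tolerance = 1e-3)
  expect_gt(fit$r_squared, 0.999)

  # quadrature-floor truth (a noisy distance curve), default model: exact
  qcurve <- data.frame(time = t,
                       distance = sqrt((2 * exp(-t / 0.2))^2 + 0.3^2))
  qfit <- fit_recovery_timeconstant(qcurve, window = c(0, 1.5))
  expect_equal(qfit$tau_s, 0.2, tolerance = 1e-3)

  # 5% additive noise: recovered within 15% across seeds
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    noisy <- curve
    noisy$distance <- noisy$distance + rnorm(length(t), 0, 0.05 * 2)
    fit_recovery_timeconstant(noisy, c(0, 1.5), model = "additive")$tau_s
  }, numeric(1))
  expect_lt(median(abs(errs - 0.2) / 0.2), 0.15)
  expect_gt(mean(abs(errs - 0.2) / 0.2 < 0.15), 0.8)
})
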