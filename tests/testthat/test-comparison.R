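mk_curve <- function(time, acc) {
  structure(data.frame(time = time, accuracy = acc, se = 0),
            class = c("decoding_curve", "data.frame"))
}

test_that("brain similarity is a per-delay Pearson mean with the expected
           invariances", {
  t <- c(0, 1, 2, 3)
  a <- mk_curve(t, c(0.2, 0.9, 0.6, 0.3))
  b <- mk_curve(t, c(0.3, 0.8, 0.5, 0.2))
  self <- brain_similarity(list(`1` = a, `2` = a), list(`1` = a, `2` = a))
  expect_equal(self$score, 1)

  neg <- mk_curve(t, mean(a$accuracy) - (a$accuracy - mean(a$accuracy)))
  expect_equal(brain_similarity(list(`1` = a), list(`1` = neg))$score, -1)

  # hand Pearson on the 4-point curves
  hand <- cor(a$accuracy, b$accuracy)
  expect_equal(brain_similarity(list(`1` = a), list(`1` = b))$score, hand)

  # symmetry and affine invariance
  s1 <- brain_similarity(list(`1` = a), list(`1` = b))$score
  s2 <- brain_similarity(list(`1` = b), list(`1` = a))$score
  expect_equal(s1, s2, tolerance = 1e-12)
  a_aff <- mk_curve(t, 3 * a$accuracy + 0.1)
  expect_equal(brain_similarity(list(`1` = a_aff), list(`1` = b))$score, s1,
               tolerance = 1e-12)

  # model curve on a different grid is interpolated onto the reference
  a_fine <- mk_curve(seq(0, 3, by = 0.5), approx(t, a$accuracy,
                                                 seq(0, 3, by = 0.5))$y)
  expect_equal(brain_similarity(list(`1` = a_fine), list(`1` = b))$score,
               s1, tolerance = 1e-12)

  flat <- mk_curve(t, rep(0.125, 4))
  expect_warning(out <- brain_similarity(list(`1` = flat, `2` = a),
                                         list(`1` = b, `2` = b)),
                 "constant")
  expect_true(is.na(out$per_delay[["1"]]))
  expect_equal(out$score, cor(a$accuracy, b$accuracy))
})

test_that("synaptic ablation zeroes the stated count and nothing else", {
  m <- init_model("fs-tanh", 20, seed = 1)
  m0 <- ablate_synapses(m, 0, seed = 2)
  expect_identical(m0$params$W, m$params$W)

  m5 <- ablate_synapses(m, 0.5, seed = 2)
  expect_equal(sum(m5$params$W == 0), floor(0.5 * 400))
  expect_identical(m5$params$W_in, m$params$W_in)

  m1 <- ablate_synapses(m, 1, seed = 2)
  expect_true(all(m1$params$W == 0))
  # with all recurrent weights gone the recurrent drive is exactly zero:
  # trajectories equal the input-driven leaky response
  cfg <- quick_cfg()
  tr <- make_trial(cfg, 0, 1.0, NULL, rng_seed = 1)
  rec <- run_trials(m1, list(tr), noise = FALSE)
  drive_only <- m1
  drive_only$params$W <- matrix(0, 20, 20)
  rec2 <- run_trials(drive_only, list(tr), noise = FALSE)
  expect_identical(rec$rates$values, rec2$rates$values)

  # ps-hebb ablation masks the gain matrix so synapses stay dead
  mh <- init_model("ps-hebb", 6, seed = 3)
  mh1 <- ablate_synapses(mh, 1, seed = 4)
  recw <- run_trials(mh1, list(tr), synaptic = TRUE, noise = FALSE)
  expect_true(all(recw$synaptic$values == 0))
})

test_that("robustness scores implement the noise-weighted mean", {
  expect_equal(stspwm:::robustness_score(c(0.2, 0.4), c(1, 0.5)),
               (0.2 * 1 + 0.4 * 0.5) / 0.6)
  expect_equal(stspwm:::robustness_score(c(0, 0.3, 0.6), c(1, 1, 1)), 1)
  expect_equal(stspwm:::robustness_score(c(0, 0.3, 0.6), c(1, 0, 0)), 0)
  # monotone under pointwise improvement
  s1 <- stspwm:::robustness_score(c(0.1, 0.2), c(0.4, 0.3))
  s2 <- stspwm:::robustness_score(c(0.1, 0.2), c(0.5, 0.35))
  expect_gt(s2, s1)
})

test_that("robustness profiles run end-to-end on a small model", {
  cfg <- quick_cfg()
  trials <- make_dataset(cfg, 48, rng_seed = 3)
  m <- init_model("fs-tanh", 10, seed = 4)
  sr <- structural_robustness(m, trials, fractions = c(0, 0.5), n_seeds = 2,
                              seed = 5)
  expect_s3_class(sr, "robustness_profile")
  expect_true(all(sr$profile$performance >= 0 &
                    sr$profile$performance <= 1))
  expect_true(sr$score >= 0 && sr$score <= 1)

  pr <- process_noise_robustness(m, trials, sigmas = c(0.05, 0.2), seed = 5)
  expect_equal(pr$profile$noise, c(0.05, 0.2))
  expect_true(pr$score >= 0 && pr$score <= 1)
  expect_error(structural_robustness(m, trials, fractions = c(0.1, 0.5)))
})

test_that("LDA projection separates separable classes in three dimensions", {
  tens <- make_separable_tensor(n_per_class = 15, n_units = 12, n_bins = 4,
                                sep = 10, time_s = c(0.1, 0.2, 0.3, 0.4))
  proj <- lda_project(tens, epochs = list(sample = c(0, 0.5)))
  expect_equal(ncol(proj$sample$points), 3)
  expect_gt(mean_silhouette(proj$sample$points,
                            as.integer(proj$sample$labels)), 0.8)

  # identical class distributions: near-zero separation
  null_tens <- tens
  set.seed(6)
  null_tens$values <- array(rnorm(length(tens$values)), dim(tens$values))
  pn <- lda_project(null_tens, epochs = list(sample = c(0, 0.5)))
  expect_lt(mean_silhouette(pn$sample$points,
                            as.integer(pn$sample$labels)), 0.3)
  expect_error(lda_project(subset_tensor(
    tens, trials = which(tens$labels$sample_id < 3))), "4 classes")
})

test_that("orthogonal Procrustes recovers known rotations exactly", {
  set.seed(7)
  A <- matrix(rnorm(60), 20, 3)
  out <- procrustes_align(A, A)
  expect_lt(out$residual, 1e-10)

  # known 3D rotation
  th <- 0.7
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  B <- A %*% Rz
  out <- procrustes_align(A, B)
  expect_lt(max(abs(out$rotation - t(Rz))), 1e-8)
  expect_lt(out$residual, 1e-8)
  expect_lt(max(abs(crossprod(out$rotation) - diag(3))), 1e-10)

  expect_warning(z <- procrustes_align(matrix(0, 5, 3), matrix(0, 5, 3)),
                 "degenerate")
  expect_equal(z$rotation, diag(3))
})

test_that("the sweep driver fills a small grid and resumes from disk", {
  cfg <- quick_cfg()
  train_trials <- make_dataset(cfg, 48, rng_seed = 8)
  test_trials <- make_dataset(cfg, 32, rng_seed = 9)
  grid <- data.frame(kind = "fs-tanh", hidden = 8, activity_reg = 1e-3,
                     weight_decay = 1e-4)
  out_csv <- tempfile(fileext = ".csv")
  tab <- sweep_models(grid, train_trials, test_trials, out_csv = out_csv,
                      max_epochs = 1, seed = 10,
                      robustness_fractions = c(0, 0.5),
                      robustness_sigmas = c(0.05, 0.1))
  expect_equal(nrow(tab), 1)
  expect_false(tab$failed)
  expect_true(all(c("accuracy", "structural_robustness",
                    "process_robustness") %in% names(tab)))
  # resume path: cached row is reused, not retrained
  t0 <- Sys.time()
  tab2 <- sweep_models(grid, train_trials, test_trials, out_csv = out_csv,
                       max_epochs = 1, seed = 10,
                       robustness_fractions = c(0, 0.5),
                       robustness_sigmas = c(0.05, 0.1))
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
  expect_equal(tab2$accuracy, tab$accuracy)
  unlink(out_csv)
})

test_that("best-per-cell reduction and the PS-hebb size convention", {
  expect_equal(pshebb_hidden_sizes(c(100, 1000)), c(10L, 100L))
  tab <- data.frame(kind = c("a", "b", "a", "b"),
                    hidden = c(10, 10, 20, 20),
                    activity_reg = 1e-3, weight_decay = 1e-4,
                    brain_similarity = c(0.2, 0.5, 0.9, 0.1),
                    failed = FALSE)
  best <- best_per_cell(tab)
  expect_equal(best$best_kind, c("b", "a"))
})
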