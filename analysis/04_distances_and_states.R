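#!/usr/bin/env Rscript
# Neural and synaptic state-space structure of the trained networks:
# stimulus-pair and distractor trajectory distances, distractor recovery
# constants, and the 3D LDA projection of sample vs late-delay activity
# with orthogonal Procrustes alignment between the two epochs.
#
# Requires: results/models/*.rds
# Writes: results/model_distances.csv, results/model_recovery.csv,
#         results/lda_projection.csv

library(stspwm)
stopifnot(dir.exists("results/models"))

cfg <- task_config(delay_set_s = c(1.0, 1.41))
test_set <- make_dataset(cfg, 1024, rng_seed = 12)
labs <- dataset_labels(test_set)
idx <- which(abs(labs$delay_s - 1.41) < 1e-9)[1:256]

dist_rows <- list()
rec_rows <- list()
lda_rows <- list()
for (f in list.files("results/models", full.names = TRUE)) {
  m <- readRDS(f)
  kind <- m$kind
  noise <- isTRUE(m$train_cfg$train_noise)
  rec <- run_trials(m, test_set[idx],
                    synaptic = kind %in% c("ps-pre", "ps-hebb"),
                    noise = noise, seed = 31)

  for (feature in c("rates", "synaptic")) {
    tens <- if (feature == "rates") rec$rates else rec$synaptic
    if (is.null(tens)) next
    ds <- stim_distance(tens)
    dd <- distractor_distance(tens)
    dist_rows[[length(dist_rows) + 1]] <-
      data.frame(kind = kind, feature = feature, time = ds$time,
                 stim = ds$distance, distractor = dd$distance)
    # recovery constant from distractor offset (1.41 s delay, centered)
    t_off <- 0.5 + (1.41 - 0.25) / 2 + 0.25
    fit <- tryCatch(
      fit_recovery_timeconstant(dd, window = c(t_off, t_off + 0.55)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rec_rows[[length(rec_rows) + 1]] <-
        data.frame(kind = kind, feature = feature, tau_s = fit$tau_s,
                   r_squared = fit$r_squared)
    }
  }

  # LDA state-space projection: sample epoch vs last 500 ms of the delay,
  # rotationally aligned with orthogonal Procrustes on the class centroids
  proj <- lda_project(rec$rates,
                      epochs = list(sample = c(0, 0.5),
                                    late_delay = c(1.41, 1.91)))
  cents <- lapply(proj, function(p) {
    t(vapply(levels(p$labels), function(cl) {
      colMeans(p$points[p$labels == cl, , drop = FALSE])
    }, numeric(3)))
  })
  al <- procrustes_align(cents$sample, cents$late_delay)
  for (ep in names(proj)) {
    pts <- if (ep == "late_delay") {
      sweep(proj[[ep]]$points, 2, colMeans(proj[[ep]]$points)) %*% al$rotation
    } else {
      sweep(proj[[ep]]$points, 2, colMeans(proj[[ep]]$points))
    }
    lda_rows[[length(lda_rows) + 1]] <-
      data.frame(kind = kind, epoch = ep,
                 sample_id = as.integer(as.character(proj[[ep]]$labels)),
                 x = pts[, 1], y = pts[, 2], z = pts[, 3])
  }
  message(kind, ": distances + projection done")
}
write.csv(do.call(rbind, dist_rows), "results/model_distances.csv",
          row.names = FALSE)
write.csv(do.call(rbind, rec_rows), "results/model_recovery.csv",
          row.names = FALSE)
write.csv(do.call(rbind, lda_rows), "results/lda_projection.csv",
          row.names = FALSE)
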