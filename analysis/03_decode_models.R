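#!/usr/bin/env Rscript
# Time-resolved decoding of sample identity from the trained networks'
# rates and, for the plastic models, from their synaptic state — the
# model-side counterpart of the recording analysis. Also computes the
# brain-similarity of each model against a surrogate reference.
#
# Requires: results/models/*.rds (from 02_train_models.R)
# Writes: results/model_decoding.csv, results/brain_similarity.csv

library(stspwm)
stopifnot(dir.exists("results/models"))

cfg <- task_config(delay_set_s = c(1.0, 1.41))
test_set <- make_dataset(cfg, 1024, rng_seed = 12)
labs <- dataset_labels(test_set)

ref_cfg <- surrogate_config(n_sessions = 3, n_units = 48,
                            trials_per_condition = 8)
refs <- make_reference_curves(ref_cfg, delays = c(1.0, 1.41), bin_ms = 90,
                              seed = 7)

rows <- list()
sims <- list()
for (f in list.files("results/models", full.names = TRUE)) {
  m <- readRDS(f)
  kind <- m$kind
  noise <- isTRUE(m$train_cfg$train_noise)
  mcurves <- list()
  for (d in c(1.0, 1.41)) {
    idx <- which(abs(labs$delay_s - d) < 1e-9)[1:224]
    rec <- run_trials(m, test_set[idx],
                      synaptic = kind %in% c("ps-pre", "ps-hebb"),
                      noise = noise, seed = 21)
    binned <- bin_rates(rec$rates, 45)
    bins <- seq(1, length(binned$time_s), by = 3)
    cr <- decode_sample(binned, seed = 22, bins = bins)
    cr$kind <- kind; cr$delay <- d; cr$feature <- "rates"
    rows[[length(rows) + 1]] <- cr
    mcurves[[as.character(d)]] <- cr
    if (!is.null(rec$synaptic)) {
      cs <- decode_sample(bin_rates(rec$synaptic, 45), seed = 22, scale = TRUE,
                          bins = bins)
      cs$kind <- kind; cs$delay <- d; cs$feature <- "synaptic"
      rows[[length(rows) + 1]] <- cs
    }
  }
  sim <- brain_similarity(mcurves, refs)
  sims[[kind]] <- data.frame(kind = kind, similarity = sim$score)
  message(sprintf("%s: brain-similarity %.3f", kind, sim$score))
}
write.csv(do.call(rbind, rows), "results/model_decoding.csv",
          row.names = FALSE)
write.csv(do.call(rbind, sims), "results/brain_similarity.csv",
          row.names = FALSE)
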