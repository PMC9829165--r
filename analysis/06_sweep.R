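#!/usr/bin/env Rscript
# Reduced hyperparameter sweep: a small grid over model kinds, hidden
# sizes and activity regularization, scoring accuracy, robustness and
# brain-similarity per cell, then the winning kind per cell. The published
# study swept ~2000 models; this driver demonstrates the machinery at desk
# scale and is resumable (delete results/sweep.csv to restart).
#
# Writes: results/sweep.csv, results/sweep_best.csv

library(stspwm)
dir.create("results", showWarnings = FALSE)

cfg <- task_config(delay_set_s = c(1.0))
train_trials <- make_dataset(cfg, 1024, rng_seed = 21)
test_trials <- make_dataset(cfg, 512, rng_seed = 22)

ref_cfg <- surrogate_config(n_sessions = 2, n_units = 32,
                            trials_per_condition = 6)
refs <- make_reference_curves(ref_cfg, delays = 1.0, bin_ms = 90, seed = 23)

fs_sizes <- c(50, 100)
grid <- rbind(
  expand.grid(kind = c("fs-tanh", "ps-pre"), hidden = fs_sizes,
              activity_reg = c(1e-3, 1.29e-2), weight_decay = 1e-4,
              stringsAsFactors = FALSE),
  expand.grid(kind = "ps-hebb", hidden = pshebb_hidden_sizes(fs_sizes),
              activity_reg = c(1e-3, 1.29e-2), weight_decay = 1e-4,
              stringsAsFactors = FALSE))

tab <- sweep_models(grid, train_trials, test_trials,
                    reference_curves = refs, decode_bin_ms = 90,
                    out_csv = "results/sweep.csv", max_epochs = 15,
                    seed = 24)
print(tab[, c("kind", "hidden", "activity_reg", "accuracy",
              "structural_robustness", "brain_similarity")])
best <- best_per_cell(tab, metric = "brain_similarity")
write.csv(best, "results/sweep_best.csv", row.names = FALSE)
message("most brain-like kind per cell:")
print(best)
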