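#!/usr/bin/env Rscript
# Trains the four-network cohort (fixed-synapse tanh/relu, presynaptic
# plasticity, anti-Hebbian plasticity) on the reduced task and saves
# checkpoints + learning histories.
#
# Writes: results/models/<kind>.rds, results/training_history.csv

library(stspwm)
dir.create("results/models", recursive = TRUE, showWarnings = FALSE)

cfg <- task_config(delay_set_s = c(1.0, 1.41))
train_set <- make_dataset(cfg, 4096, rng_seed = 11)
test_set <- make_dataset(cfg, 1024, rng_seed = 12)
dev <- test_set[769:1024]

budgets <- c(`fs-tanh` = 300, `fs-relu` = 300, `ps-pre` = 700,
             `ps-hebb` = 400) # wall-clock caps, seconds
hist_all <- list()
for (kind in names(budgets)) {
  n <- if (kind == "ps-hebb") 10L else 100L
  m <- init_model(kind, n, seed = 1)
  tc <- train_config(kind, max_epochs = 2000, eval_every = 5,
                     max_seconds = budgets[[kind]], seed = 1)
  m <- train(m, train_set, tc, dev_trials = dev, verbose = TRUE)
  ev <- evaluate_accuracy(m, test_set[1:768], noise = tc$train_noise,
                          seed = 99)
  message(sprintf("%s: acc %.3f (dis %.3f / no-dis %.3f) after %d epochs",
                  kind, ev$accuracy, ev$by_distractor["distractor"],
                  ev$by_distractor["no_distractor"], nrow(m$history)))
  saveRDS(m, file.path("results/models", paste0(kind, ".rds")))
  h <- m$history
  h$kind <- kind
  hist_all[[kind]] <- h
}
write.csv(do.call(rbind, hist_all), "results/training_history.csv",
          row.names = FALSE)
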