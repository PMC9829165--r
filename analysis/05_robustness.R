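#!/usr/bin/env Rscript
# Structural (synaptic-ablation) and process-noise robustness profiles of
# the trained cohort, each reduced to the noise-weighted score.
#
# Requires: results/models/*.rds
# Writes: results/robustness_profiles.csv, results/robustness_scores.csv

library(stspwm)
stopifnot(dir.exists("results/models"))

cfg <- task_config(delay_set_s = c(1.0, 1.41))
eval_set <- make_dataset(cfg, 512, rng_seed = 13)

prof_rows <- list()
score_rows <- list()
for (f in list.files("results/models", full.names = TRUE)) {
  m <- readRDS(f)
  sr <- structural_robustness(m, eval_set,
                              fractions = c(0, 0.1, 0.25, 0.5, 0.75),
                              n_seeds = 3, seed = 41)
  pr <- process_noise_robustness(m, eval_set,
                                 sigmas = c(0.05, 0.1, 0.2, 0.4), seed = 42)
  prof_rows[[length(prof_rows) + 1]] <-
    rbind(data.frame(kind = m$kind, type = "structural", sr$profile),
          data.frame(kind = m$kind, type = "process", pr$profile))
  score_rows[[length(score_rows) + 1]] <-
    data.frame(kind = m$kind, structural = sr$score, process = pr$score)
  message(sprintf("%s: structural %.3f, process %.3f", m$kind, sr$score,
                  pr$score))
}
write.csv(do.call(rbind, prof_rows), "results/robustness_profiles.csv",
          row.names = FALSE)
write.csv(do.call(rbind, score_rows), "results/robustness_scores.csv",
          row.names = FALSE)
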