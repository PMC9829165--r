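# Lazily trained, memoized model cohort shared across test files (training
# is by far the most expensive step, so each configuration is trained at
# most once per test run). Budgets are wall-clock caps; the reduced task
# uses the two shortest delays.

.cohort <- new.env(parent = emptyenv())

cohort_task_cfg <- function() task_config(delay_set_s = c(1.0, 1.41))

cohort_data <- function() {
  if (is.null(.cohort$data)) {
    cfg <- cohort_task_cfg()
    .cohort$data <- list(
      train = make_dataset(cfg, 4096, rng_seed = 11),
      test = make_dataset(cfg, 1024, rng_seed = 12)
    )
  }
  .cohort$data
}

cohort_budget_s <- function(kind) {
  switch(kind, `ps-pre` = 420, `ps-hebb` = 300, 180)
}

get_trained_model <- function(kind, seed = 1L) {
  key <- paste0(kind, "_", seed)
  if (!is.null(.cohort[[key]])) return(.cohort[[key]])
  data <- cohort_data()
  n <- if (kind == "ps-hebb") 10L else 100L
  m <- init_model(kind, n, seed = seed)
  cfg <- train_config(kind, max_epochs = 2000, eval_every = 5,
                      max_seconds = cohort_budget_s(kind), seed = seed)
  dev <- data$test[769:1024]
  .cohort[[key]] <- train(m, data$train, cfg, dev_trials = dev)
  .cohort[[key]]
}

# held-out trials never used for early stopping
cohort_eval_trials <- function() cohort_data()$test[1:768]

# evaluate under the model's own training-noise condition
native_eval <- function(model, trials, seed = 99L, ...) {
  noise <- isTRUE(model$train_cfg$train_noise %||% TRUE)
  evaluate_accuracy(model, trials, noise = noise, seed = seed, ...)
}

`%||%` <- stspwm:::`%||%`
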