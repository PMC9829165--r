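#' Task configuration for the distracted delayed-match-to-sample task
#'
#' Builds the timing and dimension constants of the object working-memory
#' task: a fixation period, a sample image, a variable-length memory delay
#' (optionally interrupted by a brief distractor centered on the delay
#' midpoint), a two-alternative test display, and a response-scoring window.
#' Stimuli are one-hot channels; an eleventh channel carries the fixation
#' signal.
#'
#' @param dt_ms Integration step in milliseconds (default 15).
#' @param fixation_ms,sample_ms,distractor_ms,test_ms,response_ms Epoch
#'   durations in milliseconds.
#' @param delay_set_s Candidate delay lengths in seconds, ascending.
#' @param distractor_prob Probability that a trial contains a distractor.
#' @param n_samples,n_distractors Number of sample and distractor images.
#' @return An object of class `wm_task_config`.
#' @export
task_config <- function(dt_ms = 15,
                        fixation_ms = 1000,
                        sample_ms = 500,
                        delay_set_s = c(1.0, 1.41, 2.0, 2.83, 4.0),
                        distractor_ms = 250,
                        distractor_prob = 0.5,
                        test_ms = 500,
                        response_ms = 500,
                        n_samples = 8,
                        n_distractors = 2) {
  stopifnot(dt_ms > 0, fixation_ms > 0, sample_ms > 0, distractor_ms > 0,
            test_ms > 0, response_ms > 0,
            all(delay_set_s > 0), !is.unsorted(delay_set_s),
            distractor_prob >= 0, distractor_prob <= 1,
            n_samples >= 2, n_distractors >= 1)
  cfg <- list(
    dt_ms = dt_ms,
    fixation_ms = fixation_ms,
    sample_ms = sample_ms,
    delay_set_s = delay_set_s,
    distractor_ms = distractor_ms,
    distractor_prob = distractor_prob,
    test_ms = test_ms,
    response_ms = response_ms,
    n_samples = n_samples,
    n_distractors = n_distractors,
    n_inputs = n_samples + n_distractors + 1,
    n_outputs = n_samples + n_distractors + 1
  )
  class(cfg) <- "wm_task_config"
  cfg
}

# ms -> whole steps, nearest-step rounding (durations need not divide dt)
ms_to_steps <- function(ms, dt_ms) as.integer(round(ms / dt_ms))

#' Build one task trial
#'
#' Constructs the input and desired-output time series of a single trial.
#' Input channels are `1..n_samples` sample one-hots, then `n_distractors`
#' distractor one-hots, then the fixation channel. The fixation input stays
#' on from trial start through the end of the test period. During the test
#' period the sample image is shown together with one randomly chosen
#' off-target sample image. The desired output keeps the fixation channel at
#' 1 until test onset; during the response window (the `response_ms` after
#' the test period ends) the correct sample channel must hold 1 and all
#' other channels 0.
#'
#' @param cfg A `wm_task_config`.
#' @param sample_id Integer in `0:(n_samples-1)`.
#' @param delay_s Delay length in seconds; must be one of `cfg$delay_set_s`.
#' @param distractor_id `NULL` for no distractor, else integer in
#'   `0:(n_distractors-1)`. The distractor interval is centered on the delay
#'   midpoint.
#' @param rng_seed Integer seed used to draw the off-target test image.
#' @return An object of class `wm_trial` with elements `inputs` and
#'   `targets` (steps x channels 0/1 matrices), `sample_id`, `distractor_id`,
#'   `delay_s`, `off_target`, `dt_ms` and `epochs` (1-based start/end step
#'   indices of every epoch).
#' @export
make_trial <- function(cfg, sample_id, delay_s, distractor_id = NULL,
                       rng_seed = 1L) {
  stopifnot(inherits(cfg, "wm_task_config"))
  if (!(length(sample_id) == 1 && sample_id %in% 0:(cfg$n_samples - 1))) {
    stop("sample_id must be an integer in [0, ", cfg$n_samples, ")")
  }
  if (!(length(delay_s) == 1 && any(abs(delay_s - cfg$delay_set_s) < 1e-9))) {
    stop("delay_s = ", delay_s, " is not in the configured delay set")
  }
  if (!is.null(distractor_id) && !isTRUE(is.na(distractor_id))) {
    if (!(length(distractor_id) == 1 &&
          distractor_id %in% 0:(cfg$n_distractors - 1))) {
      stop("distractor_id must be NULL or in [0, ", cfg$n_distractors, ")")
    }
  } else {
    distractor_id <- NULL
  }

  dt <- cfg$dt_ms
  n_fix <- ms_to_steps(cfg$fixation_ms, dt)
  n_smp <- ms_to_steps(cfg$sample_ms, dt)
  n_del <- ms_to_steps(delay_s * 1000, dt)
  n_dis <- ms_to_steps(cfg$distractor_ms, dt)
  n_tst <- ms_to_steps(cfg$test_ms, dt)
  n_rsp <- ms_to_steps(cfg$response_ms, dt)
  total <- n_fix + n_smp + n_del + n_tst + n_rsp

  inputs <- matrix(0, total, cfg$n_inputs)
  targets <- matrix(0, total, cfg$n_outputs)
  ch_fix <- cfg$n_inputs # last channel

  fix_start <- 1L
  smp_start <- n_fix + 1L
  del_start <- smp_start + n_smp
  tst_start <- del_start + n_del
  rsp_start <- tst_start + n_tst

  # fixation input on until end of test period
  inputs[fix_start:(rsp_start - 1L), ch_fix] <- 1
  # sample one-hot
  inputs[smp_start:(del_start - 1L), sample_id + 1L] <- 1

  epochs <- list(
    fixation = c(start = fix_start, end = smp_start - 1L),
    sample = c(start = smp_start, end = del_start - 1L),
    delay = c(start = del_start, end = tst_start - 1L),
    test = c(start = tst_start, end = rsp_start - 1L),
    response = c(start = rsp_start, end = total)
  )

  if (!is.null(distractor_id)) {
    # centered on the delay midpoint
    offset <- as.integer(round((delay_s * 1000 - cfg$distractor_ms) / 2 / dt))
    dis_start <- del_start + offset
    dis_end <- dis_start + n_dis - 1L
    inputs[dis_start:dis_end, cfg$n_samples + distractor_id + 1L] <- 1
    epochs$distractor <- c(start = dis_start, end = dis_end)
  }

  # test display: the sample plus one off-target sample image
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(rng_seed)
  off_target <- sample(setdiff(0:(cfg$n_samples - 1), sample_id), 1L)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  inputs[tst_start:(rsp_start - 1L), sample_id + 1L] <- 1
  inputs[tst_start:(rsp_start - 1L), off_target + 1L] <- 1

  # desired output: fixation until test onset, sample channel during response
  targets[fix_start:(tst_start - 1L), ch_fix] <- 1
  targets[rsp_start:total, sample_id + 1L] <- 1

  structure(list(
    inputs = inputs,
    targets = targets,
    sample_id = as.integer(sample_id),
    distractor_id = if (is.null(distractor_id)) NA_integer_ else as.integer(distractor_id),
    delay_s = delay_s,
    off_target = as.integer(off_target),
    dt_ms = dt,
    epochs = epochs,
    n_steps = total
  ), class = "wm_trial")
}

#' Generate a dataset of task trials
#'
#' Sample identity is uniform over the sample images, delay uniform over the
#' configured delay set, and a distractor (uniform over distractor images)
#' appears with probability `cfg$distractor_prob`. Deterministic given the
#' seed.
#'
#' @param cfg A `wm_task_config`.
#' @param n_trials Number of trials (>= 1).
#' @param rng_seed Integer seed.
#' @return A list of `wm_trial` objects.
#' @export
make_dataset <- function(cfg, n_trials, rng_seed = 1L) {
  stopifnot(inherits(cfg, "wm_task_config"), n_trials >= 1)
  set.seed(rng_seed)
  sample_ids <- sample.int(cfg$n_samples, n_trials, replace = TRUE) - 1L
  delays <- sample(cfg$delay_set_s, n_trials, replace = TRUE)
  has_dis <- stats::runif(n_trials) < cfg$distractor_prob
  dis_ids <- sample.int(cfg$n_distractors, n_trials, replace = TRUE) - 1L
  trial_seeds <- sample.int(.Machine$integer.max, n_trials)
  lapply(seq_len(n_trials), function(i) {
    make_trial(cfg, sample_ids[i], delays[i],
               if (has_dis[i]) dis_ids[i] else NULL,
               rng_seed = trial_seeds[i])
  })
}

#' Summarize a dataset's labels as a data frame
#' @param trials List of `wm_trial`.
#' @return data.frame with sample_id, distractor (logical), distractor_id,
#'   delay_s, n_steps per trial.
#' @export
dataset_labels <- function(trials) {
  data.frame(
    sample_id = vapply(trials, `[[`, integer(1), "sample_id"),
    distractor = !vapply(trials, function(t) is.na(t$distractor_id), logical(1)),
    distractor_id = vapply(trials, `[[`, integer(1), "distractor_id"),
    delay_s = vapply(trials, `[[`, numeric(1), "delay_s"),
    n_steps = vapply(trials, `[[`, integer(1), "n_steps")
  )
}
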