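#' Configuration for surrogate multi-session population recordings
#'
#' Parameterizes a generative stand-in for multi-electrode prefrontal
#' recordings during the distracted delayed-match-to-sample task: per-unit
#' baseline rates, a sample-tuned transient whose amplitude decays
#' exponentially through the memory delay, a distractor-evoked common-mode
#' excursion with exponential recovery, trial-level white noise, and a
#' session-level multiplicative gain. Defaults mirror the recorded
#' preparation this emulates: 6 sessions of 256 units, sample information
#' decaying with a ~1 s time constant and distractor recovery with a 0.2 s
#' time constant. All rates are rectified at zero. The default noise and
#' coding scales are set so that, at the default population size, sample
#' identity is near-perfectly decodable during the sample epoch and decays
#' toward chance over the longest delay, while the distractor excursion
#' stands clear of the finite-trial distance floor.
#'
#' @param n_sessions Number of sessions (>= 2 for the bootstrap).
#' @param n_units Units per session.
#' @param trials_per_condition Trials per (sample x distractor) condition.
#' @param dt_ms Sampling step of the generated rate traces (ms).
#' @param baseline_range Per-unit baseline rate range (uniform draw).
#' @param coding_strength SD of the per-unit sample-tuning weights.
#' @param coding_decay_s Exponential decay time constant of delay-period
#'   sample information (s).
#' @param distractor_amp Norm of the distractor-evoked population
#'   excursion.
#' @param recovery_tau_s Exponential recovery time constant after
#'   distractor offset (s).
#' @param trial_noise_sd SD of the additive unit/time noise.
#' @param session_gain_sd SD of the log-normal session gain.
#' @param delay_s Delay length of the generated trials (s).
#' @param task Task timing template; defaults to [task_config()] at
#'   `dt_ms`.
#' @return List of class `surrogate_config`.
#' @export
surrogate_config <- function(n_sessions = 6, n_units = 256,
                             trials_per_condition = 16, dt_ms = 10,
                             baseline_range = c(2, 10),
                             coding_strength = 1.5, coding_decay_s = 1.0,
                             distractor_amp = 8, recovery_tau_s = 0.2,
                             trial_noise_sd = 1.5, session_gain_sd = 0.1,
                             delay_s = 4.0, task = NULL) {
  stopifnot(n_sessions >= 2, n_units >= 2, trials_per_condition >= 1,
            coding_decay_s > 0, recovery_tau_s > 0, trial_noise_sd >= 0)
  if (is.null(task)) {
    task <- task_config(dt_ms = dt_ms,
                        delay_set_s = sort(unique(c(1.0, 1.41, 2.0, 2.83,
                                                    4.0, delay_s))))
  }
  structure(list(n_sessions = n_sessions, n_units = n_units,
                 trials_per_condition = trials_per_condition, dt_ms = dt_ms,
                 baseline_range = baseline_range,
                 coding_strength = coding_strength,
                 coding_decay_s = coding_decay_s,
                 distractor_amp = distractor_amp,
                 recovery_tau_s = recovery_tau_s,
                 trial_noise_sd = trial_noise_sd,
                 session_gain_sd = session_gain_sd,
                 delay_s = delay_s, task = task),
            class = "surrogate_config")
}

#' Generate one surrogate recording session
#'
#' Each trial's unit rates are
#' `gain * max(0, baseline + tuning[, sample] * amp(t) + distractor_profile(t) * v + noise)`:
#' the sample-tuning amplitude is 1 during sample presentation and decays
#' exponentially (time constant `coding_decay_s`) from sample offset; on
#' distractor trials a common population direction `v` (norm
#' `distractor_amp`, shared across samples within the session) is added
#' during the distractor and decays with `recovery_tau_s` afterwards — so
#' the stimulus-pair distance is unaffected at first order while the
#' distracted/undistracted distance rises and recovers.
#'
#' @param cfg A `surrogate_config`.
#' @param session_id Integer session label.
#' @param seed RNG seed.
#' @return A `trajectory_tensor` (trials x units x time) with labels.
#' @export
generate_session <- function(cfg, session_id = 1L, seed = 1L) {
  stopifnot(inherits(cfg, "surrogate_config"))
  set.seed(seed)
  tk <- cfg$task
  n_samples <- tk$n_samples
  dt_s <- cfg$dt_ms / 1000
  # timing via a template trial (with distractor, for epoch boundaries)
  tmpl <- make_trial(tk, 0L, cfg$delay_s, distractor_id = 0L, rng_seed = 1L)
  Tn <- tmpl$n_steps
  smp <- tmpl$epochs$sample
  dis <- tmpl$epochs$distractor
  time_s <- (seq_len(Tn) - smp["start"]) * dt_s

  baseline <- stats::runif(cfg$n_units, cfg$baseline_range[1],
                           cfg$baseline_range[2])
  tuning <- matrix(stats::rnorm(cfg$n_units * n_samples, 0,
                                cfg$coding_strength),
                   cfg$n_units, n_samples)
  v <- stats::rnorm(cfg$n_units)
  v <- v / sqrt(sum(v^2)) * cfg$distractor_amp
  gain <- exp(stats::rnorm(1, 0, cfg$session_gain_sd))

  # temporal profiles
  amp <- numeric(Tn)
  amp[smp["start"]:smp["end"]] <- 1
  post <- (smp["end"] + 1):Tn
  amp[post] <- exp(-(seq_along(post) * dt_s) / cfg$coding_decay_s)
  dprof <- numeric(Tn)
  dprof[dis["start"]:dis["end"]] <- 1
  dpost <- (dis["end"] + 1):Tn
  dprof[dpost] <- exp(-(seq_along(dpost) * dt_s) / cfg$recovery_tau_s)

  conds <- expand.grid(sample_id = 0:(n_samples - 1),
                       distractor = c(FALSE, TRUE))
  n_trials <- nrow(conds) * cfg$trials_per_condition
  labels <- conds[rep(seq_len(nrow(conds)), each = cfg$trials_per_condition), ]
  labels$delay_s <- cfg$delay_s
  labels$session <- session_id
  rownames(labels) <- NULL

  vals <- array(0, c(n_trials, cfg$n_units, Tn))
  for (i in seq_len(n_trials)) {
    sig <- outer(baseline, rep(1, Tn)) +
      outer(tuning[, labels$sample_id[i] + 1], amp)
    if (labels$distractor[i]) sig <- sig + outer(v, dprof)
    noise <- matrix(stats::rnorm(cfg$n_units * Tn, 0, cfg$trial_noise_sd),
                    cfg$n_units, Tn)
    vals[i, , ] <- gain * pmax(sig + noise, 0)
  }
  trajectory_tensor(vals, time_s, labels, "rates")
}

#' Generate a full multi-session surrogate dataset
#' @param cfg A `surrogate_config`.
#' @param seed Base seed; session s uses `seed + s`.
#' @return List of `trajectory_tensor`s, one per session.
#' @export
generate_sessions <- function(cfg, seed = 1L) {
  lapply(seq_len(cfg$n_sessions), function(s) {
    generate_session(cfg, session_id = s, seed = seed + s)
  })
}

#' Reference decoding curves from surrogate sessions
#'
#' Builds the per-delay decoding-accuracy curves that stand in for the
#' recorded-data reference in the brain-similarity score: for each delay a
#' surrogate dataset is generated, binned, and decoded session by session.
#' With the default decaying sample coding the curves peak during the
#' sample epoch and decline toward chance (1/8) over long delays.
#'
#' @param cfg A `surrogate_config` (its `delay_s` is overridden per curve).
#' @param delays Delay lengths (s) to build curves for.
#' @param bin_ms Decoding bin width.
#' @param seed Base RNG seed.
#' @return Named list of `decoding_curve`s keyed by delay.
#' @export
make_reference_curves <- function(cfg, delays = c(1.0, 1.41), bin_ms = 50,
                                  seed = 1L) {
  out <- list()
  for (d in delays) {
    cfg_d <- cfg
    cfg_d$delay_s <- d
    sessions <- generate_sessions(cfg_d, seed = seed + round(1000 * d))
    binned <- lapply(sessions, bin_rates, bin_ms = bin_ms)
    merged <- merge_tensors(binned)
    out[[as.character(d)]] <- decode_sample(merged, seed = seed)
  }
  out
}

#' Concatenate per-session tensors sharing a time axis
#' @param tensors List of `trajectory_tensor`s with identical unit/time
#'   dimensions.
#' @return One `trajectory_tensor` with stacked trials.
#' @export
merge_tensors <- function(tensors) {
  stopifnot(length(tensors) >= 1)
  d <- dim(tensors[[1]]$values)
  for (tt in tensors) stopifnot(all(dim(tt$values)[2:3] == d[2:3]))
  vals <- do.call(abind3, lapply(tensors, `[[`, "values"))
  labs <- do.call(rbind, lapply(tensors, `[[`, "labels"))
  trajectory_tensor(vals, tensors[[1]]$time_s, labs, tensors[[1]]$kind)
}

# bind 3D arrays along the first (trial) axis
abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  n1 <- sum(vapply(parts, function(p) dim(p)[1], integer(1)))
  out <- array(0, c(n1, d[2], d[3]))
  at <- 0
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}
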