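#' Training configuration
#'
#' Per-model default learning rates follow the reference protocol: 1e-3 for the
#' fixed-synapse networks, 0.02 for PS-pre, 0.01 for PS-hebb; Adam with
#' standard moments, L2 weight decay 1e-4 on all trainable parameters, batch
#' size 256 with one delay length per batch. Activity regularization adds
#' `strength * sum(x^2) / (n_units * n_timepoints)` (summed over the whole
#' batch, as specified) to the loss; the package default strength is 1e-3
#' (the low end of the standard sweep grid, which trains most reliably).
#' PS-hebb gradients are clipped at global norm 1 (identity activation makes
#' early training prone to blow-up). Training stops early once held-out
#' accuracy reaches `early_stop_acc`.
#'
#' @param kind Model kind (sets the default learning rate).
#' @param learning_rate,weight_decay,activity_reg,batch_size,max_epochs
#'   Optimizer settings.
#' @param early_stop_acc Dev-set accuracy at which training stops.
#' @param clip_norm Global gradient-norm clip (default 1 for ps-hebb,
#'   Inf otherwise).
#' @param eval_every Evaluate the dev set every this many epochs.
#' @param max_seconds Wall-clock training budget; the epoch loop stops once
#'   it is exceeded (Inf = no cap).
#' @param train_noise Process noise during training. The fixed-synapse and
#'   anti-Hebbian dynamics include the noise term; the presynaptic-plasticity
#'   update is written without one, so ps-pre defaults to noise-free
#'   training (robustness is probed by switching noise on at evaluation).
#' @param seed RNG seed for batching and noise.
#' @return List of class `wm_train_config`.
#' @export
train_config <- function(kind = "fs-tanh",
                         learning_rate = NULL,
                         weight_decay = 1e-4,
                         activity_reg = 1e-3,
                         batch_size = 256,
                         max_epochs = 40,
                         early_stop_acc = 0.95,
                         clip_norm = NULL,
                         eval_every = 1L,
                         max_seconds = Inf,
                         train_noise = NULL,
                         seed = 1L) {
  kind <- match.arg(kind, MODEL_KINDS)
  if (is.null(learning_rate)) {
    learning_rate <- switch(kind, `ps-pre` = 0.02, `ps-hebb` = 0.01, 1e-3)
  }
  if (is.null(clip_norm)) clip_norm <- if (kind == "ps-hebb") 1.0 else Inf
  if (is.null(train_noise)) train_noise <- kind != "ps-pre"
  stopifnot(weight_decay >= 0, activity_reg >= 0, batch_size >= 1,
            max_epochs >= 1, eval_every >= 1, max_seconds > 0)
  structure(list(kind = kind, learning_rate = learning_rate,
                 weight_decay = weight_decay, activity_reg = activity_reg,
                 batch_size = batch_size, max_epochs = max_epochs,
                 early_stop_acc = early_stop_acc, clip_norm = clip_norm,
                 eval_every = as.integer(eval_every),
                 max_seconds = max_seconds, train_noise = train_noise,
                 seed = as.integer(seed)),
            class = "wm_train_config")
}

#' Mean-squared task loss over the response window
#'
#' Mean over output channels and window timepoints of the squared error
#' between output and desired output.
#' @param outputs,targets time x channels matrices.
#' @param window Integer step indices of the scoring window.
#' @return Scalar loss.
#' @export
mse_loss <- function(outputs, targets, window) {
  if (length(window) == 0) stop("empty scoring window")
  stopifnot(all(dim(outputs) == dim(targets)), max(window) <= nrow(outputs))
  mean((outputs[window, , drop = FALSE] - targets[window, , drop = FALSE])^2)
}

#' Activity regularization penalty
#'
#' Squared sum of all activations in a batch divided by the number of units
#' and the number of timepoints (not by batch size), scaled by `strength`.
#' @param activations Array (batch x time x units) or matrix (time x units).
#' @param strength Non-negative scale.
#' @return Scalar penalty.
#' @export
activity_regularizer <- function(activations, strength) {
  stopifnot(strength >= 0)
  d <- dim(activations)
  if (length(d) == 2) d <- c(1, d)
  strength * sum(activations^2) / (d[3] * d[2])
}

# ---- batch plumbing --------------------------------------------------------

# trials (same step count) -> list(M, Y, win0, win1) of (ch x B x T) cubes
build_batch <- function(trials) {
  Tn <- trials[[1]]$n_steps
  stopifnot(all(vapply(trials, `[[`, integer(1), "n_steps") == Tn))
  B <- length(trials)
  n_in <- ncol(trials[[1]]$inputs)
  n_out <- ncol(trials[[1]]$targets)
  M <- array(0, c(n_in, B, Tn))
  Y <- array(0, c(n_out, B, Tn))
  for (j in seq_len(B)) {
    M[, j, ] <- t(trials[[j]]$inputs)
    Y[, j, ] <- t(trials[[j]]$targets)
  }
  ep <- trials[[1]]$epochs$response
  list(M = M, Y = Y, win0 = unname(ep["start"]), win1 = unname(ep["end"]))
}

# dispatch one batch through the model family's C++ kernel
batch_forward <- function(model, params, batch, grad = FALSE, noise = TRUE,
                          act_reg = 0, sigma_rec = NULL, kmask = NULL,
                          n_classes = NULL) {
  sig <- if (noise) (sigma_rec %||% model$sigma_rec) else 0
  nsd <- if (sig > 0) noise_scale(sig, model$alpha) else 0
  if (is.null(n_classes)) n_classes <- model$n_outputs - 3L # sample channels
  if (model$kind %in% c("fs-tanh", "fs-relu")) {
    act <- if (model$kind == "fs-tanh") 0L else 1L
    cpp_fs_batch(params$W, params$W_in, params$b, params$W_out, params$c,
                 batch$M, batch$Y, batch$win0, batch$win1, n_classes,
                 model$alpha, nsd, act, act_reg, grad)
  } else if (model$kind == "ps-pre") {
    cpp_pspre_batch(params$W, model$dale, params$W_in, params$b,
                    params$W_out, params$c,
                    model$kinetics$tau_a, model$kinetics$tau_u,
                    model$kinetics$U, batch$M, batch$Y,
                    batch$win0, batch$win1, n_classes,
                    model$alpha, model$dt_ms / 1000, nsd, act_reg, grad,
                    FALSE)
  } else {
    lam <- 1 - model$alpha * model$gamma
    if (is.null(kmask)) kmask <- matrix(1, model$n, model$n)
    cpp_pshebb_batch(params$C, params$W_in, params$b, params$W_out, params$c,
                     batch$M, batch$Y, batch$win0, batch$win1, n_classes,
                     model$alpha, lam, nsd, act_reg, grad, kmask)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

trainable_names <- function(kind) {
  if (kind == "ps-hebb") c("C", "W_in", "b", "W_out", "c")
  else c("W", "W_in", "b", "W_out", "c")
}

#' Train a model on the task
#'
#' Backpropagation-through-time with Adam. Trials are grouped by delay
#' length (one delay per batch). The PS-pre raw recurrent matrix is
#' rectified inside the forward pass (so non-negativity of the effective
#' matrix holds at every step), the Dale sign matrix stays fixed, and the
#' PS-hebb gain matrix is reparameterized through C at every step, so the
#' constraint structure is maintained through every optimizer update.
#'
#' @param model A `wm_model` from [init_model()].
#' @param trials Training trials from [make_dataset()].
#' @param cfg A `wm_train_config` (defaults per model kind).
#' @param dev_trials Optional held-out trials used for the early-stopping
#'   accuracy check (evaluated once per epoch).
#' @param check_constraints If TRUE, verify Dale signs / u,a bounds /
#'   positive-definiteness of K after every optimizer update and record the
#'   result.
#' @param verbose Print one line per epoch.
#' @return The trained `wm_model` with the parameters of the best
#'   dev-accuracy checkpoint (final parameters when no `dev_trials` are
#'   given), a `history` data.frame (epoch, loss, accuracy and, when
#'   `dev_trials` given, dev accuracy) and, when requested,
#'   `constraint_checks` (logical: all checks passed).
#' @export
train <- function(model, trials, cfg = train_config(model$kind),
                  dev_trials = NULL, check_constraints = FALSE,
                  verbose = FALSE) {
  stopifnot(inherits(model, "wm_model"), length(trials) >= 1)
  if (cfg$kind != model$kind) cfg <- train_config(model$kind,
                                                  seed = cfg$seed)
  set.seed(cfg$seed)
  labs <- dataset_labels(trials)
  batches <- list()
  for (d in unique(labs$delay_s)) {
    idx <- sample(which(labs$delay_s == d)) # seeded shuffle within delay
    starts <- seq(1, length(idx), by = cfg$batch_size)
    for (s in starts) {
      take <- idx[s:min(s + cfg$batch_size - 1, length(idx))]
      batches[[length(batches) + 1]] <- build_batch(trials[take])
    }
  }

  nm <- trainable_names(model$kind)
  params <- model$params[nm]
  m1 <- lapply(params, function(p) p * 0)
  m2 <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  all_ok <- TRUE
  hist <- data.frame()
  t_start <- Sys.time()
  best <- list(acc = -Inf, params = params)

  for (epoch in seq_len(cfg$max_epochs)) {
    ep_loss <- ep_acc <- 0
    ntr <- 0
    for (bi in sample(length(batches))) {
      b <- batches[[bi]]
      res <- batch_forward(model, params, b, grad = TRUE,
                           noise = cfg$train_noise,
                           act_reg = cfg$activity_reg)
      if (!is.finite(res$loss)) {
        stop("divergent loss at epoch ", epoch, " (non-finite); aborting")
      }
      g <- res$grads
      for (k in nm) {
        # match parameter shape (vectors come back as n x 1 matrices)
        if (is.matrix(params[[k]])) {
          dim(g[[k]]) <- dim(params[[k]])
        } else {
          g[[k]] <- as.numeric(g[[k]])
        }
        # PyTorch-style L2 weight decay: grad += wd * param
        g[[k]] <- g[[k]] + cfg$weight_decay * params[[k]]
      }
      if (is.finite(cfg$clip_norm)) {
        gn <- sqrt(sum(vapply(g, function(x) sum(x^2), numeric(1))))
        if (gn > cfg$clip_norm) g <- lapply(g, `*`, cfg$clip_norm / gn)
      }
      step <- step + 1L
      bc1 <- 1 - beta1^step
      bc2 <- 1 - beta2^step
      for (k in nm) {
        m1[[k]] <- beta1 * m1[[k]] + (1 - beta1) * g[[k]]
        m2[[k]] <- beta2 * m2[[k]] + (1 - beta2) * g[[k]]^2
        params[[k]] <- params[[k]] -
          cfg$learning_rate * (m1[[k]] / bc1) / (sqrt(m2[[k]] / bc2) + eps)
      }
      if (check_constraints) {
        all_ok <- all_ok && check_model_constraints(model, params, res)
      }
      bsz <- dim(b$M)[2]
      ep_loss <- ep_loss + res$loss * bsz
      ep_acc <- ep_acc + sum(res$acc)
      ntr <- ntr + bsz
    }
    elapsed <- as.numeric(difftime(Sys.time(), t_start, units = "secs"))
    out_of_time <- elapsed >= cfg$max_seconds
    row <- data.frame(epoch = epoch, loss = ep_loss / ntr,
                      accuracy = ep_acc / ntr, dev_accuracy = NA_real_)
    if (!is.null(dev_trials) &&
        (epoch %% cfg$eval_every == 0 || out_of_time ||
           epoch == cfg$max_epochs)) {
      model_now <- model
      model_now$params[nm] <- params
      ev <- evaluate_accuracy(model_now, dev_trials,
                              noise = cfg$train_noise,
                              seed = cfg$seed + epoch)
      row$dev_accuracy <- ev$accuracy
      if (ev$accuracy > best$acc) best <- list(acc = ev$accuracy,
                                               params = params)
    }
    hist <- rbind(hist, row)
    if (verbose) {
      message(sprintf("epoch %2d  loss %.4f  acc %.3f  dev %.3f", epoch,
                      row$loss, row$accuracy, row$dev_accuracy))
    }
    stop_acc <- if (!is.null(dev_trials)) row$dev_accuracy else row$accuracy
    if (isTRUE(stop_acc >= cfg$early_stop_acc) || out_of_time) break
  }
  # keep the best dev checkpoint (training with plastic dynamics can be
  # non-monotone late in optimization)
  model$params[nm] <- if (is.finite(best$acc)) best$params else params
  model$history <- hist
  model$train_cfg <- cfg
  if (check_constraints) model$constraint_checks <- all_ok
  model
}

# Dale signs, u/a bounds, K positivity -- evaluated on current parameters
check_model_constraints <- function(model, params, batch_res = NULL) {
  ok <- TRUE
  if (model$kind == "ps-pre") {
    Weff <- effective_weights(params$W, model$dale)
    sgn <- sweep(Weff, 2, model$dale, `*`)
    ok <- ok && all(sgn >= 0) # every column keeps its presynaptic sign
    if (!is.null(batch_res)) {
      ok <- ok && all(batch_res$u_final >= 0) && all(batch_res$u_final <= 1) &&
        all(batch_res$a_final >= 0) && all(batch_res$a_final <= 1)
    }
  } else if (model$kind == "ps-hebb") {
    K <- build_K(params$C)
    ok <- ok && all(K > 0) &&
      min(eigen((K + t(K)) / 2, symmetric = TRUE,
                only.values = TRUE)$values) > 0
  }
  ok
}

#' Evaluate task accuracy
#'
#' Forward passes with process noise (matching training conditions), scoring
#' the per-timepoint argmax over the sample output channels against the true
#' sample over the 500 ms window after the test period; a trial's accuracy
#' is its fraction of matching timepoints. Reported overall and split by
#' distractor condition.
#'
#' @param model Trained `wm_model`.
#' @param trials Held-out trials.
#' @param noise Process noise on/off.
#' @param sigma_rec Optional override of the process-noise SD.
#' @param kmask Optional ablation mask for the ps-hebb gain matrix.
#' @param seed RNG seed for the evaluation noise.
#' @return List: `accuracy`, `by_distractor` (named numeric), `per_trial`,
#'   `loss`.
#' @export
evaluate_accuracy <- function(model, trials, noise = TRUE, sigma_rec = NULL,
                              kmask = NULL, seed = 1L) {
  set.seed(seed)
  labs <- dataset_labels(trials)
  per_trial <- numeric(length(trials))
  loss <- 0
  for (d in unique(labs$delay_s)) {
    idx <- which(labs$delay_s == d)
    for (s in seq(1, length(idx), by = 512)) {
      take <- idx[s:min(s + 511, length(idx))]
      b <- build_batch(trials[take])
      res <- tryCatch(
        batch_forward(model, model$params, b, grad = FALSE,
                      noise = noise, sigma_rec = sigma_rec,
                      kmask = kmask),
        error = function(e) {
          if (!grepl("blow-up|non-finite", conditionMessage(e))) stop(e)
          NULL
        })
      if (is.null(res)) {
        # divergent dynamics (e.g. an ablated network losing its stability
        # structure) count as task failure, not as an analysis error
        warning("state diverged during evaluation; ", length(take),
                " trials scored 0", call. = FALSE)
        per_trial[take] <- 0
      } else {
        per_trial[take] <- res$acc
        loss <- loss + res$mse * length(take)
      }
    }
  }
  dis <- labs$distractor
  list(accuracy = mean(per_trial),
       by_distractor = c(distractor = mean(per_trial[dis]),
                         no_distractor = mean(per_trial[!dis])),
       per_trial = per_trial,
       loss = loss / length(trials))
}
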