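#' Trajectory tensor container
#'
#' The shared currency of all population analyses: a trials x units x time
#' array of rates (or synaptic variables) with a time axis in seconds
#' relative to sample onset and per-trial labels.
#'
#' @param values Numeric array, trials x units x time.
#' @param time_s Strictly increasing numeric vector, one entry per time
#'   point, seconds relative to sample onset.
#' @param labels data.frame with one row per trial; columns `sample_id`
#'   (integer), `distractor` (logical), `delay_s`, `session` at minimum.
#' @param kind `"rates"` or `"synaptic"`.
#' @return Object of class `trajectory_tensor`.
#' @export
trajectory_tensor <- function(values, time_s, labels, kind = "rates") {
  stopifnot(length(dim(values)) == 3,
            dim(values)[3] == length(time_s),
            all(diff(time_s) > 0),
            nrow(labels) == dim(values)[1],
            all(c("sample_id", "distractor") %in% names(labels)))
  if (is.null(labels$session)) labels$session <- 1L
  structure(list(values = values, time_s = time_s, labels = labels,
                 kind = kind),
            class = "trajectory_tensor")
}

#' @export
print.trajectory_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<trajectory_tensor [%s]: %d trials x %d units x %d bins, t in [%.2f, %.2f] s>\n",
              x$kind, d[1], d[2], d[3], min(x$time_s), max(x$time_s)))
  invisible(x)
}

#' Subset a trajectory tensor by trials and/or units
#' @param tensor A `trajectory_tensor`.
#' @param trials,units Index vectors (default: keep all).
#' @return A `trajectory_tensor`.
#' @export
subset_tensor <- function(tensor, trials = NULL, units = NULL) {
  v <- tensor$values
  lab <- tensor$labels
  if (!is.null(trials)) {
    v <- v[trials, , , drop = FALSE]
    lab <- lab[trials, , drop = FALSE]
  }
  if (!is.null(units)) v <- v[, units, , drop = FALSE]
  trajectory_tensor(v, tensor$time_s, lab, tensor$kind)
}

#' Gaussian-kernel rate smoothing
#'
#' Convolves each unit's time series with a normalized Gaussian kernel
#' (reflect padding at the trial boundaries), turning spike counts or raw
#' rates into smooth firing rates. The kernel sums to one so the total mass
#' is preserved away from the edges.
#'
#' @param x 3D array (trials x units x time), matrix (time x units) or
#'   `trajectory_tensor`.
#' @param kernel_sd_ms Kernel SD in milliseconds (default analyses use 10).
#' @param dt_ms Sampling step of the time axis in milliseconds.
#' @return Same shape/class as the input, smoothed along time.
#' @export
smooth_rates <- function(x, kernel_sd_ms = 10, dt_ms) {
  stopifnot(kernel_sd_ms > 0, dt_ms > 0)
  if (inherits(x, "trajectory_tensor")) {
    out <- x
    out$values <- smooth_rates(x$values, kernel_sd_ms, dt_ms)
    return(out)
  }
  sd_steps <- kernel_sd_ms / dt_ms
  r <- max(1L, ceiling(4 * sd_steps))
  k <- stats::dnorm(seq(-r, r), sd = sd_steps)
  k <- k / sum(k)
  smooth_vec_mat <- function(m) {
    # m: time x series; reflect-pad rows then convolve columns
    Tn <- nrow(m)
    ridx <- c(pmin(r:1 + 1, Tn), seq_len(Tn), pmax(Tn - (1:r), 1))
    mp <- m[ridx, , drop = FALSE]
    sm <- stats::filter(mp, k, method = "convolution", sides = 2)
    sm[(r + 1):(r + Tn), , drop = FALSE]
  }
  if (is.matrix(x)) return(unclass(smooth_vec_mat(x)))
  d <- dim(x)
  # collapse trials*units into columns of a time x series matrix
  m <- matrix(aperm(x, c(3, 1, 2)), nrow = d[3])
  sm <- smooth_vec_mat(m)
  aperm(array(as.numeric(sm), c(d[3], d[1], d[2])), c(2, 3, 1))
}

#' Average rates into time bins
#'
#' @param tensor A `trajectory_tensor` (or 3D array with `dt_ms` implied by
#'   `time_s` spacing).
#' @param bin_ms Bin width in ms; must be a whole multiple of the tensor's
#'   sampling step. Trailing samples that do not fill a bin are dropped.
#' @return A `trajectory_tensor` with per-bin mean values and bin-center
#'   time axis.
#' @export
bin_rates <- function(tensor, bin_ms) {
  stopifnot(inherits(tensor, "trajectory_tensor"))
  dt_ms <- 1000 * stats::median(diff(tensor$time_s))
  k <- bin_ms / dt_ms
  if (abs(k - round(k)) > 1e-6) {
    stop("bin_ms = ", bin_ms, " is not a multiple of the sampling step (",
         round(dt_ms, 3), " ms)")
  }
  k <- as.integer(round(k))
  d <- dim(tensor$values)
  nb <- d[3] %/% k
  if (nb < 1) stop("bin wider than the available time axis")
  idx <- seq_len(nb * k)
  v <- tensor$values[, , idx, drop = FALSE]
  dim(v) <- c(d[1], d[2], k, nb)
  binned <- apply(v, c(1, 2, 4), mean)
  centers <- vapply(seq_len(nb), function(i) {
    mean(tensor$time_s[((i - 1) * k + 1):(i * k)])
  }, numeric(1))
  trajectory_tensor(binned, centers, tensor$labels, tensor$kind)
}

#' Run a model over many trials and collect trajectory tensors
#'
#' Batched forward passes (no gradients) recording hidden rates and, for the
#' plastic models, the synaptic state: per-unit (u, a) concatenated for
#' PS-pre (plasticity is presynaptic, so the per-unit variables carry all
#' synaptic information), the flattened plastic weight matrix for PS-hebb
#' (optionally projected to at most `max_syn_features` random features).
#' All trials must share one delay length so the tensor has a common time
#' axis.
#'
#' @param model A `wm_model`.
#' @param trials Equal-length `wm_trial`s (one delay condition).
#' @param synaptic Also record the synaptic trajectory (plastic models).
#' @param noise Process noise on/off.
#' @param seed RNG seed for the noise.
#' @param session Session id stored in the labels.
#' @param max_syn_features Cap on PS-hebb synaptic features (random
#'   projection beyond it, seeded).
#' @return List with `rates` (and `synaptic` when requested), both
#'   `trajectory_tensor`s.
#' @export
run_trials <- function(model, trials, synaptic = FALSE, noise = TRUE,
                       seed = 1L, session = 1L, max_syn_features = 4096L) {
  labs <- dataset_labels(trials)
  if (length(unique(labs$delay_s)) != 1) {
    stop("run_trials needs a single delay condition; split the dataset first")
  }
  set.seed(seed)
  b <- build_batch(trials)
  p <- model$params
  sig <- if (noise) model$sigma_rec else 0
  nsd <- if (sig > 0) noise_scale(sig, model$alpha) else 0
  if (model$kind %in% c("fs-tanh", "fs-relu")) {
    act <- if (model$kind == "fs-tanh") 0L else 1L
    rec <- cpp_fs_record(p$W, p$W_in, p$b, b$M, model$alpha, nsd, act)
    syn <- NULL
  } else if (model$kind == "ps-pre") {
    rec <- cpp_pspre_record(p$W, model$dale, p$W_in, p$b,
                            model$kinetics$tau_a, model$kinetics$tau_u,
                            model$kinetics$U, b$M, model$alpha,
                            model$dt_ms / 1000, nsd, FALSE)
    syn <- if (synaptic) {
      ua <- array(0, c(2 * model$n, length(trials), dim(rec$u)[3]))
      ua[seq_len(model$n), , ] <- rec$u
      ua[model$n + seq_len(model$n), , ] <- rec$a
      aperm(ua, c(2, 1, 3))
    }
  } else {
    lam <- 1 - model$alpha * model$gamma
    kmask <- model$kmask %||% matrix(1, model$n, model$n)
    rec <- cpp_pshebb_record(p$C, p$W_in, p$b, b$M, model$alpha, lam, nsd,
                             synaptic, kmask, FALSE,
                             matrix(0, model$n, model$n))
    syn <- if (synaptic) {
      w <- rec$weights # (n^2, B, T)
      if (dim(w)[1] > max_syn_features) {
        proj <- matrix(stats::rnorm(max_syn_features * dim(w)[1],
                                    0, 1 / sqrt(dim(w)[1])),
                       max_syn_features, dim(w)[1])
        w <- vapply(seq_len(dim(w)[3]), function(t) proj %*% w[, , t],
                    matrix(0, max_syn_features, dim(w)[2]))
      }
      aperm(w, c(2, 1, 3))
    }
  }
  smp_start <- trials[[1]]$epochs$sample["start"]
  time_s <- (seq_len(trials[[1]]$n_steps) - smp_start) * model$dt_ms / 1000
  labs$session <- session
  rates <- trajectory_tensor(aperm(rec$rates, c(2, 1, 3)), time_s, labs,
                             "rates")
  out <- list(rates = rates)
  if (synaptic && !is.null(syn)) {
    out$synaptic <- trajectory_tensor(syn, time_s, labs, "synaptic")
  }
  out
}
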