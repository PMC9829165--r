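#' Mean pairwise distance between stimulus trajectories
#'
#' Uses non-distractor trials only: trial-averages the population
#' trajectory per sample, then at every time point takes the Euclidean
#' distance between each pair of sample means and averages over the
#' S(S-1)/2 pairs. Optionally normalized by the mean pre-stimulus (t < 0)
#' distance so the baseline sits at 1.
#'
#' @param tensor A `trajectory_tensor`.
#' @param normalize Divide by the mean pre-stimulus distance.
#' @return A `distance_curve` data.frame: `time`, `distance`.
#' @export
stim_distance <- function(tensor, normalize = FALSE) {
  stopifnot(inherits(tensor, "trajectory_tensor"))
  keep <- which(!tensor$labels$distractor)
  samples <- sort(unique(tensor$labels$sample_id))
  nt <- length(tensor$time_s)
  means <- lapply(samples, function(s) {
    tr <- keep[tensor$labels$sample_id[keep] == s]
    if (length(tr) == 0) stop("sample ", s, " has no non-distractor trials")
    colMeans(matrix(tensor$values[tr, , , drop = FALSE],
                    nrow = length(tr)))
  })
  # each element: units*time vector; reshape to units x time
  nu <- dim(tensor$values)[2]
  means <- lapply(means, function(m) matrix(m, nu, nt))
  S <- length(samples)
  d <- numeric(nt)
  for (i in seq_len(S - 1)) {
    for (j in (i + 1):S) {
      d <- d + sqrt(colSums((means[[i]] - means[[j]])^2))
    }
  }
  d <- d * 2 / (S * (S - 1))
  if (normalize) {
    pre <- tensor$time_s < 0
    if (!any(pre)) stop("no pre-stimulus bins to normalize by")
    d <- d / mean(d[pre])
  }
  out <- data.frame(time = tensor$time_s, distance = d)
  class(out) <- c("distance_curve", "data.frame")
  attr(out, "normalized") <- normalize
  out
}

#' Distance between distracted and non-distracted trajectories
#'
#' For each sample, the Euclidean distance between the trial-averaged
#' distractor and no-distractor trajectories, averaged over samples.
#'
#' @inheritParams stim_distance
#' @return A `distance_curve` data.frame.
#' @export
distractor_distance <- function(tensor, normalize = FALSE) {
  stopifnot(inherits(tensor, "trajectory_tensor"))
  samples <- sort(unique(tensor$labels$sample_id))
  nu <- dim(tensor$values)[2]
  nt <- length(tensor$time_s)
  d <- numeric(nt)
  for (s in samples) {
    for (cond in c(TRUE, FALSE)) {
      tr <- which(tensor$labels$sample_id == s &
                    tensor$labels$distractor == cond)
      if (length(tr) == 0) {
        stop("sample ", s, " lacks ",
             if (cond) "distractor" else "non-distractor", " trials")
      }
      m <- matrix(colMeans(matrix(tensor$values[tr, , , drop = FALSE],
                                  nrow = length(tr))), nu, nt)
      if (cond) m1 <- m else m0 <- m
    }
    d <- d + sqrt(colSums((m1 - m0)^2))
  }
  d <- d / length(samples)
  if (normalize) {
    pre <- tensor$time_s < 0
    if (!any(pre)) stop("no pre-stimulus bins to normalize by")
    d <- d / mean(d[pre])
  }
  out <- data.frame(time = tensor$time_s, distance = d)
  class(out) <- c("distance_curve", "data.frame")
  attr(out, "normalized") <- normalize
  out
}

#' Multi-level (sessions, then trials) bootstrap confidence bands
#'
#' Resamples sessions with replacement (as many draws as there are
#' sessions), then trials with replacement within every resampled session,
#' recomputes the statistic on each of the B replicates, and returns the
#' percentile interval. This propagates both session-level and trial-level
#' variability into the bands.
#'
#' @param sessions List of per-session inputs; each element is either a
#'   `trajectory_tensor` (trials resampled along the first axis, labels
#'   carried along), a matrix (rows resampled) or a vector.
#' @param statistic Function taking the list of resampled sessions and
#'   returning a numeric vector (e.g. a distance curve) or scalar.
#' @param B Number of bootstrap replicates (default 1000).
#' @param conf Confidence level (default 0.95, i.e. the 2.5th and 97.5th
#'   percentiles).
#' @param seed RNG seed.
#' @return List with `lower`, `upper` (numeric, same length as the
#'   statistic), `estimate` (statistic on the original data),
#'   `replicates` (B x length matrix) and `n_failed`.
#' @export
bootstrap_ci <- function(sessions, statistic, B = 1000, conf = 0.95,
                         seed = 1L) {
  stopifnot(length(sessions) >= 2)
  if (B < 100) warning("B = ", B, " bootstrap replicates is very small")
  set.seed(seed)
  E <- length(sessions)
  est <- statistic(sessions)
  reps <- matrix(NA_real_, B, length(est))
  n_failed <- 0L
  for (b in seq_len(B)) {
    pick <- sample.int(E, E, replace = TRUE)
    res <- lapply(sessions[pick], resample_trials)
    val <- tryCatch(statistic(res), error = function(e) NULL)
    if (is.null(val) || length(val) != length(est)) {
      n_failed <- n_failed + 1L
    } else {
      reps[b, ] <- val
    }
  }
  ok <- stats::complete.cases(reps)
  a <- (1 - conf) / 2
  qs <- apply(reps[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(a, 1 - a), names = FALSE)
  list(lower = qs[1, ], upper = qs[2, ], estimate = est,
       replicates = reps, n_failed = n_failed)
}

resample_trials <- function(x) {
  if (inherits(x, "trajectory_tensor")) {
    idx <- sample.int(dim(x$values)[1], replace = TRUE)
    return(subset_tensor(x, trials = idx))
  }
  if (is.matrix(x)) return(x[sample.int(nrow(x), replace = TRUE), ,
                             drop = FALSE])
  x[sample.int(length(x), replace = TRUE)]
}

#' Fit an exponential recovery time constant
#'
#' Least-squares fit of an exponential recovery to a distance curve on a
#' window starting at the perturbation offset, via Levenberg-Marquardt.
#' Because a Euclidean distance between noisy trajectory means has a noise
#' floor that combines with the decaying signal in quadrature, the default
#' `"quadrature"` model fits `d(t)^2 = A exp(-2 (t - t0)/tau) + c`, which
#' recovers the signal time constant exactly under such a floor and
#' coincides with the plain fit when the floor vanishes. `"additive"` fits
#' `d(t) = A exp(-(t - t0)/tau) + c` directly. Starting values: A from the
#' early window minus the tail, c from the median of the last 10% of the
#' window, tau from a third of the window length.
#'
#' @param curve A `distance_curve` (or data.frame with `time`,
#'   `distance`).
#' @param window Two-element numeric: fit window in seconds (typically from
#'   distractor offset to the end of the recovery).
#' @param model `"quadrature"` (default) or `"additive"`.
#' @return List: `tau_s`, `A`, `c0`, `r_squared`, `resid_norm`, `fit`.
#' @export
fit_recovery_timeconstant <- function(curve, window,
                                      model = c("quadrature", "additive")) {
  model <- match.arg(model)
  sel <- curve$time >= window[1] & curve$time <= window[2]
  if (sum(sel) < 4) stop("fit window contains fewer than 4 points")
  t <- curve$time[sel] - window[1]
  d <- curve$distance[sel]
  if (d[1] <= 0) stop("distance not positive at the window start")
  rate <- 1
  if (model == "quadrature") {
    d <- d^2
    rate <- 2 # d^2 decays at twice the signal rate
  }
  c0 <- stats::median(d[t >= 0.9 * max(t)])
  # amplitude start from the early window, kept away from zero so the
  # Jacobian is non-singular at the start
  A0 <- max(max(d[seq_len(min(5, length(d)))]) - c0, 0.05 * abs(c0), 1e-3)
  tau0 <- max(diff(range(t)) / 3, 1e-3)
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = list(A = A0, tau = tau0, cc = c0),
      lower = c(A = 0, tau = 1e-4, cc = -Inf),
      fn = function(p) d - (p$A * exp(-rate * t / p$tau) + p$cc),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("exponential recovery fit failed: ",
                             conditionMessage(e)))
  if (fit$info %in% c(0, 5, 9)) {
    stop("exponential recovery fit failed to converge: ", fit$message)
  }
  pars <- fit$par
  res <- fit$fvec
  list(tau_s = pars$tau, A = pars$A, c0 = pars$cc,
       r_squared = 1 - sum(res^2) / sum((d - mean(d))^2),
       resid_norm = sqrt(sum(res^2)),
       model = model,
       fit = fit)
}
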