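#' @useDynLib stspwm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

MODEL_KINDS <- c("fs-tanh", "fs-relu", "ps-pre", "ps-hebb")

#' Process-noise scale of the discretized rate dynamics
#'
#' The per-step noise added inside the nonlinearity is
#' `sqrt(2 / alpha * sigma_rec^2) * N(0, 1)`, the standard Euler
#' discretization of Ornstein-Uhlenbeck process noise.
#' @param sigma_rec Process-noise SD (default 0.05).
#' @param alpha dt / tau ratio.
#' @return Scalar standard deviation of the per-step noise draw.
#' @export
noise_scale <- function(sigma_rec, alpha) sqrt(2 / alpha * sigma_rec^2)

#' Initialize a working-memory recurrent network
#'
#' Four model families are supported. `fs-tanh` / `fs-relu`: vanilla rate
#' networks with fixed synapses; the recurrent matrix is drawn with SD
#' `0.9/sqrt(n)` (slightly sub-critical spectral radius), all other
#' parameters with SD `1/sqrt(n)`. `ps-pre`: Dale's-law network (80%
#' excitatory / 20% inhibitory) with presynaptic facilitation/depression;
#' the non-negative recurrent matrix is drawn with SD `1/n` and 50% of
#' entries set to zero; exactly half of the units carry facilitating
#' kinetics (tau_a = 0.2 s, tau_u = 1.5 s, U = 0.15), the other half
#' depressing kinetics (tau_a = 1.5 s, tau_u = 0.2 s, U = 0.45).
#' `ps-hebb`: anti-Hebbian plastic-weight network with identity activation;
#' the gain matrix K = (C^2)'(C^2) + 1e-2 O + 1e-2 I is trained through C,
#' whose entries start uniform on (-0.5, 0.5).
#'
#' @param kind One of `"fs-tanh"`, `"fs-relu"`, `"ps-pre"`, `"ps-hebb"`.
#' @param n_hidden Number of hidden units (`ps-pre` requires a multiple of
#'   10 so the 80/20 excitatory/inhibitory split and the facilitating half
#'   are exact).
#' @param seed Integer RNG seed; initialization is deterministic given it.
#' @param dt_ms,tau_ms Integration step and membrane time constant (ms).
#' @param sigma_rec Process-noise SD.
#' @param n_inputs,n_outputs Input/output dimensions (11 each by default).
#' @return An object of class `wm_model`.
#' @export
init_model <- function(kind, n_hidden, seed = 1L, dt_ms = 15, tau_ms = 100,
                       sigma_rec = 0.05, n_inputs = 11L, n_outputs = 11L) {
  kind <- match.arg(kind, MODEL_KINDS)
  stopifnot(n_hidden >= 2)
  set.seed(seed)
  n <- as.integer(n_hidden)
  sd0 <- 1 / sqrt(n)
  params <- list(
    W_in = matrix(stats::rnorm(n * n_inputs, 0, sd0), n, n_inputs),
    b = stats::rnorm(n, 0, sd0),
    W_out = matrix(stats::rnorm(n_outputs * n, 0, sd0), n_outputs, n),
    c = stats::rnorm(n_outputs, 0, sd0)
  )
  model <- list(kind = kind, n = n, dt_ms = dt_ms, tau_ms = tau_ms,
                alpha = dt_ms / tau_ms, sigma_rec = sigma_rec,
                n_inputs = as.integer(n_inputs),
                n_outputs = as.integer(n_outputs), seed = as.integer(seed))

  if (kind %in% c("fs-tanh", "fs-relu")) {
    params$W <- matrix(stats::rnorm(n * n, 0, 0.9 / sqrt(n)), n, n)
    model$activation <- if (kind == "fs-tanh") "tanh" else "relu"
  } else if (kind == "ps-pre") {
    if (n %% 10 != 0) {
      stop("ps-pre requires n_hidden divisible by 10 for exact 80/20 ",
           "excitatory/inhibitory and 50/50 facilitating/depressing splits")
    }
    W <- matrix(stats::rnorm(n * n, 0, 1 / n), n, n)
    W[sample.int(n * n, n * n / 2)] <- 0
    params$W <- W
    model$dale <- c(rep(1, 0.8 * n), rep(-1, 0.2 * n))
    facil <- sort(sample.int(n, n / 2))
    is_f <- seq_len(n) %in% facil
    model$kinetics <- list(
      tau_a = ifelse(is_f, 0.2, 1.5),
      tau_u = ifelse(is_f, 1.5, 0.2),
      U = ifelse(is_f, 0.15, 0.45),
      facilitating = is_f
    )
    model$activation <- "relu"
  } else { # ps-hebb
    params$C <- matrix(stats::runif(n * n, -0.5, 0.5), n, n)
    # weight-decay strength; per-step plastic-weight decay factor 1 - alpha*gamma
    model$gamma <- 1 / 200
    model$activation <- "identity"
  }
  model$params <- params
  class(model) <- "wm_model"
  model
}

#' @export
print.wm_model <- function(x, ...) {
  cat(sprintf("<wm_model %s, n = %d, dt = %g ms, alpha = %g>\n",
              x$kind, x$n, x$dt_ms, x$alpha))
  invisible(x)
}

#' Dale's-law effective recurrent weights
#'
#' Rectifies the raw weight matrix and applies the presynaptic sign of each
#' column: `W_eff[, j] = relu(W_raw[, j]) * d[j]`, so excitatory columns are
#' non-negative and inhibitory columns non-positive.
#' @param W_plus Raw recurrent matrix (rectified here).
#' @param D Sign vector (+1/-1 per presynaptic unit) or diagonal matrix.
#' @return Signed effective weight matrix.
#' @export
effective_weights <- function(W_plus, D) {
  d <- if (is.matrix(D)) diag(D) else D
  stopifnot(length(d) == ncol(W_plus), all(d %in% c(-1, 1)))
  sweep(pmax(W_plus, 0), 2, d, `*`)
}

#' Build the strictly positive, positive-definite gain matrix K
#'
#' `K = B'B + 1e-2 O + 1e-2 I` with `B = C^2` elementwise; `B'B` is
#' entrywise non-negative and positive semi-definite, the all-ones matrix O
#' makes K strictly positive, and the identity makes it strictly
#' positive-definite.
#' @param C Real square matrix (the trained parameter).
#' @return K, same dimension as `C`.
#' @export
build_K <- function(C) {
  B <- C^2
  K <- crossprod(B) + 0.01
  diag(K) <- diag(K) + 0.01
  K
}

#' Affine readout
#' @param x Hidden state vector.
#' @param params List with `W_out` and `c`.
#' @return Output vector `W_out x + c`.
#' @export
readout <- function(x, params) drop(params$W_out %*% x) + params$c

#' One Euler step of the fixed-synapse rate dynamics
#'
#' `x' = (1 - alpha) x + alpha phi(W x + input_drive + b + xi)` with
#' `xi = noise_scale(sigma_rec, alpha) * noise_draw`.
#' @param state_x Current state vector.
#' @param input_drive External drive `W_in m_t` (vector).
#' @param params List with `W`, `b`.
#' @param alpha dt / tau.
#' @param noise_draw Standard-normal vector (0 for noise off).
#' @param activation `"tanh"`, `"relu"` or `"identity"`.
#' @param sigma_rec Process-noise SD.
#' @return Next state vector.
#' @export
fs_step <- function(state_x, input_drive, params, alpha, noise_draw = 0,
                    activation = "tanh", sigma_rec = 0.05) {
  stopifnot(alpha > 0, alpha <= 1)
  if (any(!is.finite(state_x))) stop("non-finite state passed to fs_step")
  h <- drop(params$W %*% state_x) + input_drive + params$b +
    noise_scale(sigma_rec, alpha) * noise_draw
  phi <- switch(activation,
    tanh = tanh(h),
    relu = pmax(h, 0),
    identity = h,
    stop("unknown activation: ", activation)
  )
  (1 - alpha) * state_x + alpha * phi
}

#' One Euler step of the presynaptic facilitation/depression kinetics
#'
#' `du = dt [(U - u)/tau_u + U (1 - u) x]`,
#' `da = dt [(1 - a)/tau_a - u a x]`, both clamped to `[0, 1]`.
#' Time constants and dt are in seconds; x is the (rectified) presynaptic
#' rate.
#' @param u,a Utilization / available-resource vectors in `[0, 1]`.
#' @param x Presynaptic rates.
#' @param kinetics List with vectors `tau_a`, `tau_u`, `U`.
#' @param dt Step size in seconds.
#' @return List with updated `u` and `a`.
#' @export
pspre_synapse_step <- function(u, a, x, kinetics, dt) {
  if (dt <= 0) stop("dt must be positive")
  du <- dt * ((kinetics$U - u) / kinetics$tau_u + kinetics$U * (1 - u) * x)
  da <- dt * ((1 - a) / kinetics$tau_a - u * a * x)
  list(u = pmin(pmax(u + du, 0), 1), a = pmin(pmax(a + da, 0), 1))
}

#' One Euler step of the PS-pre network
#'
#' The recurrent drive applies the per-presynaptic-unit efficacy `u * a` to
#' the Dale-constrained effective weights; the synaptic variables then
#' advance from the same time-t rates.
#' @param state List with `x`, `u`, `a`.
#' @param input_drive External drive vector.
#' @param params List with `W` (raw), `b`; Dale signs in `dale`, kinetics in
#'   `kinetics` (as in [init_model()]).
#' @param alpha dt / tau.
#' @param noise_draw Standard-normal vector or 0.
#' @param sigma_rec Process-noise SD.
#' @return Updated state list.
#' @export
pspre_step <- function(state, input_drive, params, alpha, noise_draw = 0,
                       sigma_rec = 0.05) {
  Weff <- effective_weights(params$W, params$dale)
  # Dale consistency: column signs must match the sign vector
  bad <- vapply(seq_len(ncol(Weff)), function(j) {
    cj <- Weff[, j]
    if (params$dale[j] > 0) any(cj < 0) else any(cj > 0)
  }, logical(1))
  if (any(bad)) stop("Dale's law violated in effective weights")
  h <- drop(Weff %*% (state$u * state$a * state$x)) + input_drive + params$b +
    noise_scale(sigma_rec, alpha) * noise_draw
  x_new <- (1 - alpha) * state$x + alpha * pmax(h, 0)
  ua <- pspre_synapse_step(state$u, state$a, state$x, params$kinetics,
                           dt = alpha * params$tau_ms / 1000)
  list(x = x_new, u = ua$u, a = ua$a)
}

#' One Euler step of the anti-Hebbian plastic-weight network
#'
#' `x' = (1 - alpha) x + alpha (W x + input_drive + b + xi)` (identity
#' activation) and `W' = (1 - alpha gamma) W - alpha K o (x x')`. The
#' anti-Hebbian term is the elementwise product of the gain matrix K with
#' the rate outer product, so strictly positive K guarantees every diagonal
#' increment is non-positive.
#' @param state List with `x` and `W`.
#' @param input_drive External drive vector.
#' @param params List with `C` (K is built via [build_K()]), `b`,
#'   `gamma`, `dt_ms`.
#' @param alpha dt / tau.
#' @param noise_draw Standard-normal vector or 0.
#' @param sigma_rec Process-noise SD.
#' @return Updated state list.
#' @export
pshebb_step <- function(state, input_drive, params, alpha, noise_draw = 0,
                        sigma_rec = 0.05) {
  lam <- 1 - alpha * params$gamma
  stopifnot(lam > 0, lam < 1)
  K <- build_K(params$C)
  h <- drop(state$W %*% state$x) + input_drive + params$b +
    noise_scale(sigma_rec, alpha) * noise_draw
  x_new <- (1 - alpha) * state$x + alpha * h
  if (any(!is.finite(x_new)) || max(abs(x_new)) > 1e6) {
    stop("PS-hebb state blow-up (||x||_inf > 1e6)")
  }
  W_new <- lam * state$W - alpha * (K * tcrossprod(state$x))
  list(x = x_new, W = W_new)
}

#' Run a model through one trial (reference implementation)
#'
#' Pure-R step loop over the trial's input time series; plastic state is
#' reset at step 0 (x = 0; u = 0, a = 1 for PS-pre; W = 0 for PS-hebb).
#' The batched C++ kernels used by [train()] and [run_trials()] implement
#' the same semantics and are tested against this loop.
#'
#' @param model A `wm_model`.
#' @param trial A `wm_trial`.
#' @param noise Logical, process noise on/off.
#' @param record Character subset of `c("rates", "synaptic", "outputs")`.
#' @param seed RNG seed for the noise draws.
#' @return List with `x` (steps x units), `y` (steps x outputs) and, for
#'   plastic models, `u`/`a` or `W` trajectories.
#' @export
run_trial <- function(model, trial, noise = TRUE,
                      record = c("rates", "outputs"), seed = 1L) {
  stopifnot(inherits(model, "wm_model"), inherits(trial, "wm_trial"),
            model$dt_ms == trial$dt_ms)
  set.seed(seed)
  ns <- trial$n_steps
  n <- model$n
  p <- model$params
  p$dale <- model$dale
  p$kinetics <- model$kinetics
  p$tau_ms <- model$tau_ms
  p$dt_ms <- model$dt_ms
  p$gamma <- model$gamma
  sig <- if (noise) model$sigma_rec else 0

  X <- matrix(0, ns, n)
  Yout <- matrix(0, ns, model$n_outputs)
  Umat <- Amat <- NULL
  Wtraj <- NULL
  if (model$kind == "ps-pre") {
    state <- list(x = numeric(n), u = numeric(n), a = rep(1, n))
    Umat <- Amat <- matrix(0, ns, n)
  } else if (model$kind == "ps-hebb") {
    state <- list(x = numeric(n), W = matrix(0, n, n))
    if ("synaptic" %in% record) Wtraj <- array(0, c(ns, n * n))
  } else {
    state <- list(x = numeric(n))
  }

  for (t in seq_len(ns)) {
    drive <- drop(p$W_in %*% trial$inputs[t, ])
    z <- if (sig > 0) stats::rnorm(n) else 0
    if (model$kind == "ps-pre") {
      state <- pspre_step(state, drive, p, model$alpha, z, sigma_rec = sig)
      Umat[t, ] <- state$u
      Amat[t, ] <- state$a
    } else if (model$kind == "ps-hebb") {
      state <- pshebb_step(state, drive, p, model$alpha, z, sigma_rec = sig)
      if (!is.null(Wtraj)) Wtraj[t, ] <- as.vector(state$W)
    } else {
      state$x <- fs_step(state$x, drive, p, model$alpha, z,
                         activation = model$activation, sigma_rec = sig)
    }
    X[t, ] <- state$x
    Yout[t, ] <- readout(state$x, p)
  }
  out <- list(x = X, y = Yout)
  if (!is.null(Umat)) {
    out$u <- Umat
    out$a <- Amat
  }
  if (!is.null(Wtraj)) out$W <- Wtraj
  out
}
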