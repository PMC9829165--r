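test_that("fixed-synapse step reduces to leaky decay and tracks fixed points", {
  n <- 5
  p <- list(W = matrix(0, n, n), b = rep(0, n))
  # decay-only: W = 0, I = 0, b = 0, noise off -> x' = (1 - alpha) x
  x1 <- fs_step(rep(1, n), rep(0, n), p, alpha = 0.15, noise_draw = 0)
  expect_equal(x1, rep(0.85, n))
  expect_equal(0.15, 15 / 100) # alpha from dt = 15 ms, tau = 100 ms

  # rectifier with large positive bias: x converges to x* = phi(b),
  # cross-checked by an independent scalar fixed-point iteration
  p$b <- rep(3, n)
  x <- rep(0, n)
  for (i in 1:400) x <- fs_step(x, rep(0, n), p, 0.15, 0, activation = "relu")
  xs <- 0
  for (i in 1:400) xs <- xs + 0.15 * (max(3 + 0 * xs, 0) - xs)
  expect_equal(x, rep(xs, n), tolerance = 1e-10)
  expect_equal(xs, 3, tolerance = 1e-6)

  expect_error(fs_step(c(NaN, rep(0, n - 1)), rep(0, n), p, 0.15),
               "non-finite")
})

test_that("synaptic kinetics relax to their closed-form steady states", {
  kin <- list(tau_a = c(0.2, 1.5), tau_u = c(1.5, 0.2), U = c(0.15, 0.45))
  # x = 0: a -> 1, u -> U (signs of increments readable from the ODEs)
  st <- pspre_synapse_step(u = c(0.5, 0.5), a = c(0.5, 0.5), x = c(0, 0),
                           kin, dt = 0.015)
  expect_true(all(st$a > 0.5))
  expect_true(all(st$u < 0.5)) # both u start above U, so they decay

  # constant drive: independent algebraic solution of the equilibria
  x0 <- 0.8
  u_star <- kin$U * (1 + kin$tau_u * x0) / (1 + kin$U * kin$tau_u * x0)
  a_star <- 1 / (1 + kin$tau_a * u_star * x0)
  u <- c(0, 0); a <- c(1, 1)
  for (i in 1:40000) {
    st <- pspre_synapse_step(u, a, c(x0, x0), kin, dt = 0.001)
    u <- st$u; a <- st$a
  }
  expect_equal(u, u_star, tolerance = 1e-4)
  expect_equal(a, a_star, tolerance = 1e-4)
  expect_error(pspre_synapse_step(u, a, c(1, 1), kin, dt = 0), "positive")
})

test_that("a single active unit drives rise-then-fall depression dynamics", {
  # scalar simulation oracle of the two-ODE system: postsynaptic drive
  # u*a*x for a depressing synapse under sustained presynaptic rate
  kin <- list(tau_a = 1.5, tau_u = 0.2, U = 0.45)
  x0 <- 2
  u <- 0; a <- 1
  drive <- numeric(400)
  for (i in seq_along(drive)) {
    st <- pspre_synapse_step(u, a, x0, kin, dt = 0.015)
    u <- st$u; a <- st$a
    drive[i] <- u * a * x0
  }
  pk <- which.max(drive)
  expect_gt(pk, 1)
  expect_lt(pk, 150)
  expect_lt(drive[400], max(drive) * 0.98)
})

test_that("Dale decomposition signs every column by its presynaptic unit", {
  expect_equal(effective_weights(matrix(1, 2, 2), c(1, 1)),
               matrix(1, 2, 2))
  W2 <- effective_weights(matrix(1, 2, 2), c(1, -1))
  expect_equal(W2[, 2], c(-1, -1))
  set.seed(3)
  W <- matrix(rnorm(64), 8, 8)
  d <- sample(c(-1, 1), 8, replace = TRUE)
  We <- effective_weights(W, d)
  # elementwise sign oracle
  expect_true(all(sign(We) == sign(pmax(W, 0)) * rep(d, each = 8)))
})

test_that("the gain matrix K is strictly positive and positive-definite", {
  K0 <- build_K(matrix(0, 3, 3))
  expect_equal(K0, matrix(0.01, 3, 3) + diag(0.01, 3))
  set.seed(4)
  C <- matrix(rnorm(400), 20, 20)
  K <- build_K(C)
  expect_true(all(K >= 0.01))
  ev <- eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("anti-Hebbian weight dynamics decay geometrically and match the
           geometric-series closed form under constant rates", {
  n <- 4
  m <- init_model("ps-hebb", n, seed = 5)
  p <- m$params
  p$gamma <- m$gamma
  lam <- 1 - m$alpha * m$gamma

  # x = 0: W decays by the per-step factor toward 0
  st <- list(x = rep(0, n), W = matrix(2, n, n))
  st1 <- pshebb_step(st, rep(0, n), p, m$alpha, 0, sigma_rec = 0)
  expect_equal(st1$W, lam * matrix(2, n, n))

  # W0 = 0, one step with rates x: W1 = -alpha K o xx', diagonal <= 0
  x <- c(0.5, -1, 2, 0.1)
  st <- list(x = x, W = matrix(0, n, n))
  K <- build_K(p$C)
  W1 <- pshebb_step(st, rep(0, n), p, m$alpha, 0, sigma_rec = 0)$W
  expect_equal(W1, -m$alpha * K * tcrossprod(x))
  expect_true(all(diag(W1) <= 0))

  # constant x held fixed: W -> -(alpha K o xx') / (1 - lam), geometric sum
  Wk <- matrix(0, n, n)
  for (i in 1:40000) Wk <- lam * Wk - m$alpha * (K * tcrossprod(x))
  closed <- -m$alpha * (K * tcrossprod(x)) / (1 - lam)
  expect_equal(Wk, closed, tolerance = 1e-6)
})

test_that("readout is affine", {
  p <- list(W_out = matrix(0, 11, 4), c = rnorm(11))
  expect_equal(readout(rnorm(4), p), p$c)
  set.seed(6)
  p$W_out <- matrix(rnorm(33), 11, 3)
  x <- c(1, -2, 0.5)
  # hand computation at n = 3
  expect_equal(readout(x, p),
               p$W_out[, 1] * 1 + p$W_out[, 2] * -2 + p$W_out[, 3] * 0.5 +
                 p$c)
})

test_that("initialization matches the stated distributions and constraints", {
  m <- init_model("ps-pre", 100, seed = 7)
  expect_equal(sum(m$dale == 1), 80)
  expect_equal(sum(m$dale == -1), 20)
  expect_equal(sum(m$kinetics$facilitating), 50)
  expect_lt(abs(mean(m$params$W == 0) - 0.5), 0.02)
  expect_error(init_model("ps-pre", 55), "divisible")

  m <- init_model("fs-tanh", 500, seed = 8)
  sr <- max(Mod(eigen(m$params$W, only.values = TRUE)$values))
  expect_gt(sr, 0.8) # circular-law scaling: radius ~ 0.9
  expect_lt(sr, 1.0)

  m2 <- init_model("fs-tanh", 500, seed = 8)
  expect_identical(m$params, m2$params)
  expect_error(init_model("lstm", 10), "arg")
})

test_that("run_trial resets state, is deterministic, and guards non-finites", {
  cfg <- quick_cfg()
  tr <- make_trial(cfg, 1, 1.0, NULL, rng_seed = 2)
  m <- init_model("fs-tanh", 12, seed = 9)
  m$params$b <- rep(0, 12)
  m$params$W_in <- matrix(0, 12, 11) # zero-input trial
  out <- run_trial(m, tr, noise = FALSE)
  expect_true(all(out$x == 0)) # phi(0) = 0 fixed point

  m <- init_model("ps-pre", 20, seed = 10)
  o1 <- run_trial(m, tr, noise = TRUE, seed = 33)
  o2 <- run_trial(m, tr, noise = TRUE, seed = 33)
  expect_identical(o1, o2)
  # reset contract: the first recorded step evolves from x = 0, u = 0, a = 1
  st0 <- pspre_synapse_step(rep(0, 20), rep(1, 20), rep(0, 20),
                            m$kinetics, dt = 0.015)
  expect_equal(o1$u[1, ], st0$u)
  expect_equal(o1$a[1, ], st0$a)
})

test_that("batched kernels agree with the single-step reference loop", {
  cfg <- quick_cfg()
  tr <- make_trial(cfg, 4, 1.0, distractor_id = 1, rng_seed = 3)
  b <- stspwm:::build_batch(list(tr))
  for (kind in c("fs-tanh", "fs-relu", "ps-pre", "ps-hebb")) {
    n <- if (kind == "ps-pre") 20 else 12
    m <- init_model(kind, n, seed = 11)
    ref <- run_trial(m, tr, noise = FALSE)
    rec <- run_trials(m, list(tr), noise = FALSE, synaptic = FALSE)
    got <- t(rec$rates$values[1, , ])
    expect_equal(got, ref$x, tolerance = 1e-12,
                 label = paste("rates for", kind))
  }
})

test_that("plasticity-off limits reduce the plastic models to fixed-synapse
           dynamics exactly", {
  cfg <- quick_cfg()
  trials <- list(make_trial(cfg, 0, 1.0, 0, rng_seed = 1),
                 make_trial(cfg, 5, 1.0, NULL, rng_seed = 2))
  b <- stspwm:::build_batch(trials)

  # PS-pre with u, a frozen at 1 equals an FS-relu run on W_eff
  m <- init_model("ps-pre", 20, seed = 12)
  p <- m$params
  frozen <- stspwm:::cpp_pspre_record(p$W, m$dale, p$W_in, p$b,
                                      m$kinetics$tau_a, m$kinetics$tau_u,
                                      m$kinetics$U, b$M, m$alpha, 0.015, 0,
                                      TRUE)
  Weff <- effective_weights(p$W, m$dale)
  fs <- stspwm:::cpp_fs_record(Weff, p$W_in, p$b, b$M, m$alpha, 0, 1L)
  expect_equal(frozen$rates, fs$rates, tolerance = 1e-14)
  expect_true(all(frozen$u == 1) && all(frozen$a == 1))

  # PS-hebb with weights frozen at W0 equals an identity-activation FS run
  m <- init_model("ps-hebb", 8, seed = 13)
  p <- m$params
  W0 <- matrix(rnorm(64, 0, 0.1), 8, 8)
  hb <- stspwm:::cpp_pshebb_record(p$C, p$W_in, p$b, b$M, m$alpha,
                                   1 - m$alpha * m$gamma, 0, FALSE,
                                   matrix(1, 8, 8), TRUE, W0)
  fs <- stspwm:::cpp_fs_record(W0, p$W_in, p$b, b$M, m$alpha, 0, 2L)
  expect_equal(hb$rates, fs$rates, tolerance = 1e-12)
})

test_that("u and a stay in [0, 1] across a noisy fuzz run", {
  cfg <- quick_cfg(delays = c(1.0))
  trials <- make_dataset(cfg, 100, rng_seed = 21)
  m <- init_model("ps-pre", 20, seed = 14)
  m$params$W <- m$params$W * 50 # exaggerate recurrent drive
  rec <- run_trials(m, trials, synaptic = TRUE, noise = TRUE, seed = 3)
  expect_true(all(rec$synaptic$values >= 0))
  expect_true(all(rec$synaptic$values <= 1))
})
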