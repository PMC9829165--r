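# shared fixtures: small task configs and constructed tensors

quick_cfg <- function(delays = 1.0, dt_ms = 15) {
  task_config(dt_ms = dt_ms, delay_set_s = delays)
}

# trials x units x bins tensor with class means `sep` SDs apart at every bin
make_separable_tensor <- function(n_per_class = 12, n_classes = 8,
                                  n_units = 10, n_bins = 4, sep = 10,
                                  seed = 1, session = 1L,
                                  time_s = NULL) {
  set.seed(seed)
  centers <- matrix(rnorm(n_classes * n_units), n_classes, n_units) * sep
  n <- n_per_class * n_classes
  labels <- data.frame(sample_id = rep(0:(n_classes - 1), each = n_per_class),
                       distractor = FALSE, delay_s = 1.0, session = session)
  vals <- array(rnorm(n * n_units * n_bins), c(n, n_units, n_bins))
  for (i in seq_len(n)) {
    vals[i, , ] <- vals[i, , ] + centers[labels$sample_id[i] + 1, ]
  }
  if (is.null(time_s)) time_s <- seq(0.05, by = 0.05, length.out = n_bins)
  trajectory_tensor(vals, time_s, labels, "rates")
}

# random tensor with both distractor conditions present for every sample
make_random_tensor <- function(n_per_cell = 3, n_classes = 5, n_units = 5,
                               n_bins = 6, seed = 1) {
  set.seed(seed)
  conds <- expand.grid(sample_id = 0:(n_classes - 1),
                       distractor = c(FALSE, TRUE))
  labels <- conds[rep(seq_len(nrow(conds)), each = n_per_cell), ]
  labels$delay_s <- 1.0
  labels$session <- 1L
  rownames(labels) <- NULL
  n <- nrow(labels)
  vals <- array(rnorm(n * n_units * n_bins), c(n, n_units, n_bins))
  trajectory_tensor(vals, seq(-0.1, by = 0.05, length.out = n_bins),
                    labels, "rates")
}

mean_silhouette <- function(points, labels) {
  d <- as.matrix(dist(points))
  sil <- vapply(seq_len(nrow(points)), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(nrow(points)) != i])
    b <- min(vapply(unique(labels[!own]), function(cl) {
      mean(d[i, labels == cl])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}
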