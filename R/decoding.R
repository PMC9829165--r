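#' Time-resolved sample decoding
#'
#' Fits one linear support-vector classifier (cost = 1, no feature scaling)
#' per time bin and reports held-out accuracy from stratified k-fold
#' cross-validation, computed per session and then averaged with a standard
#' error across sessions (across folds when only one session is present).
#' Unit subsampling, when requested, is drawn once per session without
#' replacement before fitting.
#'
#' @param tensor A `trajectory_tensor`, typically binned (one delay
#'   condition).
#' @param n_folds Cross-validation folds (default 10).
#' @param cost SVM regularization constant C.
#' @param scale Standardize each feature before fitting (default FALSE,
#'   matching an unscaled linear SVM on firing rates; synaptic variables
#'   live in [0, 1] with tiny variance and need `scale = TRUE` for a
#'   fixed-C classifier to see them).
#' @param subsample_frac Fraction of units to decode from, in (0, 1].
#' @param seed RNG seed (folds and unit subsampling).
#' @param bins Optional integer indices of time bins to decode (default
#'   all).
#' @param label Column of `tensor$labels` to decode (default
#'   `"sample_id"`).
#' @return A `decoding_curve` data.frame: `time`, `accuracy`, `se`, with
#'   attributes `chance` and `n_classes`.
#' @export
decode_sample <- function(tensor, n_folds = 10, cost = 1, scale = FALSE,
                          subsample_frac = 1, seed = 1L, bins = NULL,
                          label = "sample_id") {
  stopifnot(inherits(tensor, "trajectory_tensor"),
            subsample_frac > 0, subsample_frac <= 1)
  set.seed(seed)
  if (is.null(bins)) bins <- seq_along(tensor$time_s)
  sessions <- sort(unique(tensor$labels$session))
  n_units <- dim(tensor$values)[2]
  n_sub <- max(1L, round(subsample_frac * n_units))
  acc_mat <- matrix(NA_real_, length(sessions), length(bins))
  fold_acc_one <- NULL # kept when there is a single session

  for (si in seq_along(sessions)) {
    keep <- which(tensor$labels$session == sessions[si])
    y <- factor(tensor$labels[[label]][keep])
    cls_n <- table(y)
    if (any(cls_n < n_folds)) {
      stop("class ", names(cls_n)[which.min(cls_n)], " has only ",
           min(cls_n), " trials (< ", n_folds, " folds)")
    }
    units <- if (n_sub < n_units) sort(sample.int(n_units, n_sub)) else
      seq_len(n_units)
    folds <- stratified_folds(y, n_folds)
    fa <- matrix(NA_real_, n_folds, length(bins))
    for (bi in seq_along(bins)) {
      X <- tensor$values[keep, units, bins[bi], drop = FALSE]
      dim(X) <- c(length(keep), length(units))
      if (scale) {
        mu <- colMeans(X)
        sdv <- pmax(apply(X, 2, stats::sd), 1e-12)
        X <- sweep(sweep(X, 2, mu), 2, sdv, "/")
      }
      for (f in seq_len(n_folds)) {
        te <- folds == f
        fit <- e1071::svm(X[!te, , drop = FALSE], y[!te], kernel = "linear",
                          cost = cost, scale = FALSE)
        pred <- stats::predict(fit, X[te, , drop = FALSE])
        fa[f, bi] <- mean(pred == y[te])
      }
    }
    acc_mat[si, ] <- colMeans(fa)
    if (length(sessions) == 1) fold_acc_one <- fa
  }
  acc <- colMeans(acc_mat)
  se <- if (length(sessions) > 1) {
    apply(acc_mat, 2, stats::sd) / sqrt(length(sessions))
  } else {
    apply(fold_acc_one, 2, stats::sd) / sqrt(n_folds)
  }
  out <- data.frame(time = tensor$time_s[bins], accuracy = acc, se = se)
  class(out) <- c("decoding_curve", "data.frame")
  attr(out, "n_classes") <- length(unique(tensor$labels[[label]]))
  attr(out, "chance") <- 1 / attr(out, "n_classes")
  out
}

# stratified, seeded, non-overlapping fold assignment
stratified_folds <- function(y, n_folds) {
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

#' Change-from-baseline decoding
#'
#' For each sample type, classifies the population vector at every time bin
#' against the population vectors from a fixed pre-stimulus baseline window
#' (a binary discrimination, 10-fold cross-validated), then averages over
#' sample types and sessions. Sustained departure from the baseline firing
#' pattern shows up as accuracy above 0.5 even when sample identity itself
#' is no longer decodable.
#'
#' @param tensor A binned `trajectory_tensor`.
#' @param baseline_window Two-element numeric, seconds relative to sample
#'   onset (default `c(-0.400, -0.350)`).
#' @param n_folds,cost,seed As in [decode_sample()].
#' @return A `decoding_curve` data.frame (`chance` attribute 0.5).
#' @export
decode_vs_baseline <- function(tensor, baseline_window = c(-0.400, -0.350),
                               n_folds = 10, cost = 1, seed = 1L) {
  stopifnot(inherits(tensor, "trajectory_tensor"))
  set.seed(seed)
  bl <- which(tensor$time_s >= baseline_window[1] &
                tensor$time_s <= baseline_window[2])
  if (length(bl) == 0) {
    stop("baseline window [", baseline_window[1], ", ", baseline_window[2],
         "] s is outside the tensor time axis")
  }
  sessions <- sort(unique(tensor$labels$session))
  nb <- length(tensor$time_s)
  acc_mat <- matrix(NA_real_, length(sessions), nb)
  for (si in seq_along(sessions)) {
    keep <- which(tensor$labels$session == sessions[si])
    samples <- sort(unique(tensor$labels$sample_id[keep]))
    acc_s <- matrix(NA_real_, length(samples), nb)
    for (ci in seq_along(samples)) {
      tr <- keep[tensor$labels$sample_id[keep] == samples[ci]]
      Xb <- apply(tensor$values[tr, , bl, drop = FALSE], c(1, 2), mean)
      y <- factor(rep(c("base", "post"), each = length(tr)))
      folds <- stratified_folds(y, n_folds)
      for (bi in seq_len(nb)) {
        Xt <- tensor$values[tr, , bi, drop = FALSE]
        dim(Xt) <- dim(Xb)
        X <- rbind(Xb, Xt)
        fa <- numeric(n_folds)
        for (f in seq_len(n_folds)) {
          te <- folds == f
          fit <- e1071::svm(X[!te, , drop = FALSE], y[!te],
                            kernel = "linear", cost = cost, scale = FALSE)
          fa[f] <- mean(stats::predict(fit, X[te, , drop = FALSE]) == y[te])
        }
        acc_s[ci, bi] <- mean(fa)
      }
    }
    acc_mat[si, ] <- colMeans(acc_s)
  }
  acc <- colMeans(acc_mat)
  se <- if (length(sessions) > 1) {
    apply(acc_mat, 2, stats::sd) / sqrt(length(sessions))
  } else rep(NA_real_, nb)
  out <- data.frame(time = tensor$time_s, accuracy = acc, se = se)
  class(out) <- c("decoding_curve", "data.frame")
  attr(out, "n_classes") <- 2L
  attr(out, "chance") <- 0.5
  out
}
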