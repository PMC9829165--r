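#' Brain-similarity score between two sets of decoding curves
#'
#' Pearson correlation between a model's and a reference's time-resolved
#' decoding-accuracy curves, computed per delay length and averaged
#' (unweighted) over delays. The model curve is linearly interpolated onto
#' the reference time grid first. A constant curve has no defined
#' correlation; such delays are dropped with a warning.
#'
#' @param model_curves,reference_curves Named lists of `decoding_curve`
#'   data.frames, keyed by delay (names must match).
#' @return List of class `similarity_score`: `per_delay` (named numeric,
#'   possibly with NAs) and `score` (mean over defined delays).
#' @export
brain_similarity <- function(model_curves, reference_curves) {
  delays <- intersect(names(model_curves), names(reference_curves))
  if (length(delays) == 0) stop("no common delay conditions between curves")
  r <- vapply(delays, function(d) {
    mc <- model_curves[[d]]
    rc <- reference_curves[[d]]
    m_on_ref <- stats::approx(mc$time, mc$accuracy, xout = rc$time,
                              rule = 2)$y
    if (stats::sd(m_on_ref) < 1e-12 || stats::sd(rc$accuracy) < 1e-12) {
      return(NA_real_)
    }
    stats::cor(m_on_ref, rc$accuracy)
  }, numeric(1))
  if (anyNA(r)) {
    warning("constant decoding curve for delay(s) ",
            paste(delays[is.na(r)], collapse = ", "),
            "; excluded from the similarity score")
  }
  structure(list(per_delay = r, score = mean(r, na.rm = TRUE)),
            class = "similarity_score")
}

#' @export
print.similarity_score <- function(x, ...) {
  cat("brain-similarity score:", round(x$score, 4), "\n")
  invisible(x)
}

#' Randomly ablate recurrent synapses
#'
#' Permanently zeroes a uniformly random subset of exactly
#' `floor(fraction * n^2)` recurrent weight entries for evaluation (no
#' retraining): entries of W for the fixed-synapse models and of the raw
#' non-negative matrix for PS-pre; for PS-hebb the corresponding entries of
#' the gain matrix K are masked so those synapses can never develop weight.
#' Input and readout weights are untouched.
#'
#' @param model A `wm_model`.
#' @param fraction Fraction of recurrent synapses to ablate, in `[0, 1]`.
#' @param seed RNG seed for the ablation pattern.
#' @return The ablated model.
#' @export
ablate_synapses <- function(model, fraction, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  set.seed(seed)
  n2 <- model$n^2
  k <- floor(fraction * n2)
  if (k == 0) return(model)
  hit <- sample.int(n2, k)
  if (model$kind == "ps-hebb") {
    kmask <- model$kmask %||% matrix(1, model$n, model$n)
    kmask[hit] <- 0
    model$kmask <- kmask
  } else {
    model$params$W[hit] <- 0
    model$ablated <- sort(hit)
  }
  model
}

robustness_score <- function(levels, perf) {
  if (sum(levels) == 0) return(mean(perf))
  sum(levels * perf) / sum(levels)
}

#' Structural robustness profile
#'
#' Task accuracy as a function of the fraction of randomly ablated
#' recurrent synapses, averaged over ablation seeds, reduced to a single
#' noise-weighted score `sum(f_i * perf_i) / sum(f_i)` (so a model whose
#' performance never degrades scores 1; performance at high ablation counts
#' most).
#'
#' @param model Trained `wm_model`.
#' @param trials Evaluation trials.
#' @param fractions Ascending ablation fractions including 0.
#' @param n_seeds Ablation patterns averaged per fraction (default 3).
#' @param seed Base RNG seed.
#' @return List of class `robustness_profile`: `profile` data.frame
#'   (`noise`, `performance`), `score`.
#' @export
structural_robustness <- function(model, trials,
                                  fractions = seq(0, 0.9, by = 0.1),
                                  n_seeds = 3, seed = 1L) {
  stopifnot(!is.unsorted(fractions), fractions[1] == 0)
  perf <- vapply(seq_along(fractions), function(i) {
    f <- fractions[i]
    accs <- vapply(seq_len(n_seeds), function(s) {
      ab <- ablate_synapses(model, f, seed = seed + 1000L * i + s)
      evaluate_accuracy(ab, trials, kmask = ab$kmask,
                        seed = seed + s)$accuracy
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  structure(list(profile = data.frame(noise = fractions,
                                      performance = perf),
                 score = robustness_score(fractions, perf),
                 type = "structural"),
            class = "robustness_profile")
}

#' Process-noise robustness profile
#'
#' Task accuracy with the process-noise SD set to each value in `sigmas`
#' (the trained baseline should be included), reduced to the same
#' noise-weighted score as [structural_robustness()].
#'
#' @param model Trained `wm_model`.
#' @param trials Evaluation trials.
#' @param sigmas Ascending process-noise SDs.
#' @param seed RNG seed.
#' @return A `robustness_profile`.
#' @export
process_noise_robustness <- function(model, trials,
                                     sigmas = c(0.05, 0.1, 0.2, 0.4),
                                     seed = 1L) {
  stopifnot(!is.unsorted(sigmas), all(sigmas >= 0))
  perf <- vapply(seq_along(sigmas), function(i) {
    evaluate_accuracy(model, trials, sigma_rec = sigmas[i],
                      seed = seed + i)$accuracy
  }, numeric(1))
  structure(list(profile = data.frame(noise = sigmas, performance = perf),
                 score = robustness_score(sigmas, perf),
                 type = "process"),
            class = "robustness_profile")
}

#' @export
print.robustness_profile <- function(x, ...) {
  cat(sprintf("%s robustness score: %.4f\n", x$type, x$score))
  print(x$profile, row.names = FALSE)
  invisible(x)
}

#' Project epoch-averaged population activity to three LDA dimensions
#'
#' Time-averages each trial's population vector within each requested epoch
#' window and projects it onto the first three linear discriminants of the
#' sample labels, fit per epoch. Requires at least four classes. If the
#' within-class scatter is singular, a small shrinkage ridge is added and
#' reported via the `shrunk` attribute.
#'
#' @param tensor A `trajectory_tensor`.
#' @param epochs Named list of two-element time windows in seconds, e.g.
#'   `list(sample = c(0, 0.5), late_delay = c(3.5, 4.0))`.
#' @return Named list (one entry per epoch) of lists with `points`
#'   (trials x 3), `labels`, `scalings`.
#' @export
lda_project <- function(tensor,
                        epochs = list(sample = c(0, 0.5))) {
  y <- factor(tensor$labels$sample_id)
  if (nlevels(y) < 4) stop("3D LDA projection needs at least 4 classes")
  lapply(epochs, function(w) {
    sel <- tensor$time_s >= w[1] & tensor$time_s <= w[2]
    if (!any(sel)) stop("epoch window [", w[1], ", ", w[2],
                        "] s outside the tensor time axis")
    X <- apply(tensor$values[, , sel, drop = FALSE], c(1, 2), mean)
    fit <- tryCatch(MASS::lda(X, grouping = y),
                    error = function(e) NULL)
    shrunk <- FALSE
    if (is.null(fit)) {
      # shrinkage fallback: generalized eigenproblem on ridged scatter
      shrunk <- TRUE
      mu <- colMeans(X)
      Sw <- matrix(0, ncol(X), ncol(X))
      Sb <- matrix(0, ncol(X), ncol(X))
      for (cl in levels(y)) {
        Xi <- X[y == cl, , drop = FALSE]
        ci <- colMeans(Xi)
        Sw <- Sw + crossprod(sweep(Xi, 2, ci))
        Sb <- Sb + nrow(Xi) * tcrossprod(ci - mu)
      }
      Sw <- Sw + diag(1e-6 * mean(diag(Sw)) + 1e-12, ncol(X))
      eg <- eigen(solve(Sw, Sb))
      scal <- Re(eg$vectors[, 1:3, drop = FALSE])
      pts <- X %*% scal
    } else {
      scal <- fit$scaling[, 1:3, drop = FALSE]
      pts <- scale(X, center = colMeans(X), scale = FALSE) %*% scal
    }
    structure(list(points = pts, labels = y, scalings = scal),
              shrunk = shrunk)
  })
}

#' Orthogonal Procrustes alignment
#'
#' Finds the orthogonal matrix R minimizing `||A - B R||_F` over centered
#' point sets (rotation/reflection only, no scaling) and returns B aligned
#' onto A.
#'
#' @param A,B Matched point sets (points x dims).
#' @return List: `rotation` (dims x dims orthogonal), `B_aligned`,
#'   `residual` (Frobenius norm after alignment).
#' @export
procrustes_align <- function(A, B) {
  stopifnot(all(dim(A) == dim(B)))
  Ac <- scale(A, scale = FALSE)
  Bc <- scale(B, scale = FALSE)
  Mx <- crossprod(Bc, Ac)
  if (max(abs(Mx)) < 1e-300) {
    warning("degenerate (zero) configuration; returning identity rotation")
    R <- diag(ncol(A))
  } else {
    sv <- svd(Mx)
    R <- sv$u %*% t(sv$v)
  }
  Ba <- Bc %*% R
  list(rotation = R, B_aligned = Ba,
       residual = norm(Ac - Ba, "F"))
}

#' Hyperparameter sweep driver
#'
#' Trains one model per grid cell (kind x hidden size x activity
#' regularization x weight decay) on a supplied dataset and records task
#' accuracy, robustness scores and, when reference curves are given,
#' brain-similarity. Results are appended to `out_csv` row by row, and
#' cells already present in that file are skipped, so an interrupted sweep
#' resumes where it stopped. PS-hebb hidden sizes are conventionally the
#' other models' divided by 10 (supply them that way in `grid`).
#'
#' @param grid data.frame with columns `kind`, `hidden`, `activity_reg`,
#'   `weight_decay`.
#' @param train_trials,test_trials Datasets shared across cells.
#' @param reference_curves Optional named list of per-delay reference
#'   decoding curves for the similarity score.
#' @param decode_delay_s,decode_bin_ms Decoding settings for the model
#'   curves used in the similarity score.
#' @param out_csv Optional path for incremental results.
#' @param max_epochs,seed Training budget and base seed.
#' @param robustness_fractions,robustness_sigmas Noise grids.
#' @return data.frame with one row per completed cell.
#' @export
sweep_models <- function(grid, train_trials, test_trials,
                         reference_curves = NULL,
                         decode_delay_s = NULL, decode_bin_ms = 60,
                         out_csv = NULL, max_epochs = 20, seed = 1L,
                         robustness_fractions = c(0, 0.25, 0.5),
                         robustness_sigmas = c(0.05, 0.1, 0.2)) {
  stopifnot(all(c("kind", "hidden", "activity_reg", "weight_decay") %in%
                  names(grid)), nrow(grid) >= 1)
  done <- NULL
  if (!is.null(out_csv) && file.exists(out_csv)) {
    done <- utils::read.csv(out_csv)
  }
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    key <- paste(g$kind, g$hidden, g$activity_reg, g$weight_decay)
    if (!is.null(done) &&
        key %in% paste(done$kind, done$hidden, done$activity_reg,
                       done$weight_decay)) {
      rows[[i]] <- done[paste(done$kind, done$hidden, done$activity_reg,
                              done$weight_decay) == key, ][1, ]
      next
    }
    row <- tryCatch({
      m <- init_model(as.character(g$kind), g$hidden, seed = seed + i)
      cfg <- train_config(as.character(g$kind),
                          activity_reg = g$activity_reg,
                          weight_decay = g$weight_decay,
                          max_epochs = max_epochs, seed = seed + i)
      m <- train(m, train_trials, cfg)
      ev <- evaluate_accuracy(m, test_trials, seed = seed + i)
      sr <- structural_robustness(m, test_trials,
                                  fractions = robustness_fractions,
                                  n_seeds = 2, seed = seed + i)
      pr <- process_noise_robustness(m, test_trials,
                                     sigmas = robustness_sigmas,
                                     seed = seed + i)
      sim <- NA_real_
      if (!is.null(reference_curves)) {
        labs <- dataset_labels(test_trials)
        mcurves <- list()
        for (d in names(reference_curves)) {
          dsel <- which(abs(labs$delay_s - as.numeric(d)) < 1e-9)
          if (length(dsel) == 0) next
          tens <- run_trials(m, test_trials[dsel], seed = seed + i)$rates
          mcurves[[d]] <- decode_sample(bin_rates(tens, decode_bin_ms),
                                        seed = seed + i)
        }
        if (length(mcurves) > 0) {
          sim <- brain_similarity(mcurves, reference_curves)$score
        }
      }
      data.frame(kind = as.character(g$kind), hidden = g$hidden,
                 activity_reg = g$activity_reg,
                 weight_decay = g$weight_decay,
                 accuracy = ev$accuracy,
                 acc_distractor = unname(ev$by_distractor["distractor"]),
                 acc_no_distractor = unname(ev$by_distractor["no_distractor"]),
                 structural_robustness = sr$score,
                 process_robustness = pr$score,
                 brain_similarity = sim,
                 failed = FALSE)
    }, error = function(e) {
      data.frame(kind = as.character(g$kind), hidden = g$hidden,
                 activity_reg = g$activity_reg,
                 weight_decay = g$weight_decay,
                 accuracy = NA_real_, acc_distractor = NA_real_,
                 acc_no_distractor = NA_real_,
                 structural_robustness = NA_real_,
                 process_robustness = NA_real_, brain_similarity = NA_real_,
                 failed = TRUE)
    })
    rows[[i]] <- row
    if (!is.null(out_csv)) {
      utils::write.table(row, out_csv, sep = ",", row.names = FALSE,
                         col.names = !file.exists(out_csv), append =
                           file.exists(out_csv))
    }
  }
  do.call(rbind, rows)
}

#' PS-hebb hidden sizes matched to the other families' grid
#'
#' The plastic-weight model carries n^2 synaptic state variables, so its
#' sweep uses the other models' hidden sizes divided by 10, rounded to the
#' nearest integer.
#' @param fs_sizes Integer vector of fixed-synapse hidden sizes.
#' @return Integer vector of matched PS-hebb sizes.
#' @export
pshebb_hidden_sizes <- function(fs_sizes) as.integer(round(fs_sizes / 10))

#' Best model kind per sweep cell
#'
#' Reduces a sweep table to the winning model kind in each
#' (hidden, activity_reg) cell at fixed weight decay, by the given metric.
#' @param sweep_tab Output of [sweep_models()].
#' @param metric Column to maximize.
#' @param weight_decay Cell plane to select.
#' @return data.frame `hidden`, `activity_reg`, `best_kind`, `value`.
#' @export
best_per_cell <- function(sweep_tab, metric = "brain_similarity",
                          weight_decay = 1e-4) {
  tab <- sweep_tab[sweep_tab$weight_decay == weight_decay &
                     !sweep_tab$failed, ]
  cells <- unique(tab[, c("hidden", "activity_reg")])
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- tab[tab$hidden == cells$hidden[i] &
                 tab$activity_reg == cells$activity_reg[i], ]
    j <- which.max(sub[[metric]])
    data.frame(hidden = cells$hidden[i],
               activity_reg = cells$activity_reg[i],
               best_kind = sub$kind[j], value = sub[[metric]][j])
  })
  do.call(rbind, out)
}
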