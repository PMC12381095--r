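# Linear-discriminant location decoding: shrinkage LDA, class-balanced
# folds, super-trial averaging, within-phase and cross-phase decoding, and
# the swap-with-chance cluster permutation test.

#' Decoder configuration
#'
#' @param n_folds Cross-validation folds (default 10).
#' @param super_trial_size Trials averaged per super-trial (default 4, the
#'   per-object repetition count of the paradigm).
#' @param shrinkage Regularization of the pooled covariance toward its
#'   diagonal: a value in `[0, 1]`, or `NULL` (default) for automatic
#'   analytic (Ledoit-Wolf-style) shrinkage.
#' @param n_repeats Repetitions of the fold/super-trial randomization whose
#'   accuracies are averaged (default 10).
#' @param seed Integer seed.
#' @return A list of class `decoder_config`.
#' @export
decoder_config <- function(n_folds = 10, super_trial_size = 4,
                           shrinkage = NULL, n_repeats = 10, seed = 1L) {
  stopifnot(n_folds >= 2, super_trial_size >= 1, n_repeats >= 1)
  if (!is.null(shrinkage)) stopifnot(shrinkage >= 0, shrinkage <= 1)
  structure(list(n_folds = as.integer(n_folds),
                 super_trial_size = as.integer(super_trial_size),
                 shrinkage = shrinkage, n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed)),
            class = "decoder_config")
}

# Analytic shrinkage intensity toward the diagonal target
# (Schafer-Strimmer): lambda* = sum var(s_ij) / sum s_ij^2 over i != j.
analytic_shrinkage <- function(Xc, n_eff) {
  n <- nrow(Xc)
  p <- ncol(Xc)
  if (n < 4) return(1)
  S <- crossprod(Xc) / n_eff
  # var(s_ij) ~ n/(n-1)^3 * sum_k (w_kij - mean_k w_kij)^2, w_kij = x_ki x_kj
  W2 <- crossprod(Xc^2)
  Wm <- crossprod(Xc) / n
  varS <- (n / ((n - 1)^3)) * (W2 - n * Wm^2)
  off <- !diag(TRUE, p)
  denom <- sum(S[off]^2)
  if (denom <= 0) return(1)
  min(1, max(0, sum(varS[off]) / denom))
}

#' Fit a shrinkage-regularized linear discriminant classifier
#'
#' Class means plus a pooled within-class covariance regularized toward its
#' diagonal: `Sigma_reg = (1 - lambda) * Sigma + lambda * diag(Sigma)`. With
#' `lambda = 1` the classifier reduces to a diagonal-covariance (naive)
#' discriminant; with one trial per class and `lambda = 1` it is a
#' nearest-class-mean classifier.
#'
#' @param features `trials x features` numeric matrix.
#' @param labels Class label per trial (at least 2 classes, each with at
#'   least 1 trial).
#' @param shrinkage `lambda` in `[0, 1]`, or `NULL` for automatic analytic
#'   shrinkage.
#' @return An `lda_model` with `class_means`, `pooled_covariance`,
#'   `class_priors`, `classes`, `lambda`.
#' @export
lda_fit <- function(features, labels, shrinkage = NULL) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes", call. = FALSE)
  k <- length(classes)
  n <- nrow(features)
  p <- ncol(features)
  means <- matrix(0, k, p, dimnames = list(classes, colnames(features)))
  Xc <- features
  for (cc in classes) {
    rows <- labels == cc
    means[cc, ] <- colMeans(features[rows, , drop = FALSE])
    Xc[rows, ] <- sweep(features[rows, , drop = FALSE], 2, means[cc, ])
  }
  n_eff <- max(n - k, 1)
  S <- crossprod(Xc) / n_eff
  lambda <- shrinkage %||% analytic_shrinkage(Xc, n_eff)
  S_reg <- (1 - lambda) * S + lambda * diag(diag(S), p)
  # tiny ridge keeps degenerate (e.g. noiseless) data classifiable without
  # affecting well-conditioned fits
  S_reg <- S_reg + diag(1e-12 + 1e-10 * mean(abs(diag(S_reg))), p)
  ok <- tryCatch({
    chol(S_reg)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    stop("regularized covariance is singular; increase `shrinkage`",
         call. = FALSE)
  }
  priors <- as.numeric(table(factor(labels, levels = classes))) / n
  structure(list(class_means = means, pooled_covariance = S_reg,
                 class_priors = priors, classes = classes, lambda = lambda),
            class = "lda_model")
}

#' Predict class labels with a fitted discriminant model
#'
#' Argmax of the linear discriminant scores
#' `x' Sigma^-1 mu_k - mu_k' Sigma^-1 mu_k / 2 + log pi_k`; exact ties break
#' to the lowest class index.
#'
#' @param model An `lda_model` from [lda_fit()].
#' @param features `trials x features` matrix with the model's feature
#'   dimension.
#' @return Character vector of predicted labels.
#' @export
lda_predict <- function(model, features) {
  features <- as.matrix(features)
  if (ncol(features) != ncol(model$class_means)) {
    stop("feature dimension (", ncol(features), ") does not match model (",
         ncol(model$class_means), ")", call. = FALSE)
  }
  scores <- lda_scores(model, features)
  model$classes[apply(scores, 1, which.max)]  # which.max: lowest index wins
}

# Discriminant scores (trials x classes).
lda_scores <- function(model, features) {
  W <- solve(model$pooled_covariance, t(model$class_means))   # p x k
  lin <- features %*% W
  const <- -0.5 * colSums(t(model$class_means) * W) + log(model$class_priors)
  sweep(lin, 2, const, `+`)
}

#' Class-balanced cross-validation folds
#'
#' Subsamples every class to the largest common count divisible by
#' `n_folds`, then assigns equal numbers of each class to every fold, so the
#' empirical chance level is exactly `1 / n_classes` in both training and
#' test sets. Trials dropped by the balancing get `NA`.
#'
#' @param labels Class label per trial.
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold assignments (`1..n_folds` or `NA`).
#' @export
build_balanced_folds <- function(labels, n_folds, seed) {
  labels <- as.character(labels)
  counts <- table(labels)
  per_fold <- floor(min(counts) / n_folds)
  if (per_fold < 1) {
    stop("smallest class has ", min(counts), " trials; need at least ",
         n_folds, call. = FALSE)
  }
  used <- per_fold * n_folds
  folds <- rep(NA_integer_, length(labels))
  with_seed(seed, {
    for (cc in names(counts)) {
      idx <- sample_vec(which(labels == cc), used)
      folds[idx] <- rep(seq_len(n_folds), each = per_fold)
    }
  })
  folds
}

#' Average same-class trials into super-trials
#'
#' Each super-trial is the mean of `k` distinct same-class trials; leftovers
#' smaller than `k` are dropped. Averaging must stay within one side of a
#' cross-validation split (the caller is responsible for passing only
#' training or only test trials). With `k = 1` the input is returned
#' unchanged.
#'
#' @param features `trials x features` matrix.
#' @param labels Class label per trial.
#' @param k Trials per super-trial.
#' @param seed Integer seed for the random grouping.
#' @return A list with `features` and `labels` of the super-trials, plus
#'   `groups`, the list of trial-index groups averaged.
#' @export
make_super_trials <- function(features, labels, k, seed) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  if (k == 1) {
    return(list(features = features, labels = labels,
                groups = as.list(seq_along(labels))))
  }
  counts <- table(labels)
  if (k > max(counts)) {
    stop("`k` (", k, ") exceeds every class's trial count", call. = FALSE)
  }
  groups <- list()
  with_seed(seed, {
    for (cc in names(counts)) {
      idx <- sample_vec(which(labels == cc))
      n_g <- floor(length(idx) / k)
      if (n_g == 0) next
      for (g in seq_len(n_g)) {
        groups[[length(groups) + 1]] <- idx[((g - 1) * k + 1):(g * k)]
      }
    }
  })
  out_feat <- do.call(rbind, lapply(groups, function(g) {
    colMeans(features[g, , drop = FALSE])
  }))
  out_lab <- vapply(groups, function(g) labels[g[1]], character(1))
  list(features = out_feat, labels = out_lab, groups = groups)
}

# Group trial indices into super-trial index groups (no features yet), used
# when the same grouping is applied across all time points.
super_trial_groups <- function(idx, labels, k, seed) {
  if (k == 1) return(as.list(idx))
  groups <- list()
  with_seed(seed, {
    for (cc in unique(labels)) {
      sub <- sample_vec(idx[labels[idx] == cc])
      n_g <- floor(length(sub) / k)
      for (g in seq_len(n_g)) {
        groups[[length(groups) + 1]] <- sub[((g - 1) * k + 1):(g * k)]
      }
    }
  })
  groups
}

# Average an (trial x channel x time) array over trial-index groups,
# returning (group x channel x time).
average_groups <- function(data, groups) {
  out <- array(0, dim = c(length(groups), dim(data)[2], dim(data)[3]))
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    out[i, , ] <- if (length(g) == 1) data[g, , ] else
      colMeans(data[g, , , drop = FALSE], dims = 1)
  }
  out
}

as_epochs_list <- function(x) {
  if (inherits(x, "eeg_epochs")) list(x) else x
}

#' Within-phase location decoding over time
#'
#' Per participant and time point: class-balanced folds, super-trial
#' averaging within each fold side, shrinkage-LDA training on the training
#' folds and accuracy on the held-out fold, averaged over folds and
#' `n_repeats` randomizations. Fold and super-trial assignments are drawn
#' once per repeat and reused across time points.
#'
#' @param epochs A single [eeg_epochs()] object or a list of them (one per
#'   participant), each with a `location` metadata column.
#' @param config A [decoder_config()] object.
#' @return A `decoding_timecourse`: `accuracy` (participant x time matrix),
#'   `times`, `chance_level` (`1 / n_classes`), `kind = "within"`.
#' @export
decode_within_phase <- function(epochs, config = decoder_config()) {
  stopifnot(inherits(config, "decoder_config"))
  epochs_list <- as_epochs_list(epochs)
  n_p <- length(epochs_list)
  times <- epochs_list[[1]]$times
  n_classes <- length(unique(epochs_list[[1]]$metadata$location))
  acc <- matrix(NA_real_, n_p, length(times))
  for (p in seq_len(n_p)) {
    e <- epochs_list[[p]]
    labels <- as.character(e$metadata$location)
    acc[p, ] <- decode_participant_within(e$data, labels, config,
                                          seed_key = p)
  }
  new_decoding_timecourse(acc, times, 1 / n_classes, "within", config)
}

decode_participant_within <- function(data, labels, config, seed_key) {
  n_time <- dim(data)[3]
  acc_rep <- matrix(0, config$n_repeats, n_time)
  for (r in seq_len(config$n_repeats)) {
    folds <- build_balanced_folds(
      labels, config$n_folds, derive_seed(config$seed, "folds", seed_key, r))
    fold_res <- matrix(NA_real_, config$n_folds, n_time)
    for (f in seq_len(config$n_folds)) {
      train_idx <- which(!is.na(folds) & folds != f)
      test_idx <- which(!is.na(folds) & folds == f)
      g_train <- super_trial_groups(
        train_idx, labels, config$super_trial_size,
        derive_seed(config$seed, "st-train", seed_key, r, f))
      g_test <- super_trial_groups(
        test_idx, labels, config$super_trial_size,
        derive_seed(config$seed, "st-test", seed_key, r, f))
      if (length(g_test) == 0 || length(g_train) == 0) next
      tr_data <- average_groups(data, g_train)
      te_data <- average_groups(data, g_test)
      tr_lab <- vapply(g_train, function(g) labels[g[1]], character(1))
      te_lab <- vapply(g_test, function(g) labels[g[1]], character(1))
      for (t in seq_len(n_time)) {
        model <- lda_fit(tr_data[, , t], tr_lab, config$shrinkage)
        pred <- lda_predict(model, te_data[, , t])
        fold_res[f, t] <- mean(pred == te_lab)
      }
    }
    acc_rep[r, ] <- colMeans(fold_res, na.rm = TRUE)
  }
  colMeans(acc_rep)
}

new_decoding_timecourse <- function(acc, times, chance, kind, config,
                                    train_window = NULL, test_window = NULL) {
  structure(list(accuracy = acc, times = times, chance_level = chance,
                 kind = kind, config = config, train_window = train_window,
                 test_window = test_window),
            class = "decoding_timecourse")
}

#' @export
print.decoding_timecourse <- function(x, ...) {
  cat("<decoding_timecourse> (", x$kind, ") ", nrow(x$accuracy),
      " participants x ", ncol(x$accuracy), " time points, chance ",
      format(x$chance_level), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.decoding_timecourse <- function(x, ...) {
  tibble(
    participant = rep(seq_len(nrow(x$accuracy)), times = ncol(x$accuracy)),
    time = rep(x$times, each = nrow(x$accuracy)),
    accuracy = as.vector(x$accuracy)
  )
}

#' @export
glance.decoding_timecourse <- function(x, ...) {
  tibble(kind = x$kind, n_participants = nrow(x$accuracy),
         n_times = ncol(x$accuracy), chance_level = x$chance_level,
         mean_accuracy = mean(x$accuracy),
         peak_accuracy = max(colMeans(x$accuracy)))
}

#' Cross-phase location decoding
#'
#' Trains on one phase inside its designated window and tests on the other
#' phase's window, in both directions, per participant. Training happens at
#' each training time point; the resulting accuracies are averaged over
#' training time, yielding accuracy as a function of test time within the
#' window. The reported timecourse is the mean of the two directions on a
#' common within-window time axis (ms relative to window onset), so swapping
#' the two phases leaves the result unchanged. Class balancing and
#' super-trial averaging are applied per phase and direction; there is no
#' fold structure because training and test data come from different phases.
#'
#' @param epochs_a,epochs_b [eeg_epochs()] objects or lists of them (same
#'   participants, same order).
#' @param window_a,window_b `c(from, to)` ms windows of equal length for the
#'   two phases.
#' @param config A [decoder_config()] object.
#' @return A `decoding_timecourse` with `kind = "cross"`; `times` are ms
#'   relative to window onset.
#' @export
decode_cross_phase <- function(epochs_a, window_a, epochs_b, window_b,
                               config = decoder_config()) {
  stopifnot(inherits(config, "decoder_config"))
  la <- as_epochs_list(epochs_a)
  lb <- as_epochs_list(epochs_b)
  if (length(la) != length(lb)) {
    stop("the two phases must have the same participants", call. = FALSE)
  }
  idx_a <- time_window_idx(la[[1]]$times, window_a)
  idx_b <- time_window_idx(lb[[1]]$times, window_b)
  n_t <- min(length(idx_a), length(idx_b))
  idx_a <- idx_a[seq_len(n_t)]
  idx_b <- idx_b[seq_len(n_t)]
  rel_times <- la[[1]]$times[idx_a] - la[[1]]$times[idx_a[1]]

  n_p <- length(la)
  n_classes <- length(unique(la[[1]]$metadata$location))
  acc <- matrix(NA_real_, n_p, n_t)
  for (p in seq_len(n_p)) {
    # seed keys are phase-name based, so swapping the argument order gives a
    # byte-identical result
    key_ab <- paste(la[[p]]$phase, lb[[p]]$phase, p, sep = "|")
    key_ba <- paste(lb[[p]]$phase, la[[p]]$phase, p, sep = "|")
    a1 <- decode_direction(la[[p]], idx_a, lb[[p]], idx_b, config, key_ab)
    a2 <- decode_direction(lb[[p]], idx_b, la[[p]], idx_a, config, key_ba)
    acc[p, ] <- (a1 + a2) / 2
  }
  new_decoding_timecourse(acc, rel_times, 1 / n_classes, "cross", config,
                          train_window = window_a, test_window = window_b)
}

# One direction: train on `train` epochs at each time in train_idx, test on
# `test` epochs across test_idx; accuracy averaged over training times, as a
# function of test time (relative sample index).
decode_direction <- function(train, train_idx, test, test_idx, config,
                             seed_key) {
  tr_labels <- as.character(train$metadata$location)
  te_labels <- as.character(test$metadata$location)
  acc_rep <- matrix(0, config$n_repeats, length(test_idx))
  for (r in seq_len(config$n_repeats)) {
    bal_tr <- balance_classes(tr_labels,
                              derive_seed(config$seed, "bal-tr", seed_key, r))
    bal_te <- balance_classes(te_labels,
                              derive_seed(config$seed, "bal-te", seed_key, r))
    g_tr <- super_trial_groups(bal_tr, tr_labels, config$super_trial_size,
                               derive_seed(config$seed, "xst-tr", seed_key, r))
    g_te <- super_trial_groups(bal_te, te_labels, config$super_trial_size,
                               derive_seed(config$seed, "xst-te", seed_key, r))
    tr_data <- average_groups(train$data, g_tr)
    te_data <- average_groups(test$data, g_te)
    tr_lab <- vapply(g_tr, function(g) tr_labels[g[1]], character(1))
    te_lab <- vapply(g_te, function(g) te_labels[g[1]], character(1))
    acc_t <- matrix(0, length(train_idx), length(test_idx))
    for (i in seq_along(train_idx)) {
      model <- lda_fit(tr_data[, , train_idx[i]], tr_lab, config$shrinkage)
      for (j in seq_along(test_idx)) {
        pred <- lda_predict(model, te_data[, , test_idx[j]])
        acc_t[i, j] <- mean(pred == te_lab)
      }
    }
    acc_rep[r, ] <- colMeans(acc_t)
  }
  colMeans(acc_rep)
}

# Subsample to equal class counts; returns kept indices.
balance_classes <- function(labels, seed) {
  counts <- table(labels)
  m <- min(counts)
  with_seed(seed, {
    unlist(lapply(names(counts), function(cc) {
      sample_vec(which(labels == cc), m)
    }), use.names = FALSE)
  })
}

#' Cluster permutation test of decoding accuracy against chance
#'
#' Builds the null by randomly exchanging, within each participant and time
#' point, the observed accuracy with the chance constant between the two
#' comparison vectors (equivalent to flipping the sign of
#' `accuracy - chance` per cell), applies one-sided paired t-tests
#' (accuracy above chance) at each time point, and thresholds observed
#' cluster lengths at the null's `null_percentile` max-cluster-size, as in
#' the ERP contrast. When the number of distinct swap patterns
#' (`2^(participants x time points)`) does not exceed `n_permutations`, the
#' null is enumerated exhaustively.
#'
#' @param timecourse A `decoding_timecourse`.
#' @param config A [cluster_config()] object; defaults to one-sided.
#' @param chance Chance level; defaults to the timecourse's
#'   (`1 / n_classes`).
#' @return A `cluster_result`.
#' @export
decoding_cluster_test <- function(timecourse,
                                  config = cluster_config(sidedness = "one"),
                                  chance = timecourse$chance_level) {
  stopifnot(inherits(timecourse, "decoding_timecourse"),
            inherits(config, "cluster_config"))
  D <- timecourse$accuracy - chance
  cluster_test_core(D, timecourse$times, config, flip = "cell")
}

#' Write a decoding timecourse to CSV
#'
#' Long format: participant, time, accuracy.
#'
#' @param timecourse A `decoding_timecourse`.
#' @param path Output path.
#' @export
write_decoding_timecourse <- function(timecourse, path) {
  readr::write_csv(tidy(timecourse), path)
  invisible(path)
}
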