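# Condition-mean ERPs over an electrode cluster and cluster-based
# permutation contrasts between conditions.

#' Configuration for cluster-based permutation tests
#'
#' @param alpha Pointwise significance level (default 0.05, strict `<`).
#' @param n_permutations Number of label permutations (default 10000). When
#'   the number of distinct relabelings (`2^n` participants) does not exceed
#'   this, the test switches to exhaustive enumeration automatically.
#' @param min_cluster_length Minimum number of contiguous significant time
#'   points for a cluster (default 2: clusters must contain more than one
#'   significant p-value).
#' @param null_percentile Percentile of the null max-cluster-size
#'   distribution used as the significance threshold (default 0.95,
#'   nearest-rank method; observed clusters must strictly exceed it).
#' @param sidedness `"two"` or `"one"` (one-sided tests the first condition /
#'   accuracy being larger).
#' @param seed Integer seed for the permutation draws.
#' @return A list of class `cluster_config`.
#' @export
cluster_config <- function(alpha = 0.05, n_permutations = 10000,
                           min_cluster_length = 2, null_percentile = 0.95,
                           sidedness = c("two", "one"), seed = 1L) {
  sidedness <- match.arg(sidedness)
  stopifnot(alpha > 0, alpha < 1, n_permutations >= 1,
            min_cluster_length >= 2,
            null_percentile > 0, null_percentile < 1)
  structure(list(alpha = alpha, n_permutations = as.integer(n_permutations),
                 min_cluster_length = as.integer(min_cluster_length),
                 null_percentile = null_percentile, sidedness = sidedness,
                 seed = as.integer(seed)),
            class = "cluster_config")
}

#' Condition-mean ERP matrix over an electrode cluster
#'
#' Averages each participant's epochs over trials within condition and over
#' the electrode cluster, restricted to the analysis window.
#'
#' @param epochs_list List of [eeg_epochs()] objects, one per participant,
#'   each with a `condition` metadata column.
#' @param cluster Channel labels to average over (default the left-parietal
#'   cluster `Pz`, `P1`, `P3`, `P5`).
#' @param window Analysis window in ms (default `c(0, 1200)`).
#' @param conditions Conditions to keep (default: all conditions present in
#'   every participant). Every participant must have at least one trial per
#'   condition.
#' @param by Metadata column holding the condition labels (default
#'   `"condition"`); e.g. `"probing_count"` for the probing analysis.
#' @return An `erp_matrix`: list with `values` (participant x condition x
#'   time array, microvolts), `times`, `conditions`, `cluster`.
#' @export
condition_erp <- function(epochs_list, cluster = parietal_cluster(),
                          window = c(0, 1200), conditions = NULL,
                          by = "condition") {
  stopifnot(length(epochs_list) >= 1)
  labels_per_p <- lapply(epochs_list, function(e) {
    as.character(unique(e$metadata[[by]]))
  })
  if (is.null(conditions)) {
    conditions <- Reduce(intersect, labels_per_p)
    if (length(conditions) == 0) {
      stop("no condition is present in every participant", call. = FALSE)
    }
    conditions <- sort(conditions)
  }
  first <- epochs_list[[1]]
  missing_ch <- setdiff(cluster, first$channels)
  if (length(missing_ch) > 0) {
    stop("cluster channels not in the data: ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  }
  tidx <- time_window_idx(first$times, window)
  times <- first$times[tidx]
  n_p <- length(epochs_list)
  values <- array(NA_real_, dim = c(n_p, length(conditions), length(times)),
                  dimnames = list(NULL, conditions, NULL))
  for (p in seq_len(n_p)) {
    e <- epochs_list[[p]]
    chidx <- match(cluster, e$channels)
    labs <- as.character(e$metadata[[by]])
    for (ci in seq_along(conditions)) {
      rows <- which(labs == conditions[ci])
      if (length(rows) == 0) {
        stop("participant ", p, " has no trials in condition '",
             conditions[ci], "'", call. = FALSE)
      }
      # mean over trials, then over cluster channels
      trial_mean <- apply(e$data[rows, chidx, tidx, drop = FALSE], c(2, 3), mean)
      values[p, ci, ] <- colMeans(trial_mean)
    }
  }
  structure(list(values = values, times = times, conditions = conditions,
                 cluster = cluster, window = window),
            class = "erp_matrix")
}

#' @export
print.erp_matrix <- function(x, ...) {
  d <- dim(x$values)
  cat("<erp_matrix> ", d[1], " participants x ", d[2], " conditions x ",
      d[3], " time points\n", sep = "")
  cat("  conditions: ", paste(x$conditions, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Column-wise paired t statistics for a difference matrix D (n x T).
# Zero-variance convention: t = 0 / p = 1 when the mean difference is 0,
# else t = +/-Inf / p = 0.
t_series_from_diff <- function(D, sidedness = "two") {
  n <- nrow(D)
  m <- colMeans(D)
  s <- sqrt(colSums(sweep(D, 2, m)^2) / (n - 1))
  se <- s / sqrt(n)
  t <- ifelse(se == 0, ifelse(m == 0, 0, sign(m) * Inf), m / se)
  p <- if (sidedness == "two") {
    2 * pt(abs(t), df = n - 1, lower.tail = FALSE)
  } else {
    pt(t, df = n - 1, lower.tail = FALSE)
  }
  p[se == 0] <- ifelse(m[se == 0] == 0, 1,
                       ifelse(sidedness == "two" | m[se == 0] > 0, 0, 1))
  list(t = t, p = p)
}

#' Pointwise paired t-test time series between two conditions
#'
#' @param erp An `erp_matrix` from [condition_erp()].
#' @param cond_a,cond_b Condition labels to contrast (`cond_a - cond_b`).
#' @param sidedness `"two"` (default) or `"one"`.
#' @return A tibble `time`, `t`, `p` with one row per time point.
#' @export
paired_t_series <- function(erp, cond_a, cond_b, sidedness = "two") {
  D <- erp_diff_matrix(erp, cond_a, cond_b)
  if (nrow(D) < 3) stop("need at least 3 participants", call. = FALSE)
  res <- t_series_from_diff(D, sidedness)
  tibble(time = erp$times, t = res$t, p = res$p)
}

erp_diff_matrix <- function(erp, cond_a, cond_b) {
  for (cc in c(cond_a, cond_b)) {
    if (!cc %in% erp$conditions) {
      stop("condition '", cc, "' not present in the ERP matrix", call. = FALSE)
    }
  }
  erp$values[, cond_a, ] - erp$values[, cond_b, ]
}

#' Find clusters of contiguous significant p-values
#'
#' Maximal runs of `p < alpha` (strict) with length at least `min_len`.
#'
#' @param p Numeric vector of p-values.
#' @param alpha Pointwise threshold (default 0.05).
#' @param min_len Minimum run length (default 2).
#' @return A tibble `start`, `end`, `length` (indices into `p`).
#' @export
find_clusters <- function(p, alpha = 0.05, min_len = 2) {
  stopifnot(all(p >= 0 & p <= 1))
  sig <- p < alpha
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_len
  tibble(start = starts[keep], end = ends[keep], length = r$lengths[keep])
}

# Max run length of TRUE in a logical vector, 0 if no run reaches min_len.
max_run_length <- function(sig, min_len) {
  r <- rle(sig)
  lens <- r$lengths[r$values]
  lens <- lens[lens >= min_len]
  if (length(lens) == 0) 0L else max(lens)
}

# All 2^n sign vectors as a matrix (2^n x n). Only used for small n.
all_sign_matrix <- function(n) {
  stopifnot(n <= 30)
  m <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  dimnames(m) <- NULL
  m
}

# Shared permutation-null engine. D is the participant x time difference
# matrix; `flip` chooses the exchangeability unit: whole participants
# (condition-label shuffle == sign flip of the difference waveform) or
# individual participant x time cells (swap-with-chance null).
cluster_test_core <- function(D, times, config, flip = c("participant", "cell")) {
  flip <- match.arg(flip)
  n <- nrow(D)
  Tn <- ncol(D)
  if (n < 3) stop("need at least 3 participants", call. = FALSE)

  obs <- t_series_from_diff(D, config$sidedness)
  clusters <- find_clusters(obs$p, config$alpha, config$min_cluster_length)

  css <- colSums(D^2)
  perm_t_from_signs <- function(S) {
    # S: P x n matrix of +/-1; returns P x T matrix of t statistics.
    M <- S %*% D / n
    V <- sweep(-n * M^2, 2, css, `+`) / (n - 1)
    V[V < 0] <- 0
    Tm <- M / sqrt(V / n)
    Tm[!is.finite(Tm)] <- 0
    Tm
  }
  crit <- if (config$sidedness == "two") {
    qt(1 - config$alpha / 2, df = n - 1)
  } else {
    qt(1 - config$alpha, df = n - 1)
  }

  exhaustive <- FALSE
  if (flip == "participant") {
    if (2^n <= config$n_permutations) {
      exhaustive <- TRUE
      S <- all_sign_matrix(n)
    } else {
      S <- with_seed(config$seed, {
        matrix(sample(c(-1, 1), config$n_permutations * n, replace = TRUE),
               ncol = n)
      })
    }
    Tm <- perm_t_from_signs(S)
    sig_mat <- if (config$sidedness == "two") abs(Tm) > crit else Tm > crit
    null_sizes <- apply(sig_mat, 1, max_run_length,
                        min_len = config$min_cluster_length)
  } else {
    if (2^(n * Tn) <= config$n_permutations) {
      exhaustive <- TRUE
      combos <- all_sign_matrix(n * Tn)
      null_sizes <- apply(combos, 1, function(s) {
        Dp <- D * matrix(s, nrow = n)
        res <- t_series_from_diff(Dp, config$sidedness)
        max_run_length(res$p < config$alpha, config$min_cluster_length)
      })
    } else {
      null_sizes <- with_seed(config$seed, {
        vapply(seq_len(config$n_permutations), function(b) {
          S <- matrix(sample(c(-1, 1), n * Tn, replace = TRUE), nrow = n)
          res <- t_series_from_diff(D * S, config$sidedness)
          max_run_length(res$p < config$alpha, config$min_cluster_length)
        }, numeric(1))
      })
    }
  }

  threshold <- nearest_rank(null_sizes, config$null_percentile)
  clusters$start_ms <- times[clusters$start]
  clusters$end_ms <- times[clusters$end]
  clusters$significant <- clusters$length > threshold

  structure(
    list(clusters = clusters, null_max_sizes = as.integer(null_sizes),
         size_threshold = as.integer(threshold), times = times,
         t = obs$t, p = obs$p, config = config, exhaustive = exhaustive),
    class = "cluster_result"
  )
}

#' Cluster-based permutation contrast between two conditions
#'
#' Pointwise paired t-tests between two condition ERPs, extraction of
#' clusters of contiguous significant time points, and a max-cluster-size
#' permutation null built by randomly swapping each participant's two
#' condition waveforms (equivalent to flipping the sign of the difference
#' waveform). The significance threshold is the `null_percentile`
#' (nearest-rank) of the null distribution; observed clusters strictly
#' exceeding it are marked significant. With `n` participants and
#' `2^n <= n_permutations` the null is enumerated exhaustively.
#'
#' @inheritParams paired_t_series
#' @param config A [cluster_config()] object.
#' @return A `cluster_result`: observed clusters with ms bounds and
#'   significance flags, the null max-cluster-size distribution, and the
#'   size threshold.
#' @export
cluster_permutation_test <- function(erp, cond_a, cond_b,
                                     config = cluster_config()) {
  stopifnot(inherits(config, "cluster_config"))
  D <- erp_diff_matrix(erp, cond_a, cond_b)
  cluster_test_core(D, erp$times, config, flip = "participant")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", nrow(x$clusters), " cluster(s), threshold ",
      x$size_threshold, " points (",
      if (x$exhaustive) "exhaustive" else
        paste0(length(x$null_max_sizes), " permutations"),
      ")\n", sep = "")
  if (nrow(x$clusters) > 0) {
    sig <- x$clusters[x$clusters$significant, , drop = FALSE]
    if (nrow(sig) > 0) {
      cat("  significant: ",
          paste(sprintf("%.0f-%.0f ms", sig$start_ms, sig$end_ms),
                collapse = ", "), "\n", sep = "")
    } else {
      cat("  no significant clusters\n")
    }
  }
  invisible(x)
}

#' @export
tidy.cluster_result <- function(x, ...) {
  x$clusters
}

#' @export
glance.cluster_result <- function(x, ...) {
  tibble(
    n_clusters = nrow(x$clusters),
    n_significant = sum(x$clusters$significant),
    size_threshold = x$size_threshold,
    n_permutations = length(x$null_max_sizes),
    exhaustive = x$exhaustive
  )
}

#' Serialize a cluster result to JSON
#'
#' Writes cluster bounds in ms, the size threshold and a summary of the null
#' distribution.
#'
#' @param x A `cluster_result`.
#' @param path Output path.
#' @export
write_cluster_result <- function(x, path) {
  out <- list(
    clusters = x$clusters,
    size_threshold = x$size_threshold,
    null_summary = list(
      n = length(x$null_max_sizes),
      mean = mean(x$null_max_sizes),
      percentile = x$config$null_percentile
    ),
    exhaustive = x$exhaustive
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
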