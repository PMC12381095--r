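# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot condition-mean ERPs
#'
#' Grand-average waveform per condition over the electrode cluster, with a
#' standard-error ribbon across participants.
#'
#' @param object An `erp_matrix` from [condition_erp()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.erp_matrix <- function(object, ...) {
  d <- dim(object$values)
  df <- tibble(
    participant = rep(seq_len(d[1]), times = d[2] * d[3]),
    condition = rep(rep(object$conditions, each = d[1]), times = d[3]),
    time = rep(object$times, each = d[1] * d[2]),
    amplitude = as.vector(object$values)
  ) |>
    dplyr::group_by(.data$condition, .data$time) |>
    dplyr::summarise(mean = mean(.data$amplitude),
                     se = sd(.data$amplitude) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$mean,
                                   colour = .data$condition,
                                   fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (ms)", y = expression("Amplitude (" * mu * "V)"),
                  title = paste("ERP over",
                                paste(object$cluster, collapse = ", "))) +
    ggplot2::theme_minimal()
}

#' Plot a decoding timecourse
#'
#' Group-mean accuracy over time with a standard-error ribbon and the chance
#' level; optionally marks significant clusters from a cluster test.
#'
#' @param object A `decoding_timecourse`.
#' @param cluster_result Optional `cluster_result` whose significant
#'   clusters are drawn as horizontal segments.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.decoding_timecourse <- function(object, cluster_result = NULL, ...) {
  df <- tidy(object) |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(mean = mean(.data$accuracy),
                     se = sd(.data$accuracy) / sqrt(dplyr::n()),
                     .groups = "drop")
  gg <- ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$chance_level, linetype = 2) +
    ggplot2::labs(x = "Time (ms)", y = "Decoding accuracy",
                  title = paste0(object$kind, "-phase location decoding")) +
    ggplot2::theme_minimal()
  if (!is.null(cluster_result)) {
    sig <- cluster_result$clusters[cluster_result$clusters$significant, ,
                                   drop = FALSE]
    if (nrow(sig) > 0) {
      gg <- gg + ggplot2::annotate(
        "segment", x = sig$start_ms, xend = sig$end_ms,
        y = object$chance_level * 0.98, yend = object$chance_level * 0.98,
        linewidth = 1.5)
    }
  }
  gg
}

#' Plot the null max-cluster-size distribution of a cluster test
#'
#' Histogram of the permutation null with the significance threshold and the
#' observed cluster sizes.
#'
#' @param object A `cluster_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cluster_result <- function(object, ...) {
  df <- tibble(size = object$null_max_sizes)
  gg <- ggplot2::ggplot(df, ggplot2::aes(.data$size)) +
    ggplot2::geom_histogram(binwidth = 1, boundary = -0.5) +
    ggplot2::geom_vline(xintercept = object$size_threshold, linetype = 2) +
    ggplot2::labs(x = "Max cluster size (time points)", y = "Permutations",
                  title = "Permutation null of maximum cluster size") +
    ggplot2::theme_minimal()
  if (nrow(object$clusters) > 0) {
    gg <- gg + ggplot2::geom_vline(xintercept = object$clusters$length,
                                   colour = "red", alpha = 0.6)
  }
  gg
}
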