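# Epoched multichannel EEG container. Data live in a trial x channel x time
# array in microvolts; per-trial metadata travel alongside as a tibble.

#' Construct an epoched EEG object
#'
#' @param data Numeric array `(trial, channel, time)` in microvolts.
#' @param times Time axis in ms, uniformly spaced at `1000 / srate`.
#' @param srate Sampling rate in Hz.
#' @param channels Character vector of unique channel labels (length =
#'   `dim(data)[2]`).
#' @param metadata Tibble with one row per trial (phase, condition, location,
#'   object id, ... as available).
#' @param phase Phase label (`"encoding"`, `"wm"`, `"retrieval"`), or `NA`.
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, times, srate, channels, metadata, phase = NA_character_) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (length(times) != dim(data)[3]) {
    stop("`times` length must match the third dimension of `data`", call. = FALSE)
  }
  if (length(channels) != dim(data)[2]) {
    stop("`channels` length must match the second dimension of `data`", call. = FALSE)
  }
  if (anyDuplicated(channels)) stop("channel labels must be unique", call. = FALSE)
  step <- 1000 / srate
  if (length(times) > 1 && max(abs(diff(times) - step)) > 1e-6) {
    stop("`times` must be uniformly spaced at 1000/srate ms", call. = FALSE)
  }
  metadata <- tibble::as_tibble(metadata)
  if (nrow(metadata) != dim(data)[1]) {
    stop("`metadata` must have one row per trial", call. = FALSE)
  }
  structure(
    list(data = data, times = times, srate = srate,
         channels = as.character(channels), metadata = metadata,
         phase = phase),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat("<eeg_epochs> ", d[1], " trials x ", d[2], " channels x ", d[3],
      " samples (", x$srate, " Hz), phase: ", x$phase, "\n", sep = "")
  cat("  time range: ", min(x$times), " to ", max(x$times), " ms\n", sep = "")
  invisible(x)
}

#' @export
dim.eeg_epochs <- function(x) dim(x$data)

n_trials <- function(epochs) dim(epochs$data)[1]

# Subset trials, keeping metadata aligned.
epochs_subset <- function(epochs, idx) {
  eeg_epochs(epochs$data[idx, , , drop = FALSE], epochs$times, epochs$srate,
             epochs$channels, epochs$metadata[idx, , drop = FALSE],
             epochs$phase)
}

# Indices of the samples falling inside a [from, to] ms window (inclusive).
time_window_idx <- function(times, window) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  idx <- which(times >= window[1] - 1e-9 & times <= window[2] + 1e-9)
  if (length(idx) == 0) stop("window outside the epoch time axis", call. = FALSE)
  idx
}

#' Flatten epochs to a long tibble
#'
#' One row per (trial, channel, time) sample; useful for plotting and ad-hoc
#' summaries with dplyr.
#'
#' @param x An `eeg_epochs` object.
#' @param ... Unused.
#' @return A tibble with columns `trial`, `channel`, `time`, `value` plus the
#'   metadata columns.
#' @export
as_tibble.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  long <- tibble(
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    channel = rep(rep(x$channels, each = d[1]), times = d[3]),
    time = rep(x$times, each = d[1] * d[2]),
    value = as.vector(x$data)
  )
  dplyr::left_join(long,
                   dplyr::mutate(x$metadata, trial = dplyr::row_number()),
                   by = "trial")
}

#' Persist epoched EEG to a plain-text container
#'
#' Writes a directory with three files: `header.json` (times, sampling rate,
#' channel labels, phase), `metadata.tsv` (one row per trial) and `data.tsv`
#' (one row per trial-channel pair, samples as columns). The layout is
#' human-readable, diff-able and round-trips losslessly through
#' [read_epochs()].
#'
#' @param epochs An `eeg_epochs` object.
#' @param dir Directory to create/overwrite.
#' @return `write_epochs()` returns `dir` invisibly; `read_epochs()` returns
#'   the `eeg_epochs` object.
#' @export
write_epochs <- function(epochs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  header <- list(times = epochs$times, srate = epochs$srate,
                 channels = epochs$channels, phase = epochs$phase,
                 n_trials = n_trials(epochs))
  jsonlite::write_json(header, file.path(dir, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_tsv(epochs$metadata, file.path(dir, "metadata.tsv"))
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(3, 2, 1)), nrow = d[1] * d[2],
                 ncol = d[3], byrow = TRUE)
  df <- as.data.frame(flat)
  names(df) <- paste0("s", seq_len(d[3]))
  df <- cbind(trial = rep(seq_len(d[1]), each = d[2]),
              channel = rep(epochs$channels, times = d[1]), df)
  readr::write_tsv(tibble::as_tibble(df), file.path(dir, "data.tsv"))
  invisible(dir)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(dir) {
  header <- jsonlite::read_json(file.path(dir, "header.json"),
                                simplifyVector = TRUE)
  metadata <- readr::read_tsv(file.path(dir, "metadata.tsv"),
                              show_col_types = FALSE, progress = FALSE)
  flat <- readr::read_tsv(file.path(dir, "data.tsv"),
                          show_col_types = FALSE, progress = FALSE)
  n_trial <- header$n_trials
  channels <- header$channels
  n_chan <- length(channels)
  n_time <- length(header$times)
  vals <- as.matrix(flat[, -(1:2)])
  data <- aperm(array(t(vals), dim = c(n_time, n_chan, n_trial)), c(3, 2, 1))
  eeg_epochs(data, header$times, header$srate, channels, metadata,
             header$phase %||% NA_character_)
}
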