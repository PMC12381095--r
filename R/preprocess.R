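# Minimal EEG preprocessing: Hamming windowed-sinc FIR design, zero-phase
# filtering, integer-factor downsampling, baseline correction, and iterative
# automated epoch rejection.

#' Design a Hamming windowed-sinc FIR filter
#'
#' Linear-phase type-I FIR design: an ideal sinc truncated to `order` taps
#' and shaped by a Hamming window. The cutoff is specified at the -6 dB
#' point, which for a windowed-sinc design coincides with the ideal cutoff
#' frequency.
#'
#' @param kind `"lowpass"` or `"highpass"`.
#' @param cutoff Cutoff frequency in Hz at -6 dB.
#' @param order Number of taps; odd and at least 3.
#' @param srate Sampling rate in Hz.
#' @return Numeric coefficient vector of length `order`, symmetric
#'   (linear phase), with attributes `kind`, `cutoff`, `srate`.
#' @export
#' @examples
#' h <- design_fir(kind = "lowpass", cutoff = 30, order = 441, srate = 1000)
#' # magnitude at the cutoff is -6 dB by construction:
#' 20 * log10(abs(fir_response(h, 30, 1000)))
design_fir <- function(kind = c("lowpass", "highpass"), cutoff, order, srate) {
  kind <- match.arg(kind)
  stopifnot(order >= 3, order %% 2 == 1)
  nyq <- srate / 2
  if (cutoff <= 0 || cutoff >= nyq) {
    stop("`cutoff` must lie strictly between 0 and the Nyquist frequency (",
         nyq, " Hz)", call. = FALSE)
  }
  m <- (order - 1) / 2
  n <- seq(-m, m)
  fc <- cutoff / srate                      # normalized (cycles/sample)
  h <- 2 * fc * sinc_(2 * fc * n)
  w <- 0.54 + 0.46 * cos(pi * n / m)        # Hamming, symmetric about 0
  h <- h * w
  h <- h / sum(h)                           # exact unity DC gain
  if (kind == "highpass") {                 # spectral inversion
    h <- -h
    h[m + 1] <- h[m + 1] + 1
  }
  structure(h, kind = kind, cutoff = cutoff, srate = srate)
}

sinc_ <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Frequency response of an FIR filter
#'
#' @param coeffs Coefficient vector.
#' @param freq Frequencies in Hz.
#' @param srate Sampling rate in Hz (defaults to the design attribute).
#' @return Complex response at each frequency.
#' @export
fir_response <- function(coeffs, freq, srate = attr(coeffs, "srate")) {
  n <- seq_along(coeffs) - 1
  vapply(freq, function(f) {
    sum(coeffs * exp(-1i * 2 * pi * f / srate * n))
  }, complex(1))
}

# Reflection-pad a vector at both ends by `pad` samples. Uses pure index
# reflection with period 2(n-1), so arbitrarily large pads (filters longer
# than the data) are well defined.
reflect_pad <- function(x, pad) {
  n <- length(x)
  if (n == 1) return(rep(x, 2 * pad + 1))
  pos <- c((1 - pad):0, seq_len(n), (n + 1):(n + pad))
  q <- abs(pos - 1) %% (2 * n - 2)
  idx <- ifelse(q < n, q + 1, 2 * n - 1 - q)
  x[idx]
}

# Zero-phase filtering of one vector: single-pass convolution with a
# symmetric linear-phase FIR, reflection padding, and exact group-delay
# compensation (for a symmetric FIR this is exactly zero-phase and keeps the
# designed magnitude response, unlike forward-backward filtering which
# squares it).
filter_vector <- function(x, coeffs) {
  n <- length(x)
  m <- (length(coeffs) - 1) / 2
  padded <- reflect_pad(x, m)
  y <- stats::filter(padded, coeffs, method = "convolution", sides = 2)
  as.numeric(y[(m + 1):(m + n)])
}

#' Apply a zero-phase FIR filter
#'
#' Filters along the time axis with no net group delay: a constant input maps
#' to itself times the DC gain, and an impulse maps to a symmetric output.
#' Edges are handled by reflection padding.
#'
#' @param x An [eeg_epochs()] object, a numeric vector, or a
#'   `channels x time` matrix.
#' @param coeffs Coefficients from [design_fir()] (odd length, symmetric).
#' @return Same shape/class as the input.
#' @export
apply_filter <- function(x, coeffs) {
  if (length(coeffs) %% 2 != 1) {
    stop("`coeffs` must have odd length (type-I linear phase)", call. = FALSE)
  }
  if (inherits(x, "eeg_epochs")) {
    d <- dim(x$data)
    for (i in seq_len(d[1])) {
      for (j in seq_len(d[2])) {
        x$data[i, j, ] <- filter_vector(x$data[i, j, ], coeffs)
      }
    }
    return(x)
  }
  if (is.matrix(x)) {
    return(t(apply(x, 1, filter_vector, coeffs = coeffs)))
  }
  if (length(x) == 0) stop("empty input", call. = FALSE)
  filter_vector(x, coeffs)
}

#' Downsample epochs by an integer factor
#'
#' Applies an anti-alias lowpass (windowed-sinc at 80% of the new Nyquist)
#' and keeps every `factor`-th sample. Non-integer ratios are rejected.
#'
#' @param epochs An [eeg_epochs()] object.
#' @param new_srate Target sampling rate; `srate / new_srate` must be an
#'   integer.
#' @param order Anti-alias filter order (odd; default 101).
#' @return Downsampled [eeg_epochs()] object.
#' @export
downsample_epochs <- function(epochs, new_srate, order = 101) {
  q <- epochs$srate / new_srate
  if (abs(q - round(q)) > 1e-9) {
    stop("`new_srate` must divide the current sampling rate by an integer ",
         "factor (got ratio ", format(q), ")", call. = FALSE)
  }
  q <- as.integer(round(q))
  if (q == 1L) return(epochs)
  aa <- design_fir("lowpass", cutoff = 0.8 * new_srate / 2,
                   order = order, srate = epochs$srate)
  epochs <- apply_filter(epochs, aa)
  keep <- seq(1, length(epochs$times), by = q)
  eeg_epochs(epochs$data[, , keep, drop = FALSE], epochs$times[keep],
             new_srate, epochs$channels, epochs$metadata, epochs$phase)
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the baseline window, so
#' the post-correction baseline mean is zero.
#'
#' @param epochs An [eeg_epochs()] object.
#' @param window `c(from, to)` in ms (default `c(-200, 0)`); must lie inside
#'   the epoch.
#' @return Baseline-corrected [eeg_epochs()] object.
#' @export
baseline_correct <- function(epochs, window = c(-200, 0)) {
  idx <- time_window_idx(epochs$times, window)
  base <- apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(base)  # recycles over time axis
  epochs
}

#' Rejection configuration for automated epoch rejection
#'
#' @param abs_threshold Absolute amplitude cutoff in microvolts (default 500).
#' @param sd_threshold Deviation score cutoff in SD units (default 5).
#' @param max_reject_fraction Maximum fraction of current trials rejected per
#'   iteration (default 0.05).
#' @param max_iterations Iteration cap (default 8).
#' @return A list of class `rejection_config`.
#' @export
rejection_config <- function(abs_threshold = 500, sd_threshold = 5,
                             max_reject_fraction = 0.05, max_iterations = 8) {
  stopifnot(abs_threshold > 0, sd_threshold > 0,
            max_reject_fraction > 0, max_reject_fraction <= 1,
            max_iterations >= 1)
  structure(list(abs_threshold = abs_threshold, sd_threshold = sd_threshold,
                 max_reject_fraction = max_reject_fraction,
                 max_iterations = max_iterations),
            class = "rejection_config")
}

# Per-trial deviation score: max |z| across trials of three per-trial summary
# statistics (mean, log-variance, range), a fully specified stand-in for
# joint-probability trial rejection.
trial_deviation_scores <- function(data) {
  stats_mat <- cbind(
    mean = apply(data, 1, function(tr) mean(as.vector(tr))),
    logvar = apply(data, 1, function(tr) log(var(as.vector(tr)) + 1e-12)),
    range = apply(data, 1, function(tr) diff(range(tr)))
  )
  z <- scale(stats_mat)
  z[is.nan(z)] <- 0
  apply(abs(z), 1, max)
}

#' Automated iterative epoch rejection
#'
#' Iteratively flags trials whose absolute amplitude exceeds
#' `abs_threshold` or whose deviation score (max |z| of per-trial mean,
#' log-variance and range across trials) exceeds `sd_threshold`, rejecting
#' at most `max_reject_fraction` of the current trials per iteration (worst
#' first), until no trial is flagged or `max_iterations` is reached.
#'
#' @param epochs An [eeg_epochs()] object with at least 2 trials.
#' @param config A [rejection_config()] object.
#' @return A list with `kept` (an `eeg_epochs` object), `rejected` (integer
#'   indices into the input), and `report` (tibble of per-iteration counts).
#' @export
reject_epochs <- function(epochs, config = rejection_config()) {
  stopifnot(inherits(config, "rejection_config"))
  if (n_trials(epochs) < 2) stop("need at least 2 trials", call. = FALSE)
  keep <- seq_len(n_trials(epochs))
  rejected <- integer(0)
  report <- list()
  for (iter in seq_len(config$max_iterations)) {
    data <- epochs$data[keep, , , drop = FALSE]
    n_cur <- length(keep)
    abs_max <- apply(abs(data), 1, max)
    dev <- trial_deviation_scores(data)
    flagged <- which(abs_max > config$abs_threshold | dev > config$sd_threshold)
    if (length(flagged) == 0) break
    budget <- ceiling(config$max_reject_fraction * n_cur)
    # Worst first: rank by how far past either criterion a trial is.
    severity <- pmax(abs_max[flagged] / config$abs_threshold,
                     dev[flagged] / config$sd_threshold)
    drop_local <- flagged[order(severity, decreasing = TRUE)][
      seq_len(min(budget, length(flagged)))]
    if (length(drop_local) >= n_cur) {
      stop("rejection would remove all trials", call. = FALSE)
    }
    rejected <- c(rejected, keep[drop_local])
    keep <- keep[-drop_local]
    report[[iter]] <- tibble(iteration = iter, flagged = length(flagged),
                             rejected = length(drop_local),
                             remaining = length(keep))
    if (length(keep) < 2) break
  }
  list(kept = epochs_subset(epochs, keep),
       rejected = sort(rejected),
       report = dplyr::bind_rows(report))
}
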