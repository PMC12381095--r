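# Synthetic-data generator: epoched EEG with controllable location-pattern
# and old/new effects plus 1/f spatially correlated noise, and behavioural
# tables with per-condition Bernoulli accuracy and log-normal RTs.

default_epoch_windows <- function() {
  list(encoding = c(-500, 1000), wm = c(-500, 3000), retrieval = c(-500, 2500))
}

default_signal_windows <- function() {
  list(encoding = c(60, 1000), wm = c(70, 1460), retrieval = c(330, 1360))
}

default_accuracy <- function(experiment) {
  if (experiment == 1L) {
    c(PT = 0.8168, NP = 0.7112, ABS = 0.6591)
  } else {
    c(PT = 0.7965, NPT = 0.7147, NP = 0.6775, ABS = 0.6461)
  }
}

default_rt <- function(experiment) {
  if (experiment == 1L) {
    list(PT = c(mean = 1060.80, sd = 294.63),
         NP = c(mean = 1166.81, sd = 342.96),
         ABS = c(mean = 1206.22, sd = 350.33))
  } else {
    list(PT = c(mean = 1108.37, sd = 273.99),
         NPT = c(mean = 1164.54, sd = 291.11),
         NP = c(mean = 1220.77, sd = 342.00),
         ABS = c(mean = 1229.77, sd = 369.52))
  }
}

#' Parameters of the synthetic-data generator
#'
#' Bundles every knob of the generator with defaults emulating the study
#' conditions: a 64-channel cap sampled at 250 Hz, per-phase epoch windows,
#' a condition-graded left-parietal old/new positivity in 430-670 ms, four
#' location-specific multichannel patterns active in phase-specific windows
#' with tunable cross-phase similarity, 1/f spatially correlated noise, and
#' per-condition Bernoulli accuracy / log-normal response times calibrated
#' to the printed group means.
#'
#' @param experiment `1` or `2`; selects condition sets and behavioural
#'   defaults.
#' @param n_participants Number of simulated participants (default 43).
#' @param n_channels Number of channels (default 64; see [channel_montage()]).
#' @param srate Sampling rate in Hz (default 250).
#' @param epoch_windows Named list of `c(from, to)` ms windows per phase.
#' @param oldnew_amplitude Named numeric, microvolts of old/new positivity per
#'   condition at retrieval; zero everywhere gives a null dataset.
#' @param oldnew_window `c(from, to)` ms window of the old/new deflection.
#' @param location_signal_amplitude Microvolts of the location-pattern signal.
#' @param signal_windows Named list of per-phase ms windows in which the
#'   location signal is active.
#' @param cross_phase_similarity Cosine similarity `rho` in `[0, 1]` between a
#'   location's patterns in different phases (1 = identical format).
#' @param noise_sd Per-channel noise standard deviation in microvolts.
#' @param noise_spectral_exponent Exponent `a` of the `1/f^a` noise spectrum.
#' @param spatial_mixing Length scale of the distance-decaying channel
#'   covariance (larger = more spatially correlated noise).
#' @param behavior_accuracy Named probability per condition.
#' @param behavior_rt Named list of `c(mean, sd)` in ms per condition
#'   (log-normal parameters are solved to match them).
#' @param seed Integer master seed; all randomness derives from it.
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(experiment = 1,
                             n_participants = 43,
                             n_channels = 64,
                             srate = 250,
                             epoch_windows = default_epoch_windows(),
                             oldnew_amplitude = NULL,
                             oldnew_window = c(430, 670),
                             location_signal_amplitude = 5,
                             signal_windows = default_signal_windows(),
                             cross_phase_similarity = 0.8,
                             noise_sd = 10,
                             noise_spectral_exponent = 1,
                             spatial_mixing = 0.6,
                             behavior_accuracy = NULL,
                             behavior_rt = NULL,
                             seed = 1L) {
  experiment <- check_experiment(experiment)
  conds <- experiment_conditions(experiment)
  if (is.null(oldnew_amplitude)) {
    oldnew_amplitude <- c(PT = 1.5, NPT = 1.0, NP = 0.4, ABS = 0.2)[conds]
  }
  if (is.null(behavior_accuracy)) behavior_accuracy <- default_accuracy(experiment)
  if (is.null(behavior_rt)) behavior_rt <- default_rt(experiment)
  stopifnot(all(oldnew_amplitude >= 0),
            cross_phase_similarity >= 0, cross_phase_similarity <= 1,
            noise_sd >= 0, srate > 0,
            all(unlist(behavior_accuracy) >= 0),
            all(unlist(behavior_accuracy) <= 1))
  for (ph in names(signal_windows)) {
    ew <- epoch_windows[[ph]]
    sw <- signal_windows[[ph]]
    if (sw[1] < ew[1] || sw[2] > ew[2]) {
      stop("signal window for phase '", ph, "' lies outside its epoch window",
           call. = FALSE)
    }
  }
  structure(
    list(experiment = experiment, n_participants = n_participants,
         n_channels = n_channels, srate = srate,
         epoch_windows = epoch_windows,
         oldnew_amplitude = oldnew_amplitude, oldnew_window = oldnew_window,
         location_signal_amplitude = location_signal_amplitude,
         signal_windows = signal_windows,
         cross_phase_similarity = cross_phase_similarity,
         noise_sd = noise_sd,
         noise_spectral_exponent = noise_spectral_exponent,
         spatial_mixing = spatial_mixing,
         behavior_accuracy = behavior_accuracy, behavior_rt = behavior_rt,
         seed = as.integer(seed)),
    class = "generator_params"
  )
}

#' Generate per-phase location pattern matrices
#'
#' Draws, for each task phase, a `channels x locations` matrix of spatial
#' patterns. Within a phase the location patterns are mutually orthogonal
#' unit vectors. Each pattern is built as
#' `sqrt(rho) * shared + sqrt(1 - rho) * phase-specific`, with all components
#' drawn from a common orthonormal basis, so the cosine similarity between a
#' location's patterns in any two phases equals `rho` exactly: `rho = 1`
#' yields an identical representational format across phases, `rho = 0` an
#' orthogonal one.
#'
#' @param n_channels Number of channels; must be at least
#'   `n_locations * (n_phases + 1)`.
#' @param n_locations Number of location classes (default 4).
#' @param rho Cross-phase similarity in `[0, 1]`.
#' @param seed Integer seed.
#' @param phases Phase names (default the three task phases).
#' @return Named list of `channels x locations` matrices.
#' @export
generate_location_patterns <- function(n_channels, n_locations = 4, rho, seed,
                                       phases = c("encoding", "wm", "retrieval")) {
  if (rho < 0 || rho > 1) stop("`rho` must lie in [0, 1]", call. = FALSE)
  stopifnot(n_locations >= 2)
  n_phases <- length(phases)
  need <- n_locations * (n_phases + 1)
  if (n_channels < need) {
    stop("`n_channels` must be at least n_locations * (n_phases + 1) = ",
         need, call. = FALSE)
  }
  with_seed(seed, {
    raw <- matrix(rnorm(n_channels * need), nrow = n_channels)
    qr_ <- qr(raw)
    q <- qr.Q(qr_)
    # Fix QR sign indeterminacy for reproducibility across BLAS builds.
    signs <- sign(diag(qr.R(qr_)))
    signs[signs == 0] <- 1
    q <- sweep(q, 2, signs, `*`)
    shared <- q[, seq_len(n_locations), drop = FALSE]
    out <- lapply(seq_len(n_phases), function(p) {
      spec <- q[, p * n_locations + seq_len(n_locations), drop = FALSE]
      sqrt(rho) * shared + sqrt(1 - rho) * spec
    })
    names(out) <- phases
    out
  })
}

# Half-cosine (raised sine) temporal envelope over `window`, zero elsewhere.
half_cosine_envelope <- function(times, window) {
  env <- numeric(length(times))
  inside <- times >= window[1] & times <= window[2]
  u <- (times[inside] - window[1]) / (window[2] - window[1])
  env[inside] <- sin(pi * u)
  env
}

# 1/f^a temporally coloured, spatially mixed noise for one trial:
# channels x time, unit per-channel variance before scaling by noise_sd.
colored_noise <- function(n_chan, n_time, srate, exponent, mix_chol) {
  white <- matrix(rnorm(n_time * n_chan), nrow = n_time)
  if (exponent != 0) {
    k <- seq_len(n_time) - 1
    f <- pmin(k, n_time - k) * srate / n_time
    f0 <- srate / n_time
    s <- (f + f0)^(-exponent / 2)
    s <- s * sqrt(n_time / sum(s^2))
    spec <- stats::mvfft(white) * s
    white <- Re(stats::mvfft(spec, inverse = TRUE)) / n_time
  }
  t(mix_chol) %*% t(white)   # channels x time, covariance = K
}

# Distance-decaying channel covariance (unit diagonal) and its Cholesky.
spatial_mix_chol <- function(montage, length_scale) {
  d <- as.matrix(stats::dist(montage[, c("x", "y")]))
  K <- exp(-d / max(length_scale, 1e-6))
  chol(K + diag(1e-9, nrow(K)))
}

phase_times <- function(params, phase) {
  w <- params$epoch_windows[[phase]]
  step <- 1000 / params$srate
  seq(w[1], w[2], by = step)
}

#' Simulate one participant's epoched EEG for a task phase
#'
#' Each trial's data are the sum of (i) the trial's location pattern scaled
#' by `location_signal_amplitude` under a half-cosine temporal envelope
#' inside the phase's signal window, (ii) for the retrieval phase, a
#' condition-scaled old/new positivity on the left-parietal topography
#' inside `oldnew_window`, and (iii) `1/f`-type spatially correlated noise.
#' Trial count and metadata mirror the schedule. Deterministic given
#' `params$seed` and `participant`.
#'
#' @param phase `"encoding"`, `"wm"` or `"retrieval"`.
#' @param schedule Schedule tibble for that phase (working-memory schedules
#'   use the cued object's location as the trial label, falling back to the
#'   horizontal object for neutral trials).
#' @param params A [generator_params()] object.
#' @param participant Participant index (used to derive the seed).
#' @return An [eeg_epochs()] object.
#' @export
simulate_phase_epochs <- function(phase, schedule, params, participant = 1) {
  stopifnot(inherits(params, "generator_params"))
  if (!phase %in% c("encoding", "wm", "retrieval")) {
    stop("unknown phase: ", phase, call. = FALSE)
  }
  if (!all(schedule$phase == phase)) {
    stop("schedule is for phase '", schedule$phase[1],
         "', not '", phase, "'", call. = FALSE)
  }
  montage <- channel_montage(params$n_channels)
  times <- phase_times(params, phase)
  n_time <- length(times)
  n_chan <- params$n_channels
  n_tr <- nrow(schedule)

  meta <- phase_metadata(schedule, phase)
  loc_idx <- match(meta$location, location_levels())

  env_loc <- half_cosine_envelope(times, params$signal_windows[[phase]])
  sig_loc <- params$location_signal_amplitude
  patterns <- if (sig_loc != 0) {
    generate_location_patterns(
      n_chan, n_locations = 4, rho = params$cross_phase_similarity,
      seed = derive_seed(params$seed, "patterns", participant))[[phase]]
  } else {
    matrix(0, n_chan, 4)
  }

  use_oldnew <- phase == "retrieval"
  if (use_oldnew) {
    topo <- parietal_topography(montage)
    env_on <- half_cosine_envelope(times, params$oldnew_window)
    amp_on <- params$oldnew_amplitude[meta$condition]
    amp_on[is.na(amp_on)] <- 0
  }

  mix <- spatial_mix_chol(montage, params$spatial_mixing)
  data <- array(0, dim = c(n_tr, n_chan, n_time))
  with_seed(derive_seed(params$seed, "epochs", phase, participant), {
    for (i in seq_len(n_tr)) {
      trial <- matrix(0, n_chan, n_time)
      if (sig_loc != 0 && !is.na(loc_idx[i])) {
        trial <- trial + sig_loc * tcrossprod(patterns[, loc_idx[i]], env_loc)
      }
      if (use_oldnew && amp_on[i] != 0) {
        trial <- trial + amp_on[i] * tcrossprod(topo, env_on)
      }
      if (params$noise_sd > 0) {
        trial <- trial + params$noise_sd *
          colored_noise(n_chan, n_time, params$srate,
                        params$noise_spectral_exponent, mix)
      }
      data[i, , ] <- trial
    }
  })
  eeg_epochs(data, times, params$srate, montage$label,
             dplyr::mutate(meta, participant = participant), phase)
}

# Topography of the old/new positivity: weight 1 on the left-parietal
# cluster, Gaussian falloff with scalp distance from the cluster centroid.
parietal_topography <- function(montage) {
  cl <- parietal_cluster()
  present <- intersect(cl, montage$label)
  if (length(present) == 0) {
    stop("montage does not contain the parietal cluster channels", call. = FALSE)
  }
  cen <- colMeans(montage[montage$label %in% present, c("x", "y")])
  d2 <- (montage$x - cen[["x"]])^2 + (montage$y - cen[["y"]])^2
  w <- exp(-d2 / (2 * 0.15^2))
  w[montage$label %in% present] <- 1
  w
}

# Normalize schedule metadata to (object_id, location, condition) per trial.
phase_metadata <- function(schedule, phase) {
  if (phase %in% c("encoding", "retrieval")) {
    tibble(phase = phase,
           trial_index = schedule$trial_index,
           object_id = schedule$object_id,
           location = schedule$location,
           condition = schedule$condition)
  } else {
    # wm: the decoded location label is the cued object's location; neutral
    # trials (no cue) carry the horizontal object's location.
    tibble(phase = phase,
           trial_index = schedule$trial_index,
           object_id = dplyr::coalesce(schedule$cued_object,
                                       schedule$object_horizontal),
           location = schedule$cued_location,
           condition = schedule$cue_type)
  }
}

#' Simulate a retrieval-phase dataset with the parietal old/new component
#'
#' Convenience wrapper around [simulate_phase_epochs()] for the retrieval
#' phase: adds the condition-scaled positive deflection (half-cosine envelope
#' over `oldnew_window`) on the left-parietal topography. The injected
#' amplitude ordering is whatever `params$oldnew_amplitude` specifies,
#' including ties and zeros.
#'
#' @inheritParams simulate_phase_epochs
#' @param schedule Retrieval schedule with condition metadata.
#' @return An [eeg_epochs()] object.
#' @export
simulate_retrieval_erp <- function(schedule, params, participant = 1) {
  simulate_phase_epochs("retrieval", schedule, params, participant)
}

#' Simulate a multi-participant study for one phase
#'
#' @inheritParams simulate_phase_epochs
#' @param n_participants Number of participants (default from `params`).
#' @return A list of [eeg_epochs()] objects, one per participant.
#' @export
simulate_study <- function(phase, schedule, params,
                           n_participants = params$n_participants) {
  lapply(seq_len(n_participants), function(p) {
    simulate_phase_epochs(phase, schedule, params, participant = p)
  })
}

lognormal_pars <- function(mean, sd) {
  sdlog2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Simulate retrieval-phase behaviour
#'
#' One row per participant and retrieval trial. Accuracy is Bernoulli with
#' the condition's probability; response times are log-normal with
#' parameters solved so the distribution matches the condition's configured
#' mean and SD in ms. Trials are independent given the seed.
#'
#' @param schedule Retrieval schedule tibble.
#' @param params A [generator_params()] object.
#' @param n_participants Number of participants (default from `params`).
#' @param probing_counts Optional tibble from [count_probe_instances()];
#'   joined onto the output by `object_id` (objects absent from the
#'   working-memory phase get a count of 0).
#' @return A tibble: `participant`, `trial_index`, `object_id`, `condition`,
#'   `probing_count`, `accuracy` (0/1), `rt` (ms).
#' @export
simulate_behavior <- function(schedule, params,
                              n_participants = params$n_participants,
                              probing_counts = NULL) {
  stopifnot(inherits(params, "generator_params"))
  acc <- unlist(params$behavior_accuracy)
  if (any(acc < 0 | acc > 1)) {
    stop("accuracy probabilities must lie in [0, 1]", call. = FALSE)
  }
  rt_pars <- lapply(params$behavior_rt, function(p) {
    lognormal_pars(p[["mean"]], p[["sd"]])
  })
  cond <- schedule$condition
  p_corr <- acc[cond]
  if (anyNA(p_corr)) {
    stop("behavior_accuracy lacks probabilities for conditions: ",
         paste(unique(cond[is.na(p_corr)]), collapse = ", "), call. = FALSE)
  }
  meanlog <- vapply(cond, function(cc) rt_pars[[cc]][["meanlog"]], numeric(1))
  sdlog <- vapply(cond, function(cc) rt_pars[[cc]][["sdlog"]], numeric(1))

  out <- purrr::map_dfr(seq_len(n_participants), function(p) {
    with_seed(derive_seed(params$seed, "behavior", p), {
      tibble(
        participant = p,
        trial_index = schedule$trial_index,
        object_id = schedule$object_id,
        condition = cond,
        accuracy = rbinom(nrow(schedule), 1, p_corr),
        rt = rlnorm(nrow(schedule), meanlog, sdlog)
      )
    })
  })
  if (!is.null(probing_counts)) {
    out <- dplyr::left_join(out, probing_counts, by = "object_id")
    out$probing_count[is.na(out$probing_count)] <- 0L
  } else {
    out$probing_count <- NA_integer_
  }
  dplyr::relocate(out, "probing_count", .after = "condition")
}

#' Write a behaviour table to CSV
#'
#' @param behavior Tibble from [simulate_behavior()].
#' @param path File path.
#' @export
write_behavior <- function(behavior, path) {
  readr::write_csv(behavior, path)
  invisible(path)
}
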