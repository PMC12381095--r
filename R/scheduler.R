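# Trial scheduling for the three-phase paradigm: condition assignment,
# encoding / working-memory / retrieval schedules, and probe bookkeeping.

condition_levels <- function() c("PT", "NPT", "NP", "ABS")
location_levels <- function() c("top", "bottom", "left", "right")

horizontal_locations <- function() c("left", "right")

check_experiment <- function(experiment) {
  experiment <- as.integer(experiment)
  if (!experiment %in% c(1L, 2L)) {
    stop("`experiment` must be 1 or 2", call. = FALSE)
  }
  experiment
}

experiment_conditions <- function(experiment) {
  if (experiment == 1L) c("PT", "NP", "ABS") else c("PT", "NPT", "NP", "ABS")
}

# Per-condition location counts. Locations are exactly balanced overall
# (n/4 per location); within a condition they are exact when the condition
# size divides by 4 and within +/-1 otherwise, allocated by a cyclic scheme
# over the axis-alternating order (left, top, right, bottom). Conditions take
# consecutive cyclic shifts, with PT and NP adjacent, which makes their
# horizontal/vertical counts complementary (required for the cross-axis
# PT-NP pairing in the working-memory phase) and keeps per-location column
# sums exact whenever there are four conditions.
condition_location_counts <- function(conds, n_per_cond) {
  k <- length(conds)
  loc_order <- c("left", "top", "right", "bottom")
  shift_map <- c(PT = 0L, NP = 1L, NPT = 2L, ABS = 3L)
  counts <- matrix(0L, nrow = k, ncol = 4, dimnames = list(conds, loc_order))
  base <- n_per_cond %/% 4L
  r <- n_per_cond %% 4L
  counts[] <- base
  if (r > 0) {
    if (k %% 4L != 0L) {
      stop("cannot balance locations: condition size ", n_per_cond,
           " is not divisible by 4 and the number of conditions (", k,
           ") does not permit a balanced remainder allocation",
           call. = FALSE)
    }
    for (i in seq_len(k)) {
      extra <- (shift_map[[conds[i]]] + seq_len(r) - 1L) %% 4L + 1L
      counts[i, extra] <- counts[i, extra] + 1L
    }
  }
  counts
}

#' Assign objects to experimental conditions and screen locations
#'
#' Partitions `n_objects` object identities at random into the experiment's
#' conditions (Experiment 1: `PT` prioritization+testing, `NP`
#' non-prioritization, `ABS` absent from working memory, one third each;
#' Experiment 2 adds `NPT` non-prioritization+testing, one quarter each) and
#' assigns each object a fixed screen location (`top`, `bottom`, `left`,
#' `right`). Locations are balanced exactly across the whole object set and
#' as evenly as the arithmetic allows within each condition; the `PT` and
#' `NP` conditions receive complementary horizontal/vertical counts so that
#' working-memory displays can always pair them across axes.
#'
#' @param n_objects Number of objects. Must be divisible by the number of
#'   conditions (3 for Experiment 1, 4 for Experiment 2) and by 4.
#' @param experiment `1` or `2`.
#' @param seed Integer seed; the assignment is deterministic given the seed.
#' @return A tibble with one row per object: `object_id`, `location`,
#'   `condition`, `experiment`.
#' @export
#' @examples
#' objs <- assign_conditions(180, experiment = 1, seed = 1)
#' table(objs$condition)
assign_conditions <- function(n_objects, experiment, seed) {
  experiment <- check_experiment(experiment)
  stopifnot(is.numeric(n_objects), n_objects >= 0)
  n_objects <- as.integer(n_objects)
  conds <- experiment_conditions(experiment)
  k <- length(conds)
  if (n_objects == 0L) {
    return(tibble(object_id = integer(), location = character(),
                  condition = character(), experiment = integer()))
  }
  if (n_objects %% k != 0L) {
    stop("`n_objects` (", n_objects, ") must be divisible by the number of ",
         "conditions (", k, ") for experiment ", experiment, call. = FALSE)
  }
  if (n_objects %% 4L != 0L) {
    stop("`n_objects` (", n_objects, ") must be divisible by 4 ",
         "for location balance", call. = FALSE)
  }
  n_per_cond <- n_objects %/% k
  loc_counts <- condition_location_counts(conds, n_per_cond)

  with_seed(seed, {
    ids <- sample_vec(seq_len(n_objects))
    out <- purrr::map_dfr(seq_len(k), function(i) {
      cond_ids <- ids[((i - 1L) * n_per_cond + 1L):(i * n_per_cond)]
      locs <- rep(colnames(loc_counts), times = loc_counts[i, ])
      tibble(
        object_id = cond_ids,
        location = sample_vec(locs),
        condition = conds[i],
        experiment = experiment
      )
    })
    dplyr::arrange(out, .data$object_id)
  })
}

two_pass_schedule <- function(objects, seed, phase) {
  if (nrow(objects) == 0) {
    stop("`objects` must contain at least one object", call. = FALSE)
  }
  with_seed(seed, {
    first <- sample_vec(seq_len(nrow(objects)))
    second <- sample_vec(seq_len(nrow(objects)))
    rows <- objects[c(first, second), c("object_id", "location", "condition")]
    dplyr::mutate(rows,
                  phase = phase,
                  trial_index = dplyr::row_number(),
                  .before = 1)
  })
}

#' Build the encoding-phase schedule
#'
#' Every object is shown twice at its fixed location; the schedule consists
#' of two independently shuffled passes through the full object set, so all
#' objects appear once before any repetition.
#'
#' @param objects Object table from [assign_conditions()].
#' @param seed Integer seed.
#' @return A tibble with one row per trial: `phase`, `trial_index`,
#'   `object_id`, `location`, `condition`.
#' @export
build_encoding_schedule <- function(objects, seed) {
  two_pass_schedule(objects, seed, "encoding")
}

#' Build the retrieval-phase schedule
#'
#' As in encoding, each object is tested twice, in two shuffled passes.
#'
#' @inheritParams build_encoding_schedule
#' @return A tibble with one row per trial, as in [build_encoding_schedule()].
#' @export
build_retrieval_schedule <- function(objects, seed) {
  two_pass_schedule(objects, seed, "retrieval")
}

# Pair two slot vectors (already shuffled) into trials; `a` on one axis,
# `b` on the other.
pair_slots <- function(a, b) {
  stopifnot(length(a) == length(b))
  tibble(first = a, second = b)
}

# Pair a single slot vector with itself avoiding same-object pairs.
pair_within <- function(slots) {
  stopifnot(length(slots) %% 2 == 0)
  n_pairs <- length(slots) / 2
  first <- slots[seq_len(n_pairs)]
  second <- slots[n_pairs + seq_len(n_pairs)]
  for (i in seq_len(n_pairs)) {
    if (first[i] == second[i]) {
      j <- which(first != first[i] & second != first[i])
      j <- j[j != i][1]
      if (is.na(j)) {
        stop("cannot pair objects without repeats within a trial",
             call. = FALSE)
      }
      tmp <- second[i]; second[i] <- second[j]; second[j] <- tmp
    }
  }
  tibble(first = first, second = second)
}

# Exact-count probe-kind vector (randomized block, not Bernoulli).
exact_probe_kinds <- function(n, kinds, weights) {
  counts <- n * weights
  if (any(abs(counts - round(counts)) > 1e-9)) {
    stop("trial count ", n, " does not divide exactly into the probe ",
         "proportions", call. = FALSE)
  }
  sample_vec(rep(kinds, times = round(counts)))
}

#' Build the working-memory-phase schedule
#'
#' Constructs retro-cue working-memory trials. Every working-memory-eligible
#' object (`PT` and `NP`, plus `NPT` in Experiment 2) appears exactly four
#' times. Selective-cue trials pair one `PT` object with one `NP` object,
#' one on the horizontal axis and one on the vertical axis, with the cue
#' pointing at the `PT` object's axis. Experiment 2 adds neutral-cue trials
#' pairing two `NPT` objects. Probe kinds use exact randomized-block counts:
#' selective trials are probed with the cued object on 50% of trials, the
#' non-cued object on 25% and a new object on 25%; neutral trials are probed
#' with one of the two displayed objects (chosen uniformly) on 50% of trials
#' and a new object otherwise. Exactly half of the trials of each cue type
#' therefore require a "no" response. New-object probes are drawn from a
#' reserved identity pool never shown during encoding.
#'
#' @param objects Object table from [assign_conditions()].
#' @param experiment `1` or `2`; must match the table's `experiment` column.
#' @param seed Integer seed.
#' @return A tibble with one row per trial: `phase`, `trial_index`,
#'   `object_horizontal`, `object_vertical`, `cue_type`, `cued_axis`,
#'   `cued_object`, `probe_object`, `probe_kind`, `correct_response`.
#' @export
#' @examples
#' objs <- assign_conditions(180, experiment = 1, seed = 1)
#' wm <- build_wm_schedule(objs, experiment = 1, seed = 2)
#' nrow(wm)                 # 240 trials
#' table(wm$probe_kind)     # exact 120/60/60 match/noncued/new
build_wm_schedule <- function(objects, experiment, seed) {
  experiment <- check_experiment(experiment)
  if (!all(objects$experiment == experiment)) {
    stop("`objects` were assigned for a different experiment", call. = FALSE)
  }
  n_objects <- nrow(objects)
  is_horiz <- objects$location %in% horizontal_locations()

  with_seed(seed, {
    slots4 <- function(ids) sample_vec(rep(ids, each = 4L))

    pt_h <- objects$object_id[objects$condition == "PT" & is_horiz]
    pt_v <- objects$object_id[objects$condition == "PT" & !is_horiz]
    np_h <- objects$object_id[objects$condition == "NP" & is_horiz]
    np_v <- objects$object_id[objects$condition == "NP" & !is_horiz]
    if (length(pt_h) != length(np_v) || length(pt_v) != length(np_h)) {
      stop("object location assignment does not permit cross-axis PT-NP ",
           "pairing; use assign_conditions() for a feasible layout",
           call. = FALSE)
    }

    sel_a <- pair_slots(slots4(pt_h), slots4(np_v))   # PT horizontal
    sel_b <- pair_slots(slots4(pt_v), slots4(np_h))   # PT vertical
    selective <- dplyr::bind_rows(
      tibble(object_horizontal = sel_a$first, object_vertical = sel_a$second,
             cued_axis = "horizontal", cued_object = sel_a$first,
             noncued_object = sel_a$second),
      tibble(object_horizontal = sel_b$second, object_vertical = sel_b$first,
             cued_axis = "vertical", cued_object = sel_b$first,
             noncued_object = sel_b$second)
    )
    selective$cue_type <- "selective"

    neutral <- NULL
    if (experiment == 2L) {
      npt_ids <- objects$object_id[objects$condition == "NPT"]
      pairs <- pair_within(slots4(npt_ids))
      first_h <- objects$location[match(pairs$first, objects$object_id)] %in%
        horizontal_locations()
      neutral <- tibble(
        object_horizontal = ifelse(first_h, pairs$first, pairs$second),
        object_vertical = ifelse(first_h, pairs$second, pairs$first),
        cued_axis = "none",
        cued_object = NA_integer_,
        noncued_object = NA_integer_,
        cue_type = "neutral"
      )
    }

    n_sel <- nrow(selective)
    selective$probe_kind <- exact_probe_kinds(
      n_sel, c("match", "noncued", "new"), c(0.5, 0.25, 0.25))

    if (!is.null(neutral)) {
      n_neu <- nrow(neutral)
      neutral$probe_kind <- exact_probe_kinds(
        n_neu, c("displayed", "absent"), c(0.5, 0.5))
    }

    trials <- dplyr::bind_rows(selective, neutral)
    n_new <- sum(trials$probe_kind %in% c("new", "absent"))
    new_pool <- n_objects + seq_len(n_new)

    trials$probe_object <- NA_integer_
    trials$probe_object[trials$probe_kind == "match"] <-
      trials$cued_object[trials$probe_kind == "match"]
    trials$probe_object[trials$probe_kind == "noncued"] <-
      trials$noncued_object[trials$probe_kind == "noncued"]
    disp <- which(trials$probe_kind == "displayed")
    pick_h <- runif(length(disp)) < 0.5
    trials$probe_object[disp] <- ifelse(
      pick_h, trials$object_horizontal[disp], trials$object_vertical[disp])
    trials$probe_object[trials$probe_kind %in% c("new", "absent")] <- new_pool

    trials$correct_response <- ifelse(
      trials$probe_kind %in% c("match", "displayed"), "yes", "no")

    trials <- trials[sample_vec(seq_len(nrow(trials))), ]
    trials$noncued_object <- NULL
    # Location of the to-be-decoded object: the cued object on selective
    # trials, the horizontally displayed object on neutral trials.
    ref_obj <- dplyr::coalesce(trials$cued_object, trials$object_horizontal)
    trials$cued_location <- objects$location[match(ref_obj, objects$object_id)]
    dplyr::mutate(trials, phase = "wm", trial_index = dplyr::row_number(),
                  .before = 1)
  })
}

#' Count how often each object served as the central probe
#'
#' Tallies, for every object displayed in the working-memory schedule, the
#' number of trials in which it appeared as the central probe (0-4 here).
#' New-object probes (reserved identities never shown at encoding) are not
#' counted as objects, only as probe events for the trials they occur in.
#'
#' @param wm_schedule Schedule from [build_wm_schedule()].
#' @return A tibble `object_id`, `probing_count`, one row per displayed
#'   object.
#' @export
count_probe_instances <- function(wm_schedule) {
  old_ids <- sort(unique(c(wm_schedule$object_horizontal,
                           wm_schedule$object_vertical)))
  probes <- wm_schedule$probe_object[wm_schedule$probe_object %in% old_ids]
  counts <- table(factor(probes, levels = old_ids))
  tibble(object_id = old_ids, probing_count = as.integer(counts))
}

schedule_col_types <- function() {
  readr::cols(
    phase = readr::col_character(),
    trial_index = readr::col_integer(),
    object_id = readr::col_integer(),
    location = readr::col_character(),
    condition = readr::col_character(),
    object_horizontal = readr::col_integer(),
    object_vertical = readr::col_integer(),
    cue_type = readr::col_character(),
    cued_axis = readr::col_character(),
    cued_object = readr::col_integer(),
    cued_location = readr::col_character(),
    probe_object = readr::col_integer(),
    probe_kind = readr::col_character(),
    correct_response = readr::col_character(),
    .default = readr::col_guess()
  )
}

#' Read and write trial schedules as TSV
#'
#' Schedules round-trip losslessly through a plain tab-separated file, one
#' row per trial.
#'
#' @param schedule A schedule tibble.
#' @param path File path.
#' @return `write_schedule()` returns `path` invisibly; `read_schedule()`
#'   returns the schedule tibble.
#' @export
write_schedule <- function(schedule, path) {
  readr::write_tsv(schedule, path)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  # suppress readr's note about typed columns absent from this schedule kind
  # (encoding/retrieval files lack the wm probe columns and vice versa)
  suppressWarnings(
    readr::read_tsv(path, col_types = schedule_col_types(), progress = FALSE))
}
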