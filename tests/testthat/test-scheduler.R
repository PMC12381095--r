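test_that("condition assignment yields exact counts and balanced locations", {
  objs1 <- assign_conditions(180, experiment = 1, seed = 1)
  expect_equal(as.vector(table(objs1$condition)[c("PT", "NP", "ABS")]),
               c(60, 60, 60))
  # exact balance per location overall and within condition (60 divides by 4)
  expect_true(all(table(objs1$location) == 45))
  expect_true(all(table(objs1$condition, objs1$location) == 15))

  objs2 <- assign_conditions(300, experiment = 2, seed = 1)
  expect_equal(as.vector(table(objs2$condition)[c("PT", "NPT", "NP", "ABS")]),
               c(75, 75, 75, 75))
  expect_true(all(table(objs2$location) == 75))
  # within condition within +/-1 of 75/4
  tab <- table(objs2$condition, objs2$location)
  expect_true(all(tab >= 18 & tab <= 19))

  expect_equal(nrow(assign_conditions(0, 1, seed = 1)), 0)
  expect_error(assign_conditions(100, 1, seed = 1), "divisible")
  expect_error(assign_conditions(30, 1, seed = 1), "divisible by 4")
})

test_that("assignment is deterministic in the seed and random across seeds", {
  a <- assign_conditions(24, 1, seed = 7)
  b <- assign_conditions(24, 1, seed = 7)
  cc <- assign_conditions(24, 1, seed = 8)
  expect_identical(a, b)
  expect_false(identical(a$condition, cc$condition) &&
                 identical(a$location, cc$location))
})

test_that("encoding and retrieval schedules show each object twice, all once before repeats", {
  objs <- tiny_objects(12)
  for (builder in list(build_encoding_schedule, build_retrieval_schedule)) {
    sch <- builder(objs, seed = 3)
    expect_equal(nrow(sch), 24)
    expect_true(all(table(sch$object_id) == 2))
    # first pass covers every object exactly once
    expect_setequal(sch$object_id[1:12], objs$object_id)
  }
  expect_equal(nrow(build_encoding_schedule(assign_conditions(180, 1, 1), 2)),
               360)
  expect_equal(nrow(build_encoding_schedule(assign_conditions(300, 2, 1), 2)),
               600)
  one <- objs[1, ]
  sch1 <- build_encoding_schedule(one, seed = 5)
  expect_equal(sch1$object_id, rep(one$object_id, 2))
  expect_error(build_encoding_schedule(objs[0, ], seed = 1), "at least one")
})

test_that("working-memory schedule reproduces the design arithmetic exactly", {
  objs <- assign_conditions(180, 1, seed = 2)
  wm <- build_wm_schedule(objs, 1, seed = 3)
  expect_equal(nrow(wm), 240)
  expect_equal(as.vector(table(wm$probe_kind)[c("match", "noncued", "new")]),
               c(120, 60, 60))
  expect_equal(mean(wm$correct_response == "no"), 0.5)

  # conservation: every PT and NP object appears exactly 4 times
  shown <- c(wm$object_horizontal, wm$object_vertical)
  eligible <- objs$object_id[objs$condition %in% c("PT", "NP")]
  expect_true(all(table(factor(shown, levels = eligible)) == 4))
  expect_equal(length(shown), 4 * length(eligible))
  # ABS objects never shown
  abs_ids <- objs$object_id[objs$condition == "ABS"]
  expect_false(any(shown %in% abs_ids))

  # every selective trial pairs PT (cued) with NP across axes
  cond_of <- function(id) objs$condition[match(id, objs$object_id)]
  expect_true(all(cond_of(wm$cued_object) == "PT"))
  other <- ifelse(wm$cued_object == wm$object_horizontal,
                  wm$object_vertical, wm$object_horizontal)
  expect_true(all(cond_of(other) == "NP"))
  loc_of <- function(id) objs$location[match(id, objs$object_id)]
  expect_true(all(loc_of(wm$object_horizontal) %in% c("left", "right")))
  expect_true(all(loc_of(wm$object_vertical) %in% c("top", "bottom")))
  # cue points at the cued object's axis
  cued_horiz <- wm$cued_object == wm$object_horizontal
  expect_equal(unique(wm$cued_axis[cued_horiz]), "horizontal")

  # new probes come from a reserved pool never shown at encoding
  new_probes <- wm$probe_object[wm$probe_kind == "new"]
  expect_true(all(new_probes > 180))
  expect_false(anyDuplicated(new_probes) > 0)
})

test_that("experiment-2 schedule emits 450 trials with exact neutral-cue bookkeeping", {
  objs <- assign_conditions(300, 2, seed = 4)
  wm <- build_wm_schedule(objs, 2, seed = 5)
  # 75 PT x 4 paired with 75 NP x 4 -> 300 selective; 75 NPT x 4 / 2 -> 150
  expect_equal(nrow(wm), 450)
  expect_equal(sum(wm$cue_type == "selective"), 300)
  expect_equal(sum(wm$cue_type == "neutral"), 150)
  neu <- wm[wm$cue_type == "neutral", ]
  expect_equal(as.vector(table(neu$probe_kind)[c("displayed", "absent")]),
               c(75, 75))
  # exactly half of each cue type requires a "no"
  frac_no <- tapply(wm$correct_response == "no", wm$cue_type, mean)
  expect_equal(as.vector(frac_no), c(0.5, 0.5))
  # neutral trials pair two distinct NPT objects
  cond_of <- function(id) objs$condition[match(id, objs$object_id)]
  expect_true(all(cond_of(neu$object_horizontal) == "NPT"))
  expect_true(all(cond_of(neu$object_vertical) == "NPT"))
  expect_false(any(neu$object_horizontal == neu$object_vertical))
  # displayed probes are one of the two shown objects
  disp <- neu[neu$probe_kind == "displayed", ]
  expect_true(all(disp$probe_object == disp$object_horizontal |
                    disp$probe_object == disp$object_vertical))
})

test_that("probe-instance counting satisfies the accounting identity", {
  # hand-built case: object 7 probed twice
  sch <- tibble::tibble(
    phase = "wm", trial_index = 1:3,
    object_horizontal = c(7L, 7L, 8L), object_vertical = c(9L, 10L, 7L),
    probe_object = c(7L, 7L, 100L), probe_kind = c("match", "match", "new")
  )
  pc <- count_probe_instances(sch)
  expect_equal(pc$probing_count[pc$object_id == 7], 2)
  expect_equal(sum(pc$probing_count), 2)

  # all-new probes -> all counts zero
  sch$probe_object <- c(100L, 101L, 102L)
  expect_true(all(count_probe_instances(sch)$probing_count == 0))

  # experiment-2 default: counts in 0..4 and the grand total equals the
  # number of old-object probe events
  objs <- assign_conditions(300, 2, seed = 4)
  wm <- build_wm_schedule(objs, 2, seed = 5)
  pc2 <- count_probe_instances(wm)
  expect_true(all(pc2$probing_count %in% 0:4))
  n_old_probe_trials <- sum(wm$probe_kind %in% c("match", "noncued", "displayed"))
  expect_equal(sum(pc2$probing_count), n_old_probe_trials)
})

test_that("schedules round-trip losslessly through TSV", {
  objs <- tiny_objects(12)
  wm <- build_wm_schedule(objs, 1, seed = 6)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_schedule(wm, path)
  back <- read_schedule(path)
  expect_equal(as.data.frame(back), as.data.frame(wm))

  # byte-identical serialization for identical inputs and seed
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_schedule(build_wm_schedule(objs, 1, seed = 6), path2)
  expect_identical(readBin(path, "raw", file.size(path)),
                   readBin(path2, "raw", file.size(path2)))
})

test_that("infeasible pairings raise scheduling errors", {
  objs <- tiny_objects(12)
  # force every PT object onto the horizontal axis: cross-axis pairing with
  # NP becomes impossible
  bad <- objs
  bad$location[bad$condition == "PT"] <- "left"
  expect_error(build_wm_schedule(bad, 1, seed = 1), "cross-axis")
  expect_error(build_wm_schedule(objs, 2, seed = 1), "different experiment")
})
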