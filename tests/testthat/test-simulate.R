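# Synthetic cohort generator: class signatures, stride schedules, seeding.

test_that("class signatures encode the gait-class directions", {
  normal <- class_signature("normal")
  expect_equal(normal$stance_fraction_left, normal$stance_fraction_right)
  expect_equal(normal$step_length_scale_left, normal$step_length_scale_right)

  sup <- class_signature("supination")
  expect_lt(sup$heel_metatarsal_gap, normal$heel_metatarsal_gap)
  expect_gt(sup$lateral_weight_share, normal$lateral_weight_share)

  ul <- class_signature("unstable_left")
  expect_lt(ul$step_length_scale_left, 1.0)
  expect_equal(ul$step_length_scale_right, 1.0)
  expect_lt(ul$step_length_scale_left, ul$step_length_scale_right)
  expect_false(ul$stance_fraction_left == normal$stance_fraction_left)

  ur <- class_signature("unstable_right")
  expect_equal(ur$step_length_scale_left, ul$step_length_scale_right)
  expect_equal(ur$stance_fraction_right, ul$stance_fraction_left)

  # every pair of distinct classes differs in at least one parameter
  fields <- setdiff(names(unclass(normal)), "gait_class")
  sigs <- lapply(gait_classes(), class_signature)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_false(
      isTRUE(all.equal(unclass(sigs[[i]])[fields], unclass(sigs[[j]])[fields])),
      info = paste(gait_classes()[i], "vs", gait_classes()[j])
    )
  }
})

test_that("signature overrides are applied and validated", {
  s <- class_signature("normal", overrides = list(stance_fraction_left = 0.7))
  expect_equal(s$stance_fraction_left, 0.7)
  expect_error(class_signature("limping"), "valid classes")
  expect_error(class_signature("normal", overrides = list(bogus = 1)),
               "unknown signature field")
  expect_error(class_signature("normal",
                               overrides = list(stance_fraction_left = 1.2)),
               "fraction")
})

test_that("recordings are deterministic and reject too-short durations", {
  p <- participant_profile(1, 42)
  sig <- class_signature("normal")
  r1 <- simulate_recording(p, sig, duration = 5)
  r2 <- simulate_recording(p, sig, duration = 5)
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$ground_truth, r2$ground_truth)
  expect_error(simulate_recording(p, sig, duration = 0.2), "shorter than one")
})

test_that("heel-strike count matches duration times cadence", {
  rec <- cadence60_recording()  # 60 s at 60 strides/min
  hs <- rec$ground_truth[rec$ground_truth$foot == "right" &
                           rec$ground_truth$event_type == "heel_strike", ]
  expect_gte(nrow(hs), 59)
  expect_lte(nrow(hs), 61)
})

test_that("contact fraction recovers the generating stance fraction", {
  p <- participant_profile(3, 42)
  sig <- class_signature("normal")
  rec <- simulate_recording(p, sig, duration = 40)
  contact <- detect_contact(rec)
  for (foot in c("left", "right")) {
    truth <- sig[[paste0("stance_fraction_", foot)]] * p$stance_scale
    expect_equal(mean(contact[, foot]), truth, tolerance = 0.02 / truth)
  }
})

test_that("pressure stays in ADC range and threshold 40 splits burst from baseline", {
  rec <- cadence60_recording()
  press <- rec$samples[, layout_channels(sensors = "pressure")]
  expect_true(all(press >= 0 & press <= 1023))
  # baseline: samples well inside right swing on the right heel channel
  gt <- rec$ground_truth
  to <- gt$time[gt$foot == "right" & gt$event_type == "toe_off"]
  hs <- gt$time[gt$foot == "right" & gt$event_type == "heel_strike"]
  base_idx <- unlist(lapply(to[1:20], function(tt) {
    nxt <- min(hs[hs > tt])
    round((tt + 0.1) * 100):round((nxt - 0.1) * 100)
  }))
  baseline <- rec$samples[base_idx, "right_pressure_heel"]
  expect_lt(mean(baseline) + 5 * sd(baseline), 40)
  expect_gt(max(rec$samples[, "right_pressure_heel"]), 40)
})

test_that("ground-truth events alternate heel strike then toe off per foot", {
  for (rec in tiny_cohort()[1:5]) {
    for (foot in c("left", "right")) {
      hs <- rec$ground_truth$time[rec$ground_truth$foot == foot &
                                    rec$ground_truth$event_type == "heel_strike"]
      to <- rec$ground_truth$time[rec$ground_truth$foot == foot &
                                    rec$ground_truth$event_type == "toe_off"]
      expect_true(all(diff(hs) > 0) && all(diff(to) > 0))
      m <- min(length(hs) - 1, length(to))
      expect_true(all(hs[1:m] < to[1:m]))
      expect_true(all(to[1:m] < hs[2:(m + 1)]))
    }
  }
})

test_that("cohorts have 5 recordings per participant and obey the seed contract", {
  short <- c(normal = 6, unstable_left = 3, unstable_right = 3,
             supination = 3, pronation = 3)
  cohort <- simulate_cohort(18, seed = 3, durations_per_class = short)
  expect_length(cohort, 90)
  expect_equal(sort(unique(vapply(cohort, `[[`, integer(1), "participant_id"))),
               1:18)
  again <- simulate_cohort(3, seed = 3, durations_per_class = short)
  expect_identical(lapply(cohort[1:15], `[[`, "samples"),
                   lapply(again, `[[`, "samples"))
  other <- simulate_cohort(3, seed = 4, durations_per_class = short)
  expect_false(identical(cohort[[1]]$samples, other[[1]]$samples))
  expect_error(simulate_cohort(1, seed = 1), ">= 2")
})

test_that("default durations make normal recordings 3x the abnormal ones", {
  cohort <- simulate_cohort(2, seed = 9)
  n <- vapply(cohort, function(r) nrow(r$samples), numeric(1))
  cls <- vapply(cohort, `[[`, character(1), "gait_class")
  expect_equal(unique(n[cls == "normal"] / n[cls == "pronation"]), 3)
})

test_that("participant profiles are pure functions of (seed, id)", {
  expect_identical(participant_profile(7, 123), participant_profile(7, 123))
  expect_false(identical(participant_profile(7, 123),
                         participant_profile(8, 123)))
})

test_that("recordings round-trip through CSV plus JSON sidecar", {
  dir <- withr::local_tempdir()
  rec <- tiny_cohort()[[2]]
  path <- write_recording(rec, dir)
  back <- read_recording(path)
  expect_equal(back$samples, rec$samples, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$gait_class, rec$gait_class)
  expect_equal(back$ground_truth$time, rec$ground_truth$time,
               tolerance = 1e-12)
  expect_equal(unclass(back$signature), unclass(rec$signature))
})
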