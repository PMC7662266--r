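# Contact detection, event detection and the seven segmentation schemes.

test_that("contact detection follows the any-sensor threshold rule", {
  rec <- square_wave_recording(on_samples = 20, off_samples = 70)
  contact <- detect_contact(rec, threshold = 40)
  phase <- (seq_len(nrow(rec$samples)) - 1) %% 100
  expect_identical(unname(contact[, "right"]), phase >= 20 & phase < 70)
  expect_false(any(contact[, "left"]))

  silent <- square_wave_recording(on_samples = 20, off_samples = 70, high = 0)
  expect_false(any(detect_contact(silent)))

  expect_error(detect_contact(rec, threshold = 0))
  no_press <- rec
  no_press$samples <- rec$samples[, 5:20]
  expect_error(detect_contact(no_press), "pressure")
})

test_that("events fire exactly at square-wave edges", {
  rec <- square_wave_recording(on_samples = 20, off_samples = 70, n = 400)
  ev <- detect_events(detect_contact(rec), rec$sampling_rate)
  hs <- ev$sample_index[ev$event_type == "heel_strike"]
  to <- ev$sample_index[ev$event_type == "toe_off"]
  expect_equal(hs, c(21, 121, 221, 321))
  expect_equal(to, c(71, 171, 271, 371))
})

test_that("constant contact and sub-debounce spikes yield no events", {
  n <- 200
  contact <- cbind(left = rep(TRUE, n), right = rep(FALSE, n))
  expect_equal(nrow(detect_events(contact, 100)), 0)
  contact[, "right"] <- FALSE
  contact[100, "right"] <- TRUE  # 10 ms spike, default debounce 50 ms
  expect_equal(nrow(detect_events(contact, 100)), 0)
})

test_that("detected heel strikes match simulator ground truth within 2 samples", {
  for (rec in tiny_cohort()[c(1, 3, 5)]) {
    ev <- detect_events(detect_contact(rec), rec$sampling_rate)
    for (foot in c("left", "right")) {
      for (type in c("heel_strike", "toe_off")) {
        det <- ev$time[ev$foot == foot & ev$event_type == type]
        gt <- rec$ground_truth$time[rec$ground_truth$foot == foot &
                                      rec$ground_truth$event_type == type]
        # match each detected event to its nearest ground-truth event
        expect_gt(length(det), 0)
        err <- vapply(det, function(tt) min(abs(gt - tt)), numeric(1))
        expect_lte(max(err) * rec$sampling_rate, 2)
      }
    }
  }
})

test_that("events alternate strictly per foot after debouncing", {
  for (rec in tiny_cohort()[1:5]) {
    ev <- detect_events(detect_contact(rec), rec$sampling_rate)
    for (foot in c("left", "right")) {
      sub <- ev[ev$foot == foot, ]
      sub <- sub[order(sub$time), ]
      expect_true(all(sub$event_type[-1] != sub$event_type[-nrow(sub)]))
    }
  }
})

test_that("stride and step counts follow cadence arithmetic", {
  rec <- cadence60_recording()  # 60 s, 60 strides/min
  strides <- segment_recording(rec, "stride")
  steps <- segment_recording(rec, "step")
  expect_gte(nrow(strides), 58)
  expect_lte(nrow(strides), 60)
  expect_gte(nrow(steps), 2 * nrow(strides) - 2)
  expect_lte(nrow(steps), 2 * nrow(strides) + 2)
})

test_that("stance plus swing partitions each stride exactly", {
  rec <- cadence60_recording()
  stance <- segment_recording(rec, "stance")
  swing <- segment_recording(rec, "swing")
  stride <- segment_recording(rec, "stride")
  # each stance segment's end is the start of a swing segment, whose end is
  # the next stride boundary
  for (i in seq_len(min(nrow(stance), nrow(swing)) - 1)) {
    expect_equal(swing$start_index[i], stance$end_index[i])
  }
  k <- min(nrow(stride), nrow(stance), nrow(swing))
  stride_len <- stride$end_index[1:k] - stride$start_index[1:k]
  expect_equal(
    (stance$end_index[1:k] - stance$start_index[1:k]) +
      (swing$end_index[1:k] - swing$start_index[1:k]),
    stride_len
  )
})

test_that("mean stance fraction recovers the generator value", {
  p <- participant_profile(2, 42)
  sig <- class_signature("normal")
  rec <- simulate_recording(p, sig, duration = 40)
  stance <- segment_recording(rec, "stance")
  stride <- segment_recording(rec, "stride")
  frac <- mean(stance$end_index - stance$start_index) /
    mean(stride$end_index - stride$start_index)
  expect_equal(frac, sig$stance_fraction_right * p$stance_scale,
               tolerance = 0.02 / 0.6)
})

test_that("mean segment lengths follow the scheme-length ordering", {
  rec <- cadence60_recording()
  mean_len <- vapply(SEGMENT_SCHEMES, function(s) {
    seg <- segment_recording(rec, s)
    mean(seg$end_index - seg$start_index)
  }, numeric(1))
  expect_gt(mean_len[["stride"]], mean_len[["stance"]])
  expect_gt(mean_len[["stance"]], mean_len[["step"]])
  expect_gt(mean_len[["step"]], mean_len[["swing"]])
  # swing and the opposite foot's single support are the same interval in
  # idealized gait; allow a one-sample tie
  expect_gte(mean_len[["swing"]] + 1,
             mean_len[["left_single_limb_support"]])
  expect_gt(mean_len[["left_single_limb_support"]],
            mean_len[["double_limb_support"]])
  expect_gt(mean_len[["right_single_limb_support"]],
            mean_len[["double_limb_support"]])
})

test_that("raising the threshold never increases total contact time", {
  rec <- tiny_cohort()[[1]]
  totals <- vapply(c(40, 100, 300, 600), function(th)
    sum(detect_contact(rec, th)), numeric(1))
  expect_true(all(diff(totals) <= 0))
})

test_that("too few events give an empty segment table with a warning", {
  rec <- square_wave_recording(on_samples = 0, off_samples = 100, n = 300)
  # always in contact: no transitions at all
  expect_warning(out <- segment_recording(rec, "stride"), "usable")
  expect_equal(nrow(out), 0)
})
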