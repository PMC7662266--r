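# Shared fixtures, built once per test run and memoised. All synthetic, all
# seeded; sizes are kept small so the whole suite stays fast.

.fixtures <- new.env(parent = emptyenv())

.memo <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# 2-participant cohort with shortened recordings: enough strides for feature
# tables, cheap enough to rebuild pipelines on.
tiny_cohort <- function() .memo("tiny_cohort", function() {
  simulate_cohort(2, seed = 11,
                  durations_per_class = c(normal = 30, unstable_left = 15,
                                          unstable_right = 15,
                                          supination = 15, pronation = 15),
                  noise_scale = 0.5)
})

tiny_segments <- function() .memo("tiny_segments", function() {
  segment_cohort(tiny_cohort(), scheme = "stride")
})

# Full 224-column battery on the tiny cohort's strides.
tiny_table_full <- function() .memo("tiny_table_full", function() {
  build_feature_table(tiny_segments(), tiny_cohort(), include_discarded = TRUE)
})

tiny_table <- function() .memo("tiny_table", function() {
  apply_discard_rule(tiny_table_full())
})

# One normal recording with a known profile (cadence forced to 60 so stride
# arithmetic is exact).
cadence60_recording <- function() .memo("cadence60_recording", function() {
  profile <- participant_profile(1, 42)
  profile$cadence <- 60
  simulate_recording(profile, class_signature("normal"), duration = 60)
})

# A fake recording with a single square-wave pressure channel: known contact
# edges, all other channels silent.
square_wave_recording <- function(on_samples, off_samples, n = 400,
                                  period = 100, high = 500) {
  layout <- sensor_layout()
  samples <- matrix(0, nrow = n, ncol = nrow(layout),
                    dimnames = list(NULL, layout$channel))
  phase <- (seq_len(n) - 1) %% period
  samples[phase >= on_samples & phase < off_samples, "right_pressure_heel"] <- high
  structure(list(participant_id = 1L, gait_class = "normal",
                 sampling_rate = 100, samples = samples,
                 ground_truth = NULL), class = "gait_recording")
}

random_confusion <- function(n_classes = 5, max_count = 30) {
  m <- matrix(sample.int(max_count + 1L, n_classes^2, replace = TRUE) - 1L,
              n_classes, n_classes,
              dimnames = list(gait_classes()[seq_len(n_classes)],
                              gait_classes()[seq_len(n_classes)]))
  if (sum(m) == 0) m[1, 1] <- 1L
  m
}

# Random-valued table with the canonical full-battery column names.
random_full_table <- function(n_rows = 20, seed = 5) {
  set.seed(seed)
  cols <- smartgait:::feature_column_names()
  out <- as.data.frame(matrix(rnorm(n_rows * length(cols)), n_rows,
                              dimnames = list(NULL, cols)))
  out$gait_class <- sample(gait_classes(), n_rows, replace = TRUE)
  out$participant_id <- rep_len(1:2, n_rows)
  out
}
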