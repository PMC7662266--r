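# Synthetic smart-shoe cohort generator.
#
# The generator lays down a deterministic stride schedule per recording and
# renders, per foot: raised-cosine-edged pressure bursts with sensor-specific
# onset/offset fractions inside stance, an accelerometer heel-strike impact
# transient plus cycle-locked oscillation, and a gyroscope swing-phase
# angular-velocity peak. All noise is seeded, and the exact modelled
# heel-strike/toe-off times are exported as ground truth so downstream event
# detection and segmentation can be tested against the schedule that built
# the signal.

# Deterministic per-(seed, participant) stream seed, kept below 2^31.
.mix_seed <- function(seed, id) {
  (((seed %% 50021L) * 40009) + id * 7919) %% 2147483629
}

.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Participant profile for the synthetic cohort
#'
#' Inter-subject variability is modelled as per-participant multiplicative
#' perturbations: cadence uniform on 55-65 strides/min, log-normal amplitude
#' and noise scales, and a small log-normal perturbation of the stance
#' fraction. Profiles are a pure function of `(seed, participant_id)` — the
#' same pair always yields the same profile, independent of generation order.
#'
#' @param participant_id Positive integer.
#' @param seed Cohort seed (integer).
#' @return List of class `"gait_profile"`: `participant_id`, `cadence`
#'   (strides/min), `amplitude_scale`, `noise_scale`, `stance_scale`
#'   (multiplier applied to the signature's stance fractions) and `rng_seed`.
#' @export
participant_profile <- function(participant_id, seed) {
  stopifnot(length(participant_id) == 1L, participant_id >= 1)
  .with_seed(.mix_seed(seed, participant_id), {
    list(
      participant_id = as.integer(participant_id),
      cadence = stats::runif(1, 55, 65),
      amplitude_scale = exp(stats::rnorm(1, 0, 0.10)),
      noise_scale = exp(stats::rnorm(1, 0, 0.15)),
      stance_scale = exp(stats::rnorm(1, 0, 0.03)),
      rng_seed = sample.int(2147483629L, 1L)
    ) |> structure(class = "gait_profile")
  })
}

# Half-cosine-edged burst on the sample time grid: ramps of `ramp` seconds at
# each end of [on, off], flat top in between. Degenerates to a raised cosine
# when the window is shorter than two ramps.
.burst <- function(t, on, off, amp, ramp = 0.03) {
  w <- off - on
  if (w <= 0) return(numeric(length(t)))
  ramp <- min(ramp, w / 2)
  y <- numeric(length(t))
  inside <- t >= on & t <= off
  u <- t[inside] - on
  env <- rep(1, length(u))
  env[u < ramp] <- 0.5 * (1 - cos(pi * u[u < ramp] / ramp))
  d <- w - u
  env[d < ramp] <- pmin(env[d < ramp], 0.5 * (1 - cos(pi * d[d < ramp] / ramp)))
  y[inside] <- amp * env
  y
}

#' Simulate one smart-shoe recording
#'
#' Renders a 20-channel recording of one participant walking with one gait
#' class. The stride schedule is deterministic: right heel strikes are evenly
#' spaced at the profile's cadence, the left heel strike falls a
#' step-length-weighted fraction of the stride later, and each foot leaves the
#' ground after its stance fraction of the stride. Pressure is in ADC-like
#' arbitrary units on \[0, 1023\] so that the conventional contact threshold of
#' 40 cleanly separates burst from baseline at default noise.
#'
#' Stride-to-stride variability: human gait is not metronomic — successive
#' strides vary by a few percent in timing and rather more in force. Each
#' stride therefore gets its own jitter on the heel-strike time (Gaussian,
#' `timing` seconds), on the burst/oscillation amplitudes (log-normal,
#' `amplitude` sigma) and on the stance duration (log-normal, `stance`
#' sigma). This biological variability is deliberately independent of the
#' sensor `noise_scale`: a noiseless sensor still records a variable walker,
#' and without it every participant would collapse to a single point in
#' feature space, making leave-one-participant-out evaluation degenerate.
#' Ground-truth events report the jittered (actual) times.
#'
#' @param profile A [participant_profile()].
#' @param signature A [class_signature()].
#' @param duration Recording length in seconds (must fit at least one stride).
#' @param sampling_rate Sampling rate in Hz (default 100).
#' @param stride_variability Named list with elements `timing` (seconds),
#'   `amplitude` and `stance` (log-normal sigmas); see above.
#' @return A list of class `"gait_recording"`: `participant_id`, `gait_class`,
#'   `sampling_rate`, `samples` (time-by-channel numeric matrix, columns in
#'   [sensor_layout()] order) and `ground_truth` (data.frame with columns
#'   `foot`, `event_type` in `{heel_strike, toe_off}`, `time` in seconds).
#' @examples
#' rec <- simulate_recording(participant_profile(1, 42),
#'                           class_signature("normal"), duration = 10)
#' dim(rec$samples)
#' @export
simulate_recording <- function(profile, signature, duration,
                               sampling_rate = 100,
                               stride_variability = list(timing = 0.02,
                                                         amplitude = 0.08,
                                                         stance = 0.02)) {
  stopifnot(inherits(profile, "gait_profile"),
            inherits(signature, "gait_signature"),
            duration > 0, sampling_rate > 0)
  T_stride <- 60 / profile$cadence
  if (duration < T_stride) {
    stop("duration (", duration, " s) is shorter than one stride (",
         round(T_stride, 2), " s)")
  }
  fs <- sampling_rate
  n <- floor(duration * fs)
  t <- (seq_len(n) - 1) / fs
  layout <- sensor_layout()
  samples <- matrix(0, nrow = n, ncol = nrow(layout),
                    dimnames = list(NULL, layout$channel))

  sl <- signature$step_length_scale_left
  sr <- signature$step_length_scale_right
  step_frac_left <- sl / (sl + sr)   # right HS -> left HS, fraction of stride
  lead_in <- 0.1
  grid <- list(
    right = seq(lead_in, duration, by = T_stride),
    left = seq(lead_in + step_frac_left * T_stride, duration, by = T_stride)
  )
  stance <- c(left = min(signature$stance_fraction_left * profile$stance_scale, 0.95),
              right = min(signature$stance_fraction_right * profile$stance_scale, 0.95))
  step_scale <- c(left = sl, right = sr)
  sv <- stride_variability

  gt <- list()
  seed <- (profile$rng_seed +
           match(signature$gait_class, gait_classes()) * 9973) %% 2147483629
  .with_seed(seed, {
    for (foot in c("left", "right")) {
      K <- length(grid[[foot]])
      # per-stride biological jitter: actual heel-strike times, stance
      # durations and amplitude factors
      hs_f <- grid[[foot]] + stats::rnorm(K, 0, sv$timing)
      S_k <- stance[[foot]] * T_stride * exp(stats::rnorm(K, 0, sv$stance))
      amp_k <- exp(stats::rnorm(K, 0, sv$amplitude))
      lws <- signature$lateral_weight_share
      amp0 <- 600 * profile$amplitude_scale
      # (onset fraction of stance, offset fraction, peak amplitude) per sensor;
      # the metatarsal onset is an absolute gap in seconds, capped to stay
      # inside stance
      sensor_amp <- c(pressure_heel = amp0,
                      pressure_lateral_midfoot = amp0 * 0.9 * 2 * lws,
                      pressure_medial_forefoot = amp0 * 0.9 * 2 * (1 - lws),
                      pressure_toe = amp0 * 0.8)
      onsets <- function(S) c(0, 0.15 * S,
                              min(signature$heel_metatarsal_gap, 0.45 * S),
                              0.45 * S)
      offsets <- function(S) c(0.65, 0.80, 0.95, 1.00) * S

      toe_off <- hs_f + S_k
      keep <- hs_f >= 0 & hs_f <= duration
      gt[[foot]] <- data.frame(
        foot = rep(foot, sum(keep) + sum(toe_off <= duration & keep)),
        event_type = rep(c("heel_strike", "toe_off"),
                         c(sum(keep), sum(toe_off <= duration & keep))),
        time = c(hs_f[keep], toe_off[keep & toe_off <= duration])
      )

      press <- matrix(0, n, 4, dimnames = list(NULL, names(sensor_amp)))
      for (k in seq_len(K)) {
        on_k <- onsets(S_k[k])
        off_k <- offsets(S_k[k])
        for (j in 1:4) {
          press[, j] <- press[, j] +
            .burst(t, hs_f[k] + on_k[j], hs_f[k] + off_k[j],
                   sensor_amp[j] * amp_k[k])
        }
      }
      for (ch in colnames(press)) {
        noise <- stats::rnorm(n, mean = 5, sd = 3 * profile$noise_scale)
        samples[, paste0(foot, "_", ch)] <-
          pmin(pmax(press[, ch] + noise, 0), 1023)
      }

      # IMU: phase-locked oscillation with a per-stride amplitude envelope,
      # a heel-strike impact transient and a swing-phase angular-velocity peak
      phase <- 2 * pi * (t - grid[[foot]][1]) / T_stride
      env <- amp_k[pmax(findInterval(t, grid[[foot]]), 1L)]
      ss <- step_scale[[foot]]
      as <- profile$amplitude_scale
      imp <- numeric(n)
      for (k in seq_len(K)) {
        sel <- t >= hs_f[k] & t < hs_f[k] + 0.08
        dt <- t[sel] - hs_f[k]
        imp[sel] <- imp[sel] +
          4 * as * ss * amp_k[k] * exp(-dt / 0.02) * cos(2 * pi * 25 * dt)
      }
      swing_pk <- numeric(n)
      for (k in seq_len(K)) {
        swing_end <- if (k < K) hs_f[k + 1] else hs_f[k] + T_stride
        swing_pk <- swing_pk + .burst(t, hs_f[k] + S_k[k], swing_end,
                                      200 * as * ss * amp_k[k], ramp = 0.08)
      }
      imu <- list(
        acc_x = env * (0.8 * as * ss * sin(phase) + 0.2 * as * sin(2 * phase)),
        acc_y = env * 0.6 * as * sin(2 * phase + pi / 4),
        acc_z = 1 + imp + env * 0.5 * as * sin(phase + pi / 3),
        gyro_x = env * 30 * as * (1 + 5 * (stance[[foot]] - 0.6)) * sin(phase),
        gyro_y = swing_pk - env * 40 * as * sin(phase),
        gyro_z = env * as *
          (300 * (lws - 0.5) * sin(phase) +
             400 * (signature$heel_metatarsal_gap - 0.12) * cos(phase))
      )
      imu_sd <- c(acc_x = 0.15, acc_y = 0.15, acc_z = 0.15,
                  gyro_x = 8, gyro_y = 8, gyro_z = 8)
      for (ch in names(imu)) {
        samples[, paste0(foot, "_", ch)] <-
          imu[[ch]] + stats::rnorm(n, 0, imu_sd[[ch]] * profile$noise_scale)
      }
    }
  })

  ground_truth <- rbind(gt$left, gt$right)
  ground_truth <- ground_truth[order(ground_truth$time), ]
  rownames(ground_truth) <- NULL
  structure(list(
    participant_id = profile$participant_id,
    gait_class = signature$gait_class,
    sampling_rate = fs,
    samples = samples,
    signature = signature,
    ground_truth = ground_truth
  ), class = "gait_recording")
}

#' @export
print.gait_recording <- function(x, ...) {
  cat("<gait_recording> participant", x$participant_id,
      "class", x$gait_class, "-", nrow(x$samples), "samples @",
      x$sampling_rate, "Hz,", nrow(x$ground_truth), "ground-truth events\n")
  invisible(x)
}

#' Simulate a labelled cohort
#'
#' Generates one recording per (participant, gait class): by default 3 minutes
#' of normal walking and 1 minute of each of the four abnormal gaits,
#' mirroring a treadmill acquisition protocol. Per-participant profiles are
#' derived deterministically from the cohort seed, and each participant's
#' stance fractions are additionally perturbed by the profile's `stance_scale`
#' so that leave-one-participant-out evaluation faces genuine between-subject
#' variability.
#'
#' @param n_participants Number of participants (>= 2; LOOCV needs at least 2).
#' @param seed Cohort seed.
#' @param durations_per_class Named numeric vector of seconds per class;
#'   classes not named keep the defaults (normal 180, others 60).
#' @param sampling_rate Hz.
#' @param noise_scale Global multiplier on every participant's noise scale
#'   (1 = default study conditions; lower it for separability experiments).
#' @param signature_overrides Named list: per gait class, a list of signature
#'   overrides passed to [class_signature()].
#' @return List of `"gait_recording"` objects, length `5 * n_participants`.
#' @examples
#' cohort <- simulate_cohort(2, seed = 1,
#'                           durations_per_class = c(normal = 20, unstable_left = 10,
#'                                                   unstable_right = 10, supination = 10,
#'                                                   pronation = 10))
#' length(cohort)
#' @export
simulate_cohort <- function(n_participants, seed,
                            durations_per_class = NULL,
                            sampling_rate = 100,
                            noise_scale = 1,
                            signature_overrides = list()) {
  if (n_participants < 2) {
    stop("n_participants must be >= 2 (leave-one-participant-out needs >= 2)")
  }
  durations <- c(normal = 180, unstable_left = 60, unstable_right = 60,
                 supination = 60, pronation = 60)
  if (!is.null(durations_per_class)) {
    stopifnot(!is.null(names(durations_per_class)))
    durations[names(durations_per_class)] <- durations_per_class
  }
  recs <- vector("list", n_participants * 5L)
  i <- 0L
  for (pid in seq_len(n_participants)) {
    profile <- participant_profile(pid, seed)
    profile$noise_scale <- profile$noise_scale * noise_scale
    for (cls in gait_classes()) {
      sig <- class_signature(cls, signature_overrides[[cls]] %||% list())
      i <- i + 1L
      recs[[i]] <- simulate_recording(profile, sig, durations[[cls]],
                                      sampling_rate)
    }
  }
  recs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a recording as CSV plus JSON sidecar
#'
#' The CSV holds `time_s` followed by the 20 layout-ordered channels; the JSON
#' sidecar carries participant id, gait class, sampling rate, the signature
#' parameters and the ground-truth events.
#'
#' @param recording A `"gait_recording"`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the CSV path.
#' @export
write_recording <- function(recording, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- sprintf("p%02d_%s", recording$participant_id, recording$gait_class)
  csv <- file.path(dir, paste0(stem, ".csv"))
  n <- nrow(recording$samples)
  df <- data.frame(time_s = (seq_len(n) - 1) / recording$sampling_rate,
                   recording$samples, check.names = FALSE)
  utils::write.csv(df, csv, row.names = FALSE)
  meta <- list(
    participant_id = recording$participant_id,
    gait_class = recording$gait_class,
    sampling_rate = recording$sampling_rate,
    signature = unclass(recording$signature),
    ground_truth = recording$ground_truth
  )
  jsonlite::write_json(meta, file.path(dir, paste0(stem, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(csv)
}

#' @rdname write_recording
#' @param csv_path Path to a recording CSV written by [write_recording()].
#' @export
read_recording <- function(csv_path) {
  df <- utils::read.csv(csv_path, check.names = FALSE)
  meta <- jsonlite::read_json(sub("\\.csv$", ".json", csv_path),
                              simplifyVector = TRUE)
  sig <- meta$signature
  cls <- sig$gait_class
  sig$gait_class <- NULL
  structure(list(
    participant_id = meta$participant_id,
    gait_class = meta$gait_class,
    sampling_rate = meta$sampling_rate,
    samples = as.matrix(df[, setdiff(names(df), "time_s")]),
    signature = class_signature(cls, sig),
    ground_truth = as.data.frame(meta$ground_truth)
  ), class = "gait_recording")
}
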