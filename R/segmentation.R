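# Gait-event detection and gait-cycle segmentation.
#
# Foot contact is decided from the pressure channels alone: a foot is on the
# ground at sample i iff any of its four pressure sensors reads at or above
# the threshold (default 40 ADC units). Heel strikes and toe-offs are the
# onset/offset edges of the debounced contact series, and the seven
# segmentation schemes are cut from those events.

SEGMENT_SCHEMES <- c("stride", "step", "stance", "swing",
                     "left_single_limb_support", "right_single_limb_support",
                     "double_limb_support")

#' Per-foot ground-contact series
#'
#' @param recording A `"gait_recording"`.
#' @param threshold Pressure threshold in ADC units (> 0). 40 is the
#'   conventional value separating contact bursts from baseline noise.
#' @return Logical matrix (time x 2) with columns `left`, `right`.
#' @export
detect_contact <- function(recording, threshold = 40) {
  stopifnot(threshold > 0)
  layout <- sensor_layout()
  press <- layout$channel[layout$sensor == "pressure"]
  if (!all(press %in% colnames(recording$samples))) {
    stop("recording lacks pressure channels; contact detection needs pressure")
  }
  contact <- sapply(c("left", "right"), function(foot) {
    ch <- press[startsWith(press, foot)]
    rowSums(recording$samples[, ch, drop = FALSE] >= threshold) > 0
  })
  colnames(contact) <- c("left", "right")
  contact
}

# Remove runs shorter than min_samples by flipping the shortest offending run
# into its neighbours, repeatedly; interior runs only are considered first so
# truncated boundary phases survive as leading/trailing context.
.debounce <- function(x, min_samples) {
  if (min_samples <= 1L || length(x) == 0L) return(x)
  repeat {
    r <- rle(x)
    if (length(r$lengths) <= 1L) return(x)
    interior <- seq_along(r$lengths)[-c(1L, length(r$lengths))]
    short <- interior[r$lengths[interior] < min_samples]
    if (!length(short)) return(x)
    k <- short[which.min(r$lengths[short])]
    start <- sum(r$lengths[seq_len(k - 1L)]) + 1L
    x[start:(start + r$lengths[k] - 1L)] <- !r$values[k]
  }
}

#' Detect heel-strike and toe-off events
#'
#' A heel strike is a false-to-true transition of the debounced contact
#' series, a toe-off a true-to-false transition. Contact phases (and gaps)
#' shorter than `min_phase_duration` are merged into their neighbours first,
#' so isolated noise spikes produce no events.
#'
#' @param contact Logical matrix from [detect_contact()].
#' @param sampling_rate Hz.
#' @param min_phase_duration Debounce window in seconds (default 0.05).
#' @return data.frame with columns `foot`, `event_type`
#'   (`heel_strike`/`toe_off`), `sample_index` (1-based, first sample of the
#'   new phase) and `time` (seconds, `(sample_index - 1) / sampling_rate`),
#'   sorted by time.
#' @export
detect_events <- function(contact, sampling_rate, min_phase_duration = 0.05) {
  min_samples <- max(1L, round(min_phase_duration * sampling_rate))
  out <- lapply(c("left", "right"), function(foot) {
    x <- .debounce(contact[, foot], min_samples)
    if (length(x) < 2L) {
      return(data.frame(foot = character(), event_type = character(),
                        sample_index = integer(), time = numeric()))
    }
    d <- diff(x)
    hs <- which(d == 1L) + 1L   # first sample in contact
    to <- which(d == -1L) + 1L  # first sample out of contact
    data.frame(
      foot = rep(foot, length(hs) + length(to)),
      event_type = rep(c("heel_strike", "toe_off"), c(length(hs), length(to))),
      sample_index = c(hs, to),
      time = (c(hs, to) - 1) / sampling_rate
    )
  })
  out <- do.call(rbind, out)
  out[order(out$time, out$foot), , drop = FALSE] |>
    (\(d) {rownames(d) <- NULL; d})()
}

.events_of <- function(events, foot, type) {
  sort(events$sample_index[events$foot == foot & events$event_type == type])
}

# Paired (start, end) index intervals from alternating event streams:
# for each `a` event, the first `b` event strictly after it, dropping
# incomplete trailing cycles.
.pair_intervals <- function(a, b) {
  if (!length(a) || !length(b)) return(cbind(start = integer(), end = integer()))
  starts <- integer(); ends <- integer()
  for (s in a) {
    nxt <- b[b > s]
    if (length(nxt)) {
      starts <- c(starts, s); ends <- c(ends, nxt[1])
    }
  }
  cbind(start = starts, end = ends)
}

# Maximal runs where `mask` is TRUE, excluding runs touching the recording
# boundary (those are incomplete phases).
.mask_intervals <- function(mask) {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & starts > 1L & ends < length(mask)
  cbind(start = starts[keep], end = ends[keep] + 1L)
}

#' Cut a recording into gait-cycle segments
#'
#' Seven schemes are supported, anchored on the `anchor` foot (right by
#' default):
#' * `stride`: one heel strike of the anchor foot to the next;
#' * `step`: any heel strike to the next heel strike of the other foot;
#' * `stance`: anchor heel strike to the next anchor toe-off;
#' * `swing`: anchor toe-off to the next anchor heel strike;
#' * `left_single_limb_support` / `right_single_limb_support`: maximal
#'   intervals where only that foot is in contact;
#' * `double_limb_support`: maximal intervals where both feet are in contact.
#'
#' Intervals are `[start_index, end_index)` in samples (1-based); incomplete
#' leading/trailing cycles are dropped, as are segments shorter than
#' `min_segment_samples` (statistics such as correlation need several points).
#'
#' @param recording A `"gait_recording"`.
#' @param scheme One of `stride`, `step`, `stance`, `swing`,
#'   `left_single_limb_support`, `right_single_limb_support`,
#'   `double_limb_support`.
#' @param threshold Contact threshold, see [detect_contact()].
#' @param min_phase_duration Debounce window in seconds.
#' @param anchor Reference foot for stride/stance/swing.
#' @param min_segment_samples Minimum segment length in samples (default 4).
#' @return data.frame with columns `recording_id`, `scheme`, `reference_foot`,
#'   `start_index`, `end_index`, `gait_class`, `participant_id`. Zero rows
#'   (with a warning) if fewer than two usable events were found.
#' @export
segment_recording <- function(recording, scheme = "stride", threshold = 40,
                              min_phase_duration = 0.05, anchor = "right",
                              min_segment_samples = 4L) {
  scheme <- match.arg(scheme, SEGMENT_SCHEMES)
  anchor <- match.arg(anchor, c("right", "left"))
  other <- if (anchor == "right") "left" else "right"
  contact <- detect_contact(recording, threshold)
  events <- detect_events(contact, recording$sampling_rate, min_phase_duration)

  ref <- anchor
  if (scheme %in% c("stride", "stance", "swing")) {
    hs <- .events_of(events, anchor, "heel_strike")
    to <- .events_of(events, anchor, "toe_off")
    iv <- switch(scheme,
      stride = if (length(hs) >= 2L) cbind(start = hs[-length(hs)], end = hs[-1L])
               else cbind(start = integer(), end = integer()),
      stance = .pair_intervals(hs, to),
      swing = .pair_intervals(to, hs)
    )
  } else if (scheme == "step") {
    ref <- "both"
    hs_a <- .events_of(events, anchor, "heel_strike")
    hs_o <- .events_of(events, other, "heel_strike")
    iv <- rbind(.pair_intervals(hs_a, hs_o), .pair_intervals(hs_o, hs_a))
    iv <- iv[order(iv[, "start"]), , drop = FALSE]
  } else {
    n <- nrow(recording$samples)
    # rebuild the debounced contact the events were cut from
    ms <- max(1L, round(min_phase_duration * recording$sampling_rate))
    left <- .debounce(contact[, "left"], ms)
    right <- .debounce(contact[, "right"], ms)
    mask <- switch(scheme,
      left_single_limb_support = {ref <- "left"; left & !right},
      right_single_limb_support = {ref <- "right"; right & !left},
      double_limb_support = {ref <- "both"; left & right}
    )
    iv <- .mask_intervals(mask)
  }

  if (nrow(iv) < 1L) {
    warning("fewer than 2 usable gait events under scheme '", scheme,
            "'; returning no segments")
  }
  iv <- iv[iv[, "end"] - iv[, "start"] >= min_segment_samples, , drop = FALSE]
  if (nrow(iv) == 0L) {
    return(data.frame(recording_id = character(), scheme = character(),
                      reference_foot = character(), start_index = integer(),
                      end_index = integer(), gait_class = character(),
                      participant_id = integer(), stringsAsFactors = FALSE))
  }
  data.frame(
    recording_id = sprintf("p%02d_%s", recording$participant_id,
                           recording$gait_class),
    scheme = scheme,
    reference_foot = ref,
    start_index = as.integer(iv[, "start"]),
    end_index = as.integer(iv[, "end"]),
    gait_class = recording$gait_class,
    participant_id = recording$participant_id,
    stringsAsFactors = FALSE
  )
}

#' @rdname segment_recording
#' @param recordings List of recordings (e.g. from [simulate_cohort()]).
#' @param ... Passed on to [segment_recording()].
#' @return `segment_cohort()`: row-bound segment table over all recordings.
#' @export
segment_cohort <- function(recordings, scheme = "stride", ...) {
  do.call(rbind, lapply(recordings, segment_recording, scheme = scheme, ...))
}
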