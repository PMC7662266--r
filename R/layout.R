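#' Smart-shoe sensor layout
#'
#' The canonical 20-channel layout of an instrumented pair of shoes: per shoe
#' four plantar pressure sensors (heel, lateral midfoot, medial forefoot, toe),
#' a three-axis accelerometer and a three-axis gyroscope. Channel order is
#' fixed (left shoe first) so that recordings, CSV files and feature tables are
#' byte-comparable across runs.
#'
#' @return A data.frame with one row per channel and columns `channel`
#'   (unique channel name, `<foot>_<sensor location/axis>`), `foot`
#'   (`"left"`/`"right"`) and `sensor` (`"pressure"`, `"accelerometer"` or
#'   `"gyroscope"`), in canonical order.
#' @examples
#' layout <- sensor_layout()
#' table(layout$sensor)  # 8 pressure, 6 accelerometer, 6 gyroscope
#' @export
sensor_layout <- function() {
  per_foot <- c(
    "pressure_heel", "pressure_lateral_midfoot",
    "pressure_medial_forefoot", "pressure_toe",
    "acc_x", "acc_y", "acc_z",
    "gyro_x", "gyro_y", "gyro_z"
  )
  sensor <- c(rep("pressure", 4), rep("accelerometer", 3), rep("gyroscope", 3))
  data.frame(
    channel = c(paste0("left_", per_foot), paste0("right_", per_foot)),
    foot = rep(c("left", "right"), each = 10L),
    sensor = rep(sensor, 2L),
    stringsAsFactors = FALSE
  )
}

#' @rdname sensor_layout
#' @param layout A layout as returned by [sensor_layout()].
#' @param sensors Character vector, subset of
#'   `c("pressure", "accelerometer", "gyroscope")`.
#' @return `layout_channels()`: the channel names of the requested sensor
#'   types, in layout order.
#' @export
layout_channels <- function(layout = sensor_layout(),
                            sensors = c("pressure", "accelerometer", "gyroscope")) {
  sensors <- match.arg(sensors, several.ok = TRUE)
  layout$channel[layout$sensor %in% sensors]
}

#' The five gait classes
#'
#' Class labels in canonical order: normal gait first, then unstable left,
#' unstable right, supination (toe-out) and pronation (toe-in). Confusion
#' matrices and reports use this order throughout.
#'
#' @return Character vector of length 5.
#' @export
gait_classes <- function() {
  c("normal", "unstable_left", "unstable_right", "supination", "pronation")
}
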