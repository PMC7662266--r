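# Information-gain feature ranking and the fixed retention rule.

#' Information gain of a feature for the gait-class label
#'
#' The feature is discretized into `n_bins` equal-width bins over its own
#' range and the gain is `H(label) - H(label | bin)` in bits (log base 2).
#' A constant feature, or a single-class label, gives 0.
#'
#' @param values Numeric feature values.
#' @param labels Class labels, same length.
#' @param n_bins Number of equal-width bins (default 10).
#' @return Information gain in bits, in `[0, H(label)]`.
#' @export
information_gain <- function(values, labels, n_bins = 10) {
  stopifnot(length(values) == length(labels), length(values) >= 2)
  labels <- as.factor(labels)
  h <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  H_label <- h(table(labels) / length(labels))
  if (H_label == 0) return(0)
  r <- range(values)
  if (r[1] == r[2]) return(0)
  bins <- pmin(pmax(findInterval(values, seq(r[1], r[2], length.out = n_bins + 1),
                                 rightmost.closed = TRUE), 1L), n_bins)
  H_cond <- 0
  for (b in unique(bins)) {
    sel <- bins == b
    p_b <- mean(sel)
    H_cond <- H_cond + p_b * h(table(labels[sel]) / sum(sel))
  }
  max(H_label - H_cond, 0)
}

#' Rank feature columns by information gain
#'
#' @param table Feature table from [build_feature_table()] (must have a
#'   `gait_class` column).
#' @param n_bins Bins for [information_gain()].
#' @return data.frame `feature`, `ig_bits`, sorted by descending gain (ties
#'   broken by feature name) — the input for a ranking plot or for
#'   [discard_bottom_k()].
#' @export
rank_features <- function(table, n_bins = 10) {
  stopifnot("gait_class" %in% colnames(table))
  feats <- feature_columns(table)
  ig <- vapply(feats, function(f)
    information_gain(table[[f]], table$gait_class, n_bins), numeric(1))
  out <- data.frame(feature = feats, ig_bits = unname(ig),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$ig_bits, out$feature), ]
  rownames(out) <- NULL
  out
}

#' Fixed feature-retention rule
#'
#' Drops the 52 low-information feature families from a full 224-column
#' table: power on the 12 accelerometer and gyroscope channels, and all 40
#' zero-crossing and maximum columns, leaving 172. The rule is a fixed
#' family rule — it does not look at the data — and is idempotent.
#'
#' @param table Feature table built with the full battery.
#' @return The table with the discarded columns removed.
#' @export
apply_discard_rule <- function(table) {
  layout <- sensor_layout()
  imu <- layout$channel[layout$sensor != "pressure"]
  drop <- c(paste0(imu, "_power"),
            paste0(layout$channel, "_zerocrossing"),
            paste0(layout$channel, "_maxvalue"))
  present <- drop %in% colnames(table)
  already <- !any(present)
  if (!already && !all(present)) {
    stop("table is missing expected full-battery columns: ",
         paste(drop[!present], collapse = ", "))
  }
  table[, !colnames(table) %in% drop, drop = FALSE]
}

#' @rdname apply_discard_rule
#' @param k Number of lowest-ranked features to drop.
#' @param n_bins Bins for the underlying information-gain ranking.
#' @return `discard_bottom_k()`: the table with the `k` lowest-information
#'   features removed (data-driven alternative to the fixed rule).
#' @export
discard_bottom_k <- function(table, k, n_bins = 10) {
  ranking <- rank_features(table, n_bins)
  stopifnot(k >= 0, k <= nrow(ranking))
  drop <- utils::tail(ranking$feature, k)
  table[, !colnames(table) %in% drop, drop = FALSE]
}

#' Subset a feature table to a sensor combination
#'
#' @param table A feature table.
#' @param sensors Subset of `c("pressure", "accelerometer", "gyroscope")`.
#' @return The table restricted to feature columns derived from those sensor
#'   types (metadata columns kept).
#' @export
select_sensors <- function(table, sensors) {
  sensors <- match.arg(sensors,
                       c("pressure", "accelerometer", "gyroscope"),
                       several.ok = TRUE)
  sens <- feature_column_sensors()
  keep <- names(sens)[sens %in% sensors]
  cols <- c(intersect(colnames(table), keep),
            intersect(c("gait_class", "participant_id"), colnames(table)))
  table[, cols, drop = FALSE]
}
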