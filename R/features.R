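# Statistical feature battery.
#
# Ten per-channel statistics (mean, standard deviation, kurtosis, crest
# factor, skewness, entropy, spectral flux, power, zero-crossing count,
# maximum) over 20 channels, plus 24 within-shoe same-sensor Pearson
# correlations, give the canonical 224-column table. The retention rule drops
# power on the 12 inertial channels and all 40 zero-crossing/maximum columns,
# leaving 172.

PER_CHANNEL_FEATURES <- c("mean", "std", "kurtosis", "crest_factor",
                          "skewness", "entropy", "spectral_flux", "power",
                          "zerocrossing", "maxvalue")

#' Single feature values
#'
#' Computes one statistic of the battery on a numeric vector (two vectors for
#' `correlation`). Definitions (N = segment length, sample statistics with
#' N - 1 denominators):
#' * `mean`, `std`: ordinary sample mean / standard deviation;
#' * `correlation`: Pearson correlation;
#' * `kurtosis`: excess kurtosis, fourth central moment over `std^4`, minus 3;
#' * `crest_factor`: `max(x) / sqrt(sum(x^2) / (N - 1))`;
#' * `skewness`: third standardized moment;
#' * `entropy`: Shannon entropy (nats) of a 10-bin equal-width histogram of
#'   the segment's own range;
#' * `spectral_flux`: sum of squared successive differences (a time-domain
#'   total-variation-like statistic, one scalar per channel);
#' * `power`: mean of squares;
#' * `zerocrossing`: number of sign changes (zeros ignored);
#' * `maxvalue`: maximum.
#'
#' Degenerate segments (zero variance, or zero range for entropy) yield 0 for
#' correlation, kurtosis, skewness and entropy rather than NaN, so downstream
#' PCA never sees missing values. `crest_factor` falls back to 0 only when
#' the RMS itself is 0.
#'
#' The kurtosis and skewness defaults use the conventional standardized
#' moments. `literal = TRUE` switches both to a lower-exponent variant
#' (fourth moment over variance; second power of the standardized deviation)
#' occasionally seen in print; the conventional forms are the default because
#' the variants are not scale-invariant (kurtosis) or asymptotically constant
#' (skewness).
#'
#' @param name One of `correlation` or the ten per-channel statistics.
#' @param x,y Numeric vectors (`y` only for `correlation`).
#' @param n_bins Histogram bins for `entropy` (default 10).
#' @param literal Use the lower-exponent kurtosis/skewness variants.
#' @return A single numeric value.
#' @examples
#' feature_value("power", c(1, 2, 3))          # 14/3
#' feature_value("spectral_flux", c(0, 1, 0, 1)) # 3
#' @export
feature_value <- function(name, x, y = NULL, n_bins = 10, literal = FALSE) {
  name <- match.arg(name, c("correlation", PER_CHANNEL_FEATURES))
  stopifnot(all(is.finite(x)))
  n <- length(x)
  if (name %in% c("std", "correlation", "kurtosis", "skewness",
                  "crest_factor") && n < 2) {
    stop("feature '", name, "' needs at least 2 samples")
  }
  if (name == "correlation") {
    stopifnot(length(y) == n, all(is.finite(y)))
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
    return(stats::cor(x, y))
  }
  m <- mean(x)
  switch(name,
    mean = m,
    std = stats::sd(x),
    kurtosis = {
      s <- stats::sd(x)
      if (s == 0) 0
      else if (literal) mean((x - m)^4) / s^2 - 3
      else mean((x - m)^4) / s^4 - 3
    },
    crest_factor = {
      rms <- sqrt(sum(x^2) / (n - 1))
      if (rms == 0) 0 else max(x) / rms
    },
    skewness = {
      s <- stats::sd(x)
      if (s == 0) 0
      else if (literal) mean(((x - m) / s)^2)
      else mean(((x - m) / s)^3)
    },
    entropy = .entropy(x, n_bins),
    spectral_flux = sum(diff(x)^2),
    power = mean(x^2),
    zerocrossing = {
      s <- sign(x)
      s <- s[s != 0]
      if (length(s) < 2) 0 else sum(diff(s) != 0)
    },
    maxvalue = max(x)
  )
}

.entropy <- function(x, n_bins = 10) {
  r <- range(x)
  if (r[1] == r[2]) return(0)
  counts <- tabulate(
    pmin(pmax(findInterval(x, seq(r[1], r[2], length.out = n_bins + 1),
                           rightmost.closed = TRUE), 1L), n_bins),
    nbins = n_bins
  )
  p <- counts[counts > 0] / length(x)
  -sum(p * log(p))
}

#' Within-shoe correlation channel pairs
#'
#' All unordered pairs of same-sensor channels within one shoe: C(4,2) = 6
#' pressure pairs per shoe (12 over both), C(3,2) = 3 per inertial sensor per
#' shoe (6 each over both).
#'
#' @param layout A [sensor_layout()].
#' @param sensor_type `"pressure"`, `"accelerometer"` or `"gyroscope"`.
#' @return data.frame with columns `foot`, `chan_a`, `chan_b` (full channel
#'   names) in canonical order.
#' @export
correlation_pairs <- function(layout = sensor_layout(),
                              sensor_type = c("pressure", "accelerometer",
                                              "gyroscope")) {
  sensor_type <- match.arg(sensor_type)
  out <- lapply(c("left", "right"), function(foot) {
    ch <- layout$channel[layout$sensor == sensor_type & layout$foot == foot]
    if (length(ch) < 2) {
      return(data.frame(foot = character(), chan_a = character(),
                        chan_b = character()))
    }
    idx <- utils::combn(length(ch), 2)
    data.frame(foot = foot, chan_a = ch[idx[1, ]], chan_b = ch[idx[2, ]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Canonical feature column names: 24 correlations first (pressure, then
# accelerometer, then gyroscope pairs), then the 10 per-channel statistics in
# layout channel order.
.strip_foot <- function(channel) sub("^(left|right)_", "", channel)

feature_column_names <- function(layout = sensor_layout()) {
  corr <- unlist(lapply(c("pressure", "accelerometer", "gyroscope"),
    function(st) {
      p <- correlation_pairs(layout, st)
      paste0(p$foot, "_", .strip_foot(p$chan_a), "x", .strip_foot(p$chan_b),
             "_correlation")
    }))
  per <- as.vector(t(outer(layout$channel, PER_CHANNEL_FEATURES, paste,
                           sep = "_")))
  c(corr, per)
}

# Sensor type of each feature column (used for sensor-combination
# subsetting). Built constructively in the same order as
# feature_column_names(), since correlation names are not unambiguously
# parseable (the pair separator collides with axis names ending in "x").
feature_column_sensors <- function(layout = sensor_layout()) {
  corr_sens <- unlist(lapply(c("pressure", "accelerometer", "gyroscope"),
    function(st) rep(st, nrow(correlation_pairs(layout, st)))))
  per_sens <- rep(layout$sensor, each = length(PER_CHANNEL_FEATURES))
  stats::setNames(c(corr_sens, per_sens), feature_column_names(layout))
}

#' Names of the feature columns of a feature table
#'
#' @param table A feature table from [build_feature_table()].
#' @return Character vector of feature column names (metadata columns
#'   `gait_class` and `participant_id` excluded).
#' @export
feature_columns <- function(table) {
  setdiff(colnames(table), c("gait_class", "participant_id"))
}

# Vectorized per-channel statistics for one segment: 10 x n_channels matrix.
.channel_features <- function(X, n_bins = 10, literal = FALSE) {
  n <- nrow(X)
  m <- colMeans(X)
  centered <- sweep(X, 2, m)
  s2 <- colSums(centered^2) / (n - 1)
  s <- sqrt(s2)
  ok <- s > 0
  kurt <- skew <- numeric(ncol(X))
  m4 <- colMeans(centered^4)
  if (literal) {
    kurt[ok] <- m4[ok] / s2[ok] - 3
    skew[ok] <- colMeans(sweep(centered, 2, s, "/")^2)[ok]
  } else {
    kurt[ok] <- m4[ok] / s2[ok]^2 - 3
    skew[ok] <- (colMeans(centered^3) / s^3)[ok]
  }
  rms <- sqrt(colSums(X^2) / (n - 1))
  crest <- ifelse(rms > 0, apply(X, 2, max) / rms, 0)
  ent <- apply(X, 2, .entropy, n_bins = n_bins)
  zc <- apply(X, 2, function(x) {
    sg <- sign(x); sg <- sg[sg != 0]
    if (length(sg) < 2) 0 else sum(diff(sg) != 0)
  })
  rbind(mean = m, std = s, kurtosis = kurt, crest_factor = crest,
        skewness = skew, entropy = ent,
        spectral_flux = colSums(diff(X)^2), power = colMeans(X^2),
        zerocrossing = zc, maxvalue = apply(X, 2, max))
}

#' Build the segments-by-features table
#'
#' Computes the full 224-column battery (or the 172-column retained set) for
#' every segment, reading samples from the matching recordings. Segments
#' shorter than `min_length` samples are skipped with a message giving the
#' count.
#'
#' @param segments Segment table from [segment_cohort()].
#' @param recordings List of the recordings the segments were cut from.
#' @param layout A [sensor_layout()].
#' @param include_discarded If `TRUE`, keep all 224 columns; if `FALSE`
#'   (default), apply the retention rule and return 172.
#' @param n_bins,literal Passed to the entropy / kurtosis / skewness
#'   definitions, see [feature_value()].
#' @param min_length Minimum segment length in samples (default 4).
#' @return data.frame: feature columns in canonical order, then `gait_class`
#'   and `participant_id`.
#' @export
build_feature_table <- function(segments, recordings,
                                layout = sensor_layout(),
                                include_discarded = FALSE,
                                n_bins = 10, literal = FALSE,
                                min_length = 4L) {
  rec_ids <- vapply(recordings, function(r)
    sprintf("p%02d_%s", r$participant_id, r$gait_class), character(1))
  names(recordings) <- rec_ids
  missing_ids <- setdiff(unique(segments$recording_id), rec_ids)
  if (length(missing_ids)) {
    stop("segments reference unloaded recordings: ",
         paste(missing_ids, collapse = ", "))
  }
  cols <- feature_column_names(layout)
  corr_cols <- cols[endsWith(cols, "_correlation")]
  pairs <- do.call(rbind, lapply(c("pressure", "accelerometer", "gyroscope"),
                                 correlation_pairs, layout = layout))

  too_short <- (segments$end_index - segments$start_index) < min_length
  if (any(too_short)) {
    message(sum(too_short), " segment(s) shorter than ", min_length,
            " samples skipped")
    segments <- segments[!too_short, , drop = FALSE]
  }
  M <- matrix(NA_real_, nrow = nrow(segments), ncol = length(cols),
              dimnames = list(NULL, cols))
  for (i in seq_len(nrow(segments))) {
    rec <- recordings[[segments$recording_id[i]]]
    X <- rec$samples[segments$start_index[i]:(segments$end_index[i] - 1L),
                     layout$channel, drop = FALSE]
    cf <- .channel_features(X, n_bins = n_bins, literal = literal)
    M[i, (length(corr_cols) + 1L):length(cols)] <- as.vector(cf)
    sda <- cf["std", pairs$chan_a]
    sdb <- cf["std", pairs$chan_b]
    co <- numeric(nrow(pairs))
    ok <- sda > 0 & sdb > 0
    if (any(ok)) {
      co[ok] <- mapply(function(a, b) stats::cor(X[, a], X[, b]),
                       pairs$chan_a[ok], pairs$chan_b[ok])
    }
    M[i, corr_cols] <- co
  }
  out <- as.data.frame(M)
  out$gait_class <- segments$gait_class
  out$participant_id <- segments$participant_id
  if (!include_discarded) out <- apply_discard_rule(out)
  out
}
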