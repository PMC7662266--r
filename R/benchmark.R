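# Benchmark drivers: sensor-combination ablation, principal-component sweep,
# segmentation-scheme sweep, paired one-tailed t-tests and CSV report
# rendering.

#' The seven sensor combinations
#'
#' Every nonempty subset of {pressure, accelerometer, gyroscope}, with the
#' number of retained features each contributes: pressure 76, accelerometer
#' 48, gyroscope 48 (so e.g. accelerometer+gyroscope has 96 and all three
#' 172). The pairwise counts follow from the per-sensor retained counts,
#' which are 12 correlations + 8 channels x 8 retained statistics for
#' pressure and 6 + 6 x 7 for each inertial sensor.
#'
#' @return Named list (names `P`, `A`, `G`, `PA`, `PG`, `AG`, `PAG`) of
#'   character vectors of sensor types.
#' @export
sensor_combos <- function() {
  list(
    P = "pressure", A = "accelerometer", G = "gyroscope",
    PA = c("pressure", "accelerometer"),
    PG = c("pressure", "gyroscope"),
    AG = c("accelerometer", "gyroscope"),
    PAG = c("pressure", "accelerometer", "gyroscope")
  )
}

#' Sensor-combination ablation benchmark
#'
#' Evaluates every sensor combination with every requested classifier under
#' leave-one-participant-out cross-validation, the component count chosen per
#' training fold by the cumulative explained-variance threshold.
#'
#' @param table Retained (172-column) feature table for the full sensor set.
#' @param algorithms Character vector of classifier algorithms.
#' @param variance Explained-variance threshold.
#' @param seed Seed passed to every [classifier_spec()].
#' @param combos Subset of `names(sensor_combos())` to run (default all 7).
#' @return List of class `"gait_benchmark"`: `grid` (one row per combo x
#'   classifier with mean/sd accuracy, precision, recall and mean component
#'   count) and `reports` (nested per-combo, per-algorithm
#'   `"gait_metrics_report"` objects, so every grid cell can be recomputed
#'   from stored confusion matrices).
#' @export
run_sensor_ablation <- function(table,
                                algorithms = c("random_forest", "knn",
                                               "logistic_regression", "svm"),
                                variance = 0.99, seed = 1L,
                                combos = names(sensor_combos())) {
  all_combos <- sensor_combos()
  stopifnot(all(combos %in% names(all_combos)))
  reports <- list()
  rows <- list()
  for (cname in combos) {
    sub <- select_sensors(table, all_combos[[cname]])
    for (alg in algorithms) {
      rep <- run_loso(sub, classifier_spec(alg, seed = seed),
                      variance = variance)
      reports[[cname]][[alg]] <- rep
      rows[[length(rows) + 1L]] <- data.frame(
        combo = cname, algorithm = alg,
        n_features = length(feature_columns(sub)),
        mean_n_pcs = mean(rep$per_fold$n_pcs),
        accuracy_mean = rep$mean[["accuracy"]],
        accuracy_sd = rep$sd[["accuracy"]],
        precision_mean = rep$mean[["precision"]],
        precision_sd = rep$sd[["precision"]],
        recall_mean = rep$mean[["recall"]],
        recall_sd = rep$sd[["recall"]]
      )
    }
  }
  structure(list(grid = do.call(rbind, rows), reports = reports,
                 variance = variance, seed = seed),
            class = "gait_benchmark")
}

#' Segmentation-scheme sweep
#'
#' Evaluates one sensor combination and classifier under each of the seven
#' gait-cycle schemes, reported in decreasing-segment-length order (stride
#' first, double limb support last). A scheme yielding no usable segments is
#' reported as missing rather than failing the sweep.
#'
#' @param recordings Cohort recordings.
#' @param sensors Sensor types to keep (default accelerometer + gyroscope).
#' @param algorithm Classifier algorithm.
#' @param variance,seed As in [run_sensor_ablation()].
#' @param schemes Schemes to run, in report order.
#' @return List: `summary` data.frame (scheme, n_segments, accuracy mean/sd)
#'   and `reports` per scheme.
#' @export
run_segmentation_sweep <- function(recordings,
                                   sensors = c("accelerometer", "gyroscope"),
                                   algorithm = "svm", variance = 0.99,
                                   seed = 1L, schemes = SEGMENT_SCHEMES) {
  spec <- classifier_spec(algorithm, seed = seed)
  reports <- list()
  rows <- list()
  for (scheme in schemes) {
    segs <- suppressWarnings(segment_cohort(recordings, scheme = scheme))
    if (is.null(segs) || nrow(segs) == 0) {
      rows[[scheme]] <- data.frame(scheme = scheme, n_segments = 0L,
                                   accuracy_mean = NA_real_,
                                   accuracy_sd = NA_real_)
      next
    }
    tab <- select_sensors(build_feature_table(segs, recordings), sensors)
    rep <- run_loso(tab, spec, variance = variance)
    reports[[scheme]] <- rep
    rows[[scheme]] <- data.frame(scheme = scheme, n_segments = nrow(segs),
                                 accuracy_mean = rep$mean[["accuracy"]],
                                 accuracy_sd = rep$sd[["accuracy"]])
  }
  list(summary = do.call(rbind, rows[schemes]), reports = reports)
}

#' Principal-component-count sweep
#'
#' Re-runs the leave-one-participant-out evaluation with the component count
#' fixed at each grid value (overriding the variance threshold), as in a
#' "performance versus number of PCs" table.
#'
#' @param table Feature table (already subset to the sensor combination of
#'   interest).
#' @param algorithm Classifier algorithm.
#' @param pc_grid Integer vector of component counts.
#' @param seed Classifier seed.
#' @return data.frame: `n_pcs`, mean/sd accuracy, precision, recall.
#' @export
run_pc_sweep <- function(table, algorithm = "svm", pc_grid, seed = 1L) {
  d <- length(feature_columns(table))
  if (any(pc_grid > d)) {
    stop("pc_grid exceeds the ", d, " available features")
  }
  spec <- classifier_spec(algorithm, seed = seed)
  do.call(rbind, lapply(pc_grid, function(k) {
    rep <- run_loso(table, spec, n_pcs = k)
    data.frame(n_pcs = k,
               accuracy_mean = rep$mean[["accuracy"]],
               accuracy_sd = rep$sd[["accuracy"]],
               precision_mean = rep$mean[["precision"]],
               precision_sd = rep$sd[["precision"]],
               recall_mean = rep$mean[["recall"]],
               recall_sd = rep$sd[["recall"]])
  }))
}

#' Paired one-tailed t-test on per-fold scores
#'
#' Classical paired t-test on fold-wise (per-participant) differences with a
#' one-tailed alternative. Zero-variance differences are handled explicitly:
#' all-equal scores give p = 0.5 (the symmetric null), a constant nonzero
#' difference gives p = 0 or 1 in the stated direction with a `degenerate`
#' flag.
#'
#' @param a,b Paired score vectors (same participants, same order).
#' @param alternative `"greater"` tests mean(a - b) > 0.
#' @return List: `t`, `df`, `p`, `significance` (`**` p < 0.01, `*` p < 0.05)
#'   and `degenerate`.
#' @export
paired_t_test <- function(a, b, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  # mirror t.test's "essentially constant" guard instead of an exact-zero test
  if (stats::sd(d) <= 1e-10 * max(abs(mean(d)), 1)) {
    if (abs(mean(d)) <= 1e-10) {
      res <- list(t = 0, df = length(d) - 1, p = 0.5, degenerate = TRUE)
    } else {
      up <- (mean(d) > 0) == (alternative == "greater")
      res <- list(t = sign(mean(d)) * Inf, df = length(d) - 1,
                  p = if (up) 0 else 1, degenerate = TRUE)
    }
  } else {
    tt <- stats::t.test(a, b, paired = TRUE, alternative = alternative)
    res <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value, degenerate = FALSE)
  }
  res$significance <- if (res$p < 0.01) "**" else if (res$p < 0.05) "*" else ""
  res
}

#' Pairwise t-test table across benchmark cells
#'
#' Compares one reference cell of a [run_sensor_ablation()] result against
#' the others, pairing per-fold metric values by participant — e.g. SVM
#' against the other classifiers on one combo, or the accelerometer+gyroscope
#' combo against the single sensors under SVM.
#'
#' @param benchmark A `"gait_benchmark"`.
#' @param combo,algorithm Reference cell.
#' @param against `"algorithms"` compares the reference algorithm with the
#'   other algorithms on the same combo; `"combos"` compares the reference
#'   combo with the other combos under the same algorithm.
#' @param alternative Direction, passed to [paired_t_test()] (default: the
#'   reference cell is greater).
#' @return data.frame with one row per comparison and one-tailed p per
#'   metric, with significance markers.
#' @export
ttest_table <- function(benchmark, combo = "AG", algorithm = "svm",
                        against = c("algorithms", "combos"),
                        alternative = "greater") {
  against <- match.arg(against)
  ref <- benchmark$reports[[combo]][[algorithm]]$per_fold
  others <- if (against == "algorithms") {
    alg <- setdiff(names(benchmark$reports[[combo]]), algorithm)
    stats::setNames(lapply(alg, function(a)
      benchmark$reports[[combo]][[a]]$per_fold), alg)
  } else {
    cmb <- setdiff(names(benchmark$reports), combo)
    stats::setNames(lapply(cmb, function(cm)
      benchmark$reports[[cm]][[algorithm]]$per_fold), cmb)
  }
  do.call(rbind, lapply(names(others), function(nm) {
    o <- others[[nm]]
    stopifnot(identical(ref$participant, o$participant))
    row <- data.frame(comparison = nm)
    for (m in c("accuracy", "precision", "recall")) {
      tt <- paired_t_test(ref[[m]], o[[m]], alternative)
      row[[paste0(m, "_p")]] <- tt$p
      row[[paste0(m, "_sig")]] <- tt$significance
    }
    row
  }))
}

#' Render benchmark results to CSV report files
#'
#' Writes, under `dir`: `ablation_summary.csv` (the grid), `per_fold.csv`
#' (every fold of every cell), `confusion_matrices.csv` (stored matrices in
#' long form with per-column error-rate rows appended, in the printed
#' convention of [column_error_rates()]), `ttests_vs_<algorithm>.csv` and
#' `explained_variance_<combo>.csv` (global standardize-plus-PCA curve per
#' combo, for an explained-variance figure).
#'
#' @param benchmark A `"gait_benchmark"` from [run_sensor_ablation()].
#' @param dir Output directory.
#' @param table The feature table the benchmark was run on (for the
#'   explained-variance curves); omit to skip those files.
#' @param baseline_algorithm Reference algorithm for the t-test table.
#' @return Invisibly, the paths written.
#' @export
render_report <- function(benchmark, dir, table = NULL,
                          baseline_algorithm = "svm") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  w <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  w(benchmark$grid, "ablation_summary.csv")

  per_fold <- do.call(rbind, lapply(names(benchmark$reports), function(cm) {
    do.call(rbind, lapply(names(benchmark$reports[[cm]]), function(alg) {
      pf <- benchmark$reports[[cm]][[alg]]$per_fold
      cbind(combo = cm, algorithm = alg, pf)
    }))
  }))
  w(per_fold, "per_fold.csv")

  conf <- do.call(rbind, lapply(names(benchmark$reports), function(cm) {
    do.call(rbind, lapply(names(benchmark$reports[[cm]]), function(alg) {
      rep <- benchmark$reports[[cm]][[alg]]
      do.call(rbind, lapply(seq_along(rep$confusions), function(i) {
        m <- rep$confusions[[i]]
        err <- column_error_rates(m)
        block <- as.data.frame(rbind(m, round(err$per_class, 1)))
        cbind(combo = cm, algorithm = alg,
              participant = rep$per_fold$participant[i],
              row = c(rownames(m), "error_rate_pct"), block)
      }))
    }))
  }))
  rownames(conf) <- NULL
  w(conf, "confusion_matrices.csv")

  if (length(benchmark$reports[[1]]) > 1 &&
      baseline_algorithm %in% names(benchmark$reports[[1]])) {
    tt <- do.call(rbind, lapply(names(benchmark$reports), function(cm) {
      cbind(combo = cm,
            ttest_table(benchmark, combo = cm,
                        algorithm = baseline_algorithm,
                        against = "algorithms"))
    }))
    w(tt, paste0("ttests_vs_", baseline_algorithm, ".csv"))
  }

  if (!is.null(table)) {
    for (cm in names(benchmark$reports)) {
      sub <- select_sensors(table, sensor_combos()[[cm]])
      X <- as.matrix(sub[, feature_columns(sub), drop = FALSE])
      std <- suppressWarnings(fit_standardizer(X))
      pca <- fit_pca(apply_standardizer(std, X))
      w(explained_variance_table(pca),
        paste0("explained_variance_", cm, ".csv"))
    }
  }
  invisible(paths)
}
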