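# Benchmark drivers, paired t-tests and report rendering.

smoke_benchmark <- function() .memo("smoke_benchmark", function() {
  run_sensor_ablation(tiny_table(), algorithms = c("svm", "knn"),
                      combos = c("A", "G", "AG"), seed = 1)
})

test_that("paired t-test matches the closed-form t distribution", {
  set.seed(41)
  for (i in 1:10) {
    n <- sample(5:20, 1)
    a <- rnorm(n, 0.8, 0.1)
    b <- rnorm(n, 0.75, 0.1)
    tt <- paired_t_test(a, b, "greater")
    d <- a - b
    t_oracle <- mean(d) / (sd(d) / sqrt(n))
    expect_equal(tt$t, t_oracle, tolerance = 1e-10)
    expect_equal(tt$p, 1 - pt(t_oracle, n - 1), tolerance = 1e-10)
    # swapping the arguments flips the one-tailed p
    expect_equal(paired_t_test(b, a, "greater")$p, 1 - tt$p,
                 tolerance = 1e-10)
  }
})

test_that("paired t-test handles degenerate differences explicitly", {
  a <- c(0.8, 0.7, 0.9, 0.6)
  same <- paired_t_test(a, a, "greater")
  expect_equal(same$t, 0)
  expect_equal(same$p, 0.5)
  up <- paired_t_test(a + 1, a, "greater")
  expect_true(up$degenerate)
  expect_lt(up$p, 0.01)
  expect_equal(up$significance, "**")
  down <- paired_t_test(a - 1, a, "greater")
  expect_equal(down$p, 1)
})

test_that("sensor combos carry the retained-feature count arithmetic", {
  counts <- c(P = 76, A = 48, G = 48, PA = 124, PG = 124, AG = 96, PAG = 172)
  per_sensor <- c(pressure = 76, accelerometer = 48, gyroscope = 48)
  combos <- sensor_combos()
  expect_length(combos, 7)
  for (nm in names(combos)) {
    expect_equal(unname(sum(per_sensor[combos[[nm]]])), unname(counts[nm]),
                 info = nm)
  }
})

test_that("the ablation grid covers every cell and is auditable", {
  bench <- smoke_benchmark()
  expect_equal(nrow(bench$grid), 3 * 2)
  expect_setequal(bench$grid$combo, c("A", "G", "AG"))
  # every reported mean is recomputable from the stored confusion matrices
  for (i in seq_len(nrow(bench$grid))) {
    row <- bench$grid[i, ]
    rep <- bench$reports[[row$combo]][[row$algorithm]]
    accs <- vapply(rep$confusions, function(cm)
      suppressWarnings(metrics(cm))$accuracy, numeric(1))
    expect_equal(mean(accs), row$accuracy_mean)
    expect_equal(sd(accs), row$accuracy_sd)
  }
  expect_equal(unique(bench$grid$n_features[bench$grid$combo == "AG"]), 96)
})

test_that("pc sweep runs the grid and rejects out-of-range counts", {
  tab <- select_sensors(tiny_table(), "gyroscope")
  sweep <- run_pc_sweep(tab, "knn", pc_grid = c(2, 5), seed = 1)
  expect_equal(sweep$n_pcs, c(2, 5))
  expect_true(all(sweep$accuracy_mean >= 0 & sweep$accuracy_mean <= 1))
  expect_error(run_pc_sweep(tab, "knn", pc_grid = 500), "exceeds")
})

test_that("fixed full-rank pc count equals the variance-1 rule", {
  tab <- select_sensors(tiny_table(), "pressure")
  full <- length(feature_columns(tab))
  a <- run_loso(tab, classifier_spec("knn", seed = 1), n_pcs = full)
  b <- run_loso(tab, classifier_spec("knn", seed = 1), variance = 1.0)
  expect_equal(b$per_fold$n_pcs, rep(full, 2))
  expect_identical(a$confusions, b$confusions)
})

test_that("segmentation sweep reports every scheme on a smoke cohort", {
  sweep <- .memo("seg_sweep", function() {
    run_segmentation_sweep(tiny_cohort(), algorithm = "knn", seed = 1)
  })
  expect_equal(sweep$summary$scheme, SEGMENT_SCHEMES)
  expect_true(all(sweep$summary$n_segments > 0))
  expect_true(all(is.finite(sweep$summary$accuracy_mean)))
})

test_that("t-test tables compare the reference cell against the rest", {
  bench <- smoke_benchmark()
  tt <- ttest_table(bench, combo = "AG", algorithm = "svm",
                    against = "algorithms")
  expect_equal(tt$comparison, "knn")
  expect_true(all(tt$accuracy_p >= 0 & tt$accuracy_p <= 1))
  tc <- ttest_table(bench, combo = "AG", algorithm = "svm",
                    against = "combos")
  expect_setequal(tc$comparison, c("A", "G"))
})

test_that("report rendering emits all sections and round-trips", {
  dir <- withr::local_tempdir()
  bench <- smoke_benchmark()
  paths <- render_report(bench, dir, table = tiny_table())
  names <- basename(paths)
  expect_true("ablation_summary.csv" %in% names)
  expect_true("per_fold.csv" %in% names)
  expect_true("confusion_matrices.csv" %in% names)
  expect_true("ttests_vs_svm.csv" %in% names)
  expect_true(all(paste0("explained_variance_", c("A", "G", "AG"), ".csv")
                  %in% names))

  # error-rate rows recompute exactly from the stored matrices
  conf <- read.csv(file.path(dir, "confusion_matrices.csv"))
  one <- conf[conf$combo == "AG" & conf$algorithm == "svm" &
                conf$participant == 1, ]
  m <- as.matrix(one[one$row != "error_rate_pct", gait_classes()])
  err_row <- unlist(one[one$row == "error_rate_pct", gait_classes()])
  expect_equal(unname(err_row),
               unname(round(column_error_rates(m)$per_class, 1)))

  # parse -> render is byte-identical
  summ <- read.csv(file.path(dir, "ablation_summary.csv"))
  path2 <- file.path(dir, "roundtrip.csv")
  write.csv(summ, path2, row.names = FALSE)
  write.csv(read.csv(path2), file.path(dir, "roundtrip2.csv"),
            row.names = FALSE)
  expect_identical(readLines(path2), readLines(file.path(dir, "roundtrip2.csv")))
})
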