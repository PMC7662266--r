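# Leave-one-participant-out evaluation of the four classifiers, weighted
# multiclass metrics, and the column-wise confusion-matrix error rates.

#' Classifier specification
#'
#' The four benchmarked algorithms with their standard hyperparameters:
#' * `svm` — C-classification with RBF kernel
#'   `k(x, x') = exp(-gamma * ||x - x'||^2)`, `C = 1`, `degree = 3`,
#'   `gamma = "scale"`, i.e. `1 / (d * Var(X))` with `Var(X)` the variance of
#'   the pooled training matrix;
#' * `random_forest` — 100 trees, Gini splits, minimum 15 samples to split,
#'   depth capped at 30, minimum leaf size 1;
#' * `knn` — k = 5 nearest neighbours, Euclidean distance, majority vote;
#' * `logistic_regression` — multinomial extension of the logistic model
#'   `phi(x) = 1 / (1 + exp(-f(x)))` with linear `f`.
#'
#' The classifiers are treated as pluggable fit/predict black boxes
#' (e1071, ranger, class and nnet respectively); this package owns the
#' evaluation protocol around them.
#'
#' @param algorithm One of `"svm"`, `"random_forest"`, `"knn"`,
#'   `"logistic_regression"`.
#' @param seed RNG seed used for every stochastic fit.
#' @param ... Hyperparameter overrides (checked against the defaults above).
#' @return List of class `"classifier_spec"`.
#' @export
classifier_spec <- function(algorithm = c("svm", "random_forest", "knn",
                                          "logistic_regression"),
                            seed = 1L, ...) {
  algorithm <- match.arg(algorithm)
  defaults <- switch(algorithm,
    svm = list(C = 1, kernel = "radial", gamma = "scale", degree = 3),
    random_forest = list(trees = 100, splitrule = "gini", min_split = 15,
                         max_depth = 30, min_leaf = 1),
    knn = list(k = 5),
    logistic_regression = list(maxit = 200)
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad)) {
    stop("unknown hyperparameter(s) for ", algorithm, ": ",
         paste(bad, collapse = ", "))
  }
  defaults[names(overrides)] <- overrides
  structure(c(list(algorithm = algorithm, seed = as.integer(seed)), defaults),
            class = "classifier_spec")
}

.fit_predict <- function(spec, X_train, y_train, X_test) {
  y_train <- factor(y_train)
  if (nlevels(droplevels(y_train)) < nlevels(y_train)) {
    warning("class(es) absent from training fold: ",
            paste(setdiff(levels(y_train), levels(droplevels(y_train))),
                  collapse = ", "))
    y_train <- droplevels(y_train)
  }
  set.seed(spec$seed)
  pred <- switch(spec$algorithm,
    svm = {
      gamma <- if (identical(spec$gamma, "scale")) {
        v <- mean((X_train - mean(X_train))^2)
        1 / (ncol(X_train) * max(v, .Machine$double.eps))
      } else spec$gamma
      fit <- e1071::svm(X_train, y_train, type = "C-classification",
                        kernel = spec$kernel, cost = spec$C, gamma = gamma,
                        degree = spec$degree, scale = FALSE)
      stats::predict(fit, X_test)
    },
    random_forest = {
      fit <- ranger::ranger(
        x = X_train, y = y_train, num.trees = spec$trees,
        splitrule = spec$splitrule, min.node.size = spec$min_split,
        max.depth = spec$max_depth, min.bucket = spec$min_leaf,
        seed = spec$seed, num.threads = 1
      )
      stats::predict(fit, data = X_test, num.threads = 1)$predictions
    },
    knn = class::knn(X_train, X_test, y_train, k = spec$k),
    logistic_regression = {
      df <- data.frame(X_train)
      df$.y <- y_train
      fit <- nnet::multinom(.y ~ ., data = df, trace = FALSE,
                            maxit = spec$maxit,
                            MaxNWts = (ncol(X_train) + 1) * nlevels(y_train) + 5)
      te <- data.frame(X_test)
      colnames(te) <- colnames(df)[seq_len(ncol(X_test))]
      stats::predict(fit, newdata = te)
    }
  )
  as.character(pred)
}

#' Leave-one-participant-out folds
#'
#' One fold per participant: that participant's rows form the test set, all
#' other rows the training set. The folds partition the table exactly.
#'
#' @param table Feature table with a `participant_id` column.
#' @return List of folds, each `list(participant, train, test)` with row
#'   indices.
#' @export
loso_folds <- function(table) {
  ids <- sort(unique(table$participant_id))
  if (length(ids) < 2) stop("leave-one-participant-out needs >= 2 participants")
  lapply(ids, function(id) {
    test <- which(table$participant_id == id)
    list(participant = id, train = setdiff(seq_len(nrow(table)), test),
         test = test)
  })
}

#' Five-class confusion matrix
#'
#' Rows are true classes, columns predicted classes, both in [gait_classes()]
#' order.
#'
#' @param true,predicted Class label vectors.
#' @param classes Class order (defaults to [gait_classes()]).
#' @return Integer matrix of counts.
#' @export
confusion_matrix <- function(true, predicted, classes = gait_classes()) {
  as.matrix(table(factor(true, levels = classes),
                  factor(predicted, levels = classes)))
}

#' Train on a fold and evaluate on its held-out participant
#'
#' Standardizer and PCA are fitted on the training rows only; the component
#' count follows the cumulative explained-variance threshold unless `n_pcs`
#' fixes it. The classifier is then fitted on the transformed training scores
#' and evaluated on the transformed test rows.
#'
#' @param table Feature table.
#' @param fold One fold from [loso_folds()].
#' @param spec A [classifier_spec()].
#' @param variance Cumulative explained-variance threshold (default 0.99).
#' @param n_pcs Optional fixed component count overriding the threshold.
#' @return List: `confusion` (matrix), `n_pcs` (components used),
#'   `participant`.
#' @export
train_eval_fold <- function(table, fold, spec, variance = 0.99,
                            n_pcs = NULL) {
  feats <- feature_columns(table)
  X <- as.matrix(table[, feats, drop = FALSE])
  std <- suppressWarnings(fit_standardizer(X[fold$train, , drop = FALSE]))
  Z_train <- apply_standardizer(std, X[fold$train, , drop = FALSE])
  Z_test <- apply_standardizer(std, X[fold$test, , drop = FALSE])
  pca <- fit_pca(Z_train)
  k <- if (is.null(n_pcs)) n_components_for_variance(pca, variance) else {
    if (n_pcs > ncol(pca$rotation)) {
      stop("n_pcs = ", n_pcs, " exceeds the ", ncol(pca$rotation),
           " available components")
    }
    n_pcs
  }
  S_train <- pca_transform(pca, Z_train, k)
  S_test <- pca_transform(pca, Z_test, k)
  pred <- .fit_predict(spec, S_train, table$gait_class[fold$train], S_test)
  list(confusion = confusion_matrix(table$gait_class[fold$test], pred),
       n_pcs = k, participant = fold$participant)
}

#' Weighted multiclass metrics
#'
#' Accuracy is the trace over the total; per-class precision is
#' `TP / (TP + FP)` (defined as 0, with a warning, for classes never
#' predicted) and recall `TP / (TP + FN)`; the reported precision and recall
#' are weighted averages with true-class supports as weights. With those
#' weights, weighted recall equals accuracy on a single confusion matrix.
#'
#' @param cm Confusion matrix from [confusion_matrix()].
#' @return List: `accuracy`, `precision`, `recall`, and per-class vectors
#'   `class_precision`, `class_recall`, `support`.
#' @export
metrics <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  tp <- diag(cm)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  prec <- ifelse(predicted > 0, tp / predicted, 0)
  if (any(predicted == 0 & support > 0)) {
    warning("class(es) never predicted; precision set to 0: ",
            paste(rownames(cm)[predicted == 0 & support > 0], collapse = ", "))
  }
  rec <- ifelse(support > 0, tp / support, 0)
  list(
    accuracy = sum(tp) / total,
    precision = sum(support * prec) / total,
    recall = sum(support * rec) / total,
    class_precision = prec,
    class_recall = rec,
    support = support
  )
}

#' Cross-fold metrics report
#'
#' @param folds List of fold results from [train_eval_fold()].
#' @return List of class `"gait_metrics_report"`: `per_fold` data.frame
#'   (participant, n_pcs, accuracy, precision, recall), `mean` and `sd`
#'   (sample SD across folds) for each metric, and `confusions` (the per-fold
#'   matrices, so every reported number can be recomputed).
#' @export
metrics_report <- function(folds) {
  per_fold <- do.call(rbind, lapply(folds, function(f) {
    m <- suppressWarnings(metrics(f$confusion))
    data.frame(participant = f$participant, n_pcs = f$n_pcs,
               accuracy = m$accuracy, precision = m$precision,
               recall = m$recall)
  }))
  cols <- c("accuracy", "precision", "recall")
  structure(list(
    per_fold = per_fold,
    mean = vapply(per_fold[cols], mean, numeric(1)),
    sd = vapply(per_fold[cols], stats::sd, numeric(1)),
    confusions = lapply(folds, `[[`, "confusion")
  ), class = "gait_metrics_report")
}

#' @export
print.gait_metrics_report <- function(x, ...) {
  cat("<gait_metrics_report>", nrow(x$per_fold), "folds\n")
  for (m in names(x$mean)) {
    cat(sprintf("  %-9s %.2f%% +/- %.2f\n", m, 100 * x$mean[[m]],
                100 * x$sd[[m]]))
  }
  invisible(x)
}

#' Run a full leave-one-participant-out evaluation
#'
#' @inheritParams train_eval_fold
#' @return A `"gait_metrics_report"`.
#' @export
run_loso <- function(table, spec, variance = 0.99, n_pcs = NULL) {
  folds <- loso_folds(table)
  metrics_report(lapply(folds, function(f)
    train_eval_fold(table, f, spec, variance, n_pcs)))
}

#' Column-wise confusion-matrix error rates
#'
#' For each predicted-class column, the percentage of its predictions that
#' were wrong: `(column sum - diagonal) / column sum * 100` (0 for an empty
#' column). The summary is the unweighted mean of the per-column percentages
#' — the convention used in published per-participant confusion-matrix
#' tables.
#'
#' @param cm Square confusion matrix.
#' @return List: `per_class` (named percentages) and `average`.
#' @export
column_error_rates <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm))
  colsum <- colSums(cm)
  err <- ifelse(colsum > 0, (colsum - diag(cm)) / colsum * 100, 0)
  names(err) <- colnames(cm)
  list(per_class = err, average = mean(err))
}
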