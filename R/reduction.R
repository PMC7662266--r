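# Standardization and PCA with the cumulative explained-variance rule.

#' Fit / apply a feature standardizer
#'
#' Stores per-feature training means and standard deviations; transformed
#' training data has mean 0 and SD 1 per non-degenerate feature. Zero-variance
#' features get SD 1 (with a warning) so they map to exactly 0. Test rows must
#' be transformed with training statistics only — never refit on test data.
#'
#' @param rows Numeric matrix or data.frame of feature columns (>= 2 rows).
#' @return List of class `"gait_standardizer"` with `mean` and `sd` vectors.
#' @export
fit_standardizer <- function(rows) {
  X <- as.matrix(rows)
  stopifnot(nrow(X) >= 2)
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  if (any(sd == 0)) {
    warning(sum(sd == 0), " zero-variance feature(s); SD set to 1")
    sd[sd == 0] <- 1
  }
  structure(list(mean = mu, sd = sd), class = "gait_standardizer")
}

#' @rdname fit_standardizer
#' @param model A fitted `"gait_standardizer"`.
#' @return `apply_standardizer()`: the standardized numeric matrix.
#' @export
apply_standardizer <- function(model, rows) {
  X <- as.matrix(rows)
  stopifnot(identical(colnames(X), names(model$mean)))
  sweep(sweep(X, 2, model$mean), 2, model$sd, "/")
}

#' Principal component analysis of standardized features
#'
#' Eigendecomposition of the empirical covariance, components ordered by
#' decreasing variance. Each axis is oriented so its largest-magnitude
#' loading is positive, making scores deterministic across linear-algebra
#' backends.
#'
#' @param rows Standardized numeric matrix (>= 2 rows).
#' @return List of class `"gait_pca"`: `rotation` (d x k_max orthonormal
#'   axes), `eigenvalues` (score variances), `explained_variance_ratio` and
#'   `cumulative_explained_variance`.
#' @export
fit_pca <- function(rows) {
  X <- as.matrix(rows)
  stopifnot(nrow(X) >= 2, ncol(X) >= 1)
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  rotation <- sweep(pc$rotation, 2, flip, "*")
  ev <- pc$sdev^2
  ratio <- ev / sum(ev)
  structure(list(
    rotation = rotation,
    eigenvalues = ev,
    explained_variance_ratio = ratio,
    cumulative_explained_variance = cumsum(ratio)
  ), class = "gait_pca")
}

#' Number of components for a variance threshold
#'
#' Smallest k whose cumulative explained-variance ratio reaches the
#' threshold. The conventional threshold in this pipeline is 0.99.
#'
#' @param model A `"gait_pca"`.
#' @param threshold In (0, 1].
#' @return Integer component count.
#' @export
n_components_for_variance <- function(model, threshold = 0.99) {
  stopifnot(threshold > 0, threshold <= 1)
  which(model$cumulative_explained_variance >= threshold - 1e-12)[1]
}

#' Project rows onto the first k principal axes
#'
#' @param model A `"gait_pca"`.
#' @param rows Standardized rows (same columns the model was fit on).
#' @param k Number of components (1 <= k <= k_max).
#' @return Scores matrix (rows x k).
#' @export
pca_transform <- function(model, rows, k = ncol(model$rotation)) {
  if (k <= 0) stop("k must be positive")
  stopifnot(k <= ncol(model$rotation))
  as.matrix(rows) %*% model$rotation[, seq_len(k), drop = FALSE]
}

#' @rdname pca_transform
#' @param scores Scores from [pca_transform()].
#' @return `pca_inverse()`: reconstruction in the standardized feature space.
#' @export
pca_inverse <- function(model, scores) {
  k <- ncol(scores)
  scores %*% t(model$rotation[, seq_len(k), drop = FALSE])
}

#' Explained-variance table
#'
#' @param model A `"gait_pca"`.
#' @return data.frame `component`, `ratio`, `cumulative` — the input for an
#'   explained-variance curve.
#' @export
explained_variance_table <- function(model) {
  data.frame(component = seq_along(model$explained_variance_ratio),
             ratio = model$explained_variance_ratio,
             cumulative = model$cumulative_explained_variance)
}
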