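#' Principal component analysis
#'
#' Mean-centered PCA by singular value decomposition, with a deterministic
#' sign convention (the largest-magnitude loading of each component is made
#' positive) so that fitted models are reproducible across platforms.
#'
#' @param X A [feature_matrix()] or numeric matrix (samples x features).
#' @param k Number of components to keep; `k <= min(n_samples - 1,
#'   n_features)`.
#' @return An object of class `pca_model`: `mean` (feature means),
#'   `loadings` (features x k, orthonormal columns),
#'   `explained_variance_ratio` (length k, non-increasing fractions) and
#'   `sdev` (component standard deviations).
#' @export
#' @examples
#' X <- matrix(rnorm(60), 10, 6)
#' m <- fit_pca(X, 2)
#' sum(m$explained_variance_ratio) <= 1
fit_pca <- function(X, k) {
  M <- fm_values(X)
  n <- nrow(M); p <- ncol(M)
  if (k < 1 || k > min(n - 1, p))
    of_stop("invalid_spec",
            "k must satisfy 1 <= k <= min(n_samples - 1, n_features) = %d",
            min(n - 1, p))
  mu <- colMeans(M)
  Xc <- sweep(M, 2, mu)
  sv <- svd(Xc)
  total <- sum(sv$d^2)
  if (total < 1e-12 * max(1, mean(abs(mu))^2))
    of_stop("degenerate_input",
            "all samples are identical: zero total variance, PCA undefined")
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  # sign convention: largest-|loading| entry of each component positive
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) loadings[, j] <- -loadings[, j]
  }
  rownames(loadings) <- colnames(M)
  colnames(loadings) <- sprintf("PC%d", seq_len(k))
  structure(
    list(mean = mu, loadings = loadings,
         explained_variance_ratio = sv$d[seq_len(k)]^2 / total,
         sdev = sv$d[seq_len(k)] / sqrt(max(n - 1, 1))),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d features -> %d components (%.1f%% variance)\n",
              nrow(x$loadings), ncol(x$loadings),
              100 * sum(x$explained_variance_ratio)))
  invisible(x)
}

#' Project samples onto fitted principal components
#'
#' Scores are `(X - mean) %*% loadings`.
#'
#' @param model A `pca_model` from [fit_pca()].
#' @param X A [feature_matrix()] or numeric matrix with the same feature
#'   count the model was fitted on.
#' @return A [feature_matrix()] of scores if `X` is one (labels and
#'   modality preserved), otherwise a plain score matrix.
#' @export
transform_pca <- function(model, X) {
  stopifnot(inherits(model, "pca_model"))
  M <- fm_values(X)
  if (ncol(M) != length(model$mean))
    of_stop("dimension_mismatch",
            "model was fitted on %d features but input has %d",
            length(model$mean), ncol(M))
  scores <- sweep(M, 2, model$mean) %*% model$loadings
  if (inherits(X, "feature_matrix")) {
    feature_matrix(scores, X$labels, X$sample_ids, X$modality)
  } else {
    scores
  }
}

#' Maximum admissible number of principal components
#'
#' Overfitting guard: the number of components fed to a classifier is kept
#' strictly below half the size of the smallest class.
#'
#' @param class_sizes Integer vector of per-class sample counts, all >= 2.
#' @return The largest integer strictly smaller than `min(class_sizes) / 2`.
#' @export
#' @examples
#' max_components(c(35, 35))  # 17
max_components <- function(class_sizes) {
  if (length(class_sizes) == 0 || any(class_sizes < 2))
    of_stop("invalid_spec", "every class must contain at least 2 samples")
  m <- min(class_sizes)
  as.integer(floor((m - 1) / 2))
}
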