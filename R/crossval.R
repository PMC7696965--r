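# Cross-validation of the PCA -> discriminant chain, on one modality or on
# the fused pair. `features` is either a single matrix/feature_matrix or a
# named list of them (one entry per modality); with a list, each modality
# gets its own PCA and the scores are concatenated, mirroring fuse_features.

#' Cross-validate the PCA-discriminant pipeline
#'
#' For every fold the held-out samples are predicted by a model fitted on
#' the remaining samples. By default the PCA of each modality is refitted
#' inside every training fold (no information leaks from the test fold);
#' `refit_pca = FALSE` fits PCA once on all samples and cross-validates only
#' the classifier, the common shortcut in which dimension reduction precedes
#' validation.
#'
#' @param features A [feature_matrix()]/matrix, or a named list of them
#'   (same rows in the same order) for fused evaluation.
#' @param labels Class labels; taken from the (first) `feature_matrix` if
#'   omitted.
#' @param kind Classifier kind, `"linear"` or `"quadratic"`.
#' @param k_components Principal components kept per modality (default 2).
#' @param scheme `"loocv"` or `"kfold"`.
#' @param k Number of folds for `"kfold"` (default 10).
#' @param seed Seed for the stratified fold assignment (`"kfold"` only).
#' @param refit_pca Refit PCA within each training fold (default `TRUE`).
#' @param ridge Passed to [fit_discriminant()].
#' @param standardize Passed to the fused score concatenation.
#'
#' @return An object of class `cv_result`: `scheme`, `k` (number of folds),
#'   `seed`, `per_fold_errors` (fraction misclassified per fold),
#'   `error_rate` (percent misclassified overall), `predictions` and
#'   `confusion`.
#' @export
#' @examples
#' co <- generate_cohort(cohort_spec(n_patients = 6, seed = 2))
#' vs <- quantify_cohort(co)
#' cross_validate(vs, scheme = "loocv")$error_rate
cross_validate <- function(features, labels = NULL,
                           kind = c("linear", "quadratic"),
                           k_components = 2,
                           scheme = c("loocv", "kfold"), k = 10, seed = 1,
                           refit_pca = TRUE, ridge = NULL,
                           standardize = FALSE) {
  kind <- match.arg(kind)
  scheme <- match.arg(scheme)
  if (!is.list(features) || inherits(features, "feature_matrix"))
    features <- list(features)
  mats <- lapply(features, fm_values)
  n <- nrow(mats[[1]])
  if (!all(vapply(mats, nrow, 0L) == n))
    of_stop("sample_mismatch", "all modalities must have the same sample rows")
  if (is.null(labels)) {
    is_fm <- vapply(features, inherits, TRUE, "feature_matrix")
    if (!any(is_fm))
      of_stop("invalid_spec",
              "labels must be supplied when no input is a feature_matrix")
    labels <- features[[which(is_fm)[1]]]$labels
  }
  labels <- factor(labels)
  if (length(labels) != n) of_stop("invalid_spec", "one label per sample required")
  if (n < 3) of_stop("invalid_spec", "need at least 3 samples to cross-validate")
  if (nlevels(labels) < 2)
    of_stop("invalid_spec", "both classes must be present")

  folds <- if (scheme == "loocv") {
    as.list(seq_len(n))
  } else {
    if (k < 2 || k > n)
      of_stop("invalid_spec", "k must satisfy 2 <= k <= n (k=%d, n=%d)", k, n)
    stratified_folds(labels, k, seed)
  }

  ks <- rep_len(k_components, length(mats))
  # without refitting, dimension reduction is done once on all samples
  scores_all <- if (!refit_pca) {
    do.call(cbind, lapply(seq_along(mats), function(m)
      transform_pca(fit_pca(mats[[m]], ks[m]), mats[[m]])))
  } else NULL

  pred <- factor(rep(NA_character_, n), levels = levels(labels))
  per_fold <- numeric(length(folds))
  for (f in seq_along(folds)) {
    test <- folds[[f]]
    train <- setdiff(seq_len(n), test)
    if (nlevels(droplevels(labels[train])) < nlevels(labels))
      of_stop("fold_degenerate",
              "training fold %d lost a class entirely; use stratified folds or more samples",
              f)
    if (refit_pca) {
      tr <- list(); te <- list()
      for (m in seq_along(mats)) {
        pm <- fit_pca(mats[[m]][train, , drop = FALSE], ks[m])
        tr[[m]] <- transform_pca(pm, mats[[m]][train, , drop = FALSE])
        te[[m]] <- transform_pca(pm, mats[[m]][test, , drop = FALSE])
      }
      Xtr <- do.call(cbind, tr); Xte <- do.call(cbind, te)
    } else {
      Xtr <- scores_all[train, , drop = FALSE]
      Xte <- scores_all[test, , drop = FALSE]
    }
    if (standardize && length(mats) > 1) {
      sds <- apply(Xtr, 2, sd); sds[sds == 0] <- 1
      Xtr <- sweep(Xtr, 2, sds, "/"); Xte <- sweep(Xte, 2, sds, "/")
    }
    model <- fit_discriminant(Xtr, labels[train], kind, ridge)
    ph <- predict_discriminant(model, Xte)
    pred[test] <- ph
    per_fold[f] <- mean(ph != labels[test])
  }

  cm <- confusion(as.character(labels), as.character(pred),
                  positive_class = if ("tumor" %in% levels(labels))
                    "tumor" else levels(labels)[2])
  structure(
    list(scheme = scheme, k = length(folds),
         seed = if (scheme == "kfold") seed else NA_integer_,
         per_fold_errors = per_fold,
         error_rate = 100 * mean(as.character(pred) != as.character(labels)),
         predictions = pred, confusion = cm),
    class = "cv_result"
  )
}

#' @rdname cross_validate
#' @param ... Passed on to [cross_validate()].
#' @export
loocv <- function(features, labels = NULL, ...) {
  cross_validate(features, labels, scheme = "loocv", ...)
}

#' @rdname cross_validate
#' @export
kfold_cv <- function(features, labels = NULL, k = 10, seed = 1, ...) {
  cross_validate(features, labels, scheme = "kfold", k = k, seed = seed, ...)
}

# stratified, seeded fold assignment. Within each class samples are
# shuffled and dealt round-robin; the dealing start is rotated between
# classes so overall fold sizes differ by at most one.
stratified_folds <- function(labels, k, seed) {
  n <- length(labels)
  fold_of <- integer(n)
  with_seed(seed, {
    offset <- 0L
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold_of[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- (offset + length(idx)) %% k
    }
  })
  lapply(seq_len(k), function(f) which(fold_of == f))
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s (%d folds): error rate %.2f%%\n",
              x$scheme, x$k, x$error_rate))
  invisible(x)
}
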