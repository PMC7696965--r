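#' Fit a Gaussian discriminant classifier (LDA / QDA)
#'
#' Classical Gaussian discriminant analysis: each class is modelled as a
#' multivariate normal with its empirical mean; the linear variant pools one
#' within-class covariance matrix across classes (linear decision boundary),
#' the quadratic variant keeps one covariance per class (quadratic
#' boundary). Priors are the empirical class frequencies. A small ridge is
#' added to the covariance diagonal to keep it positive-definite with few
#' samples in few dimensions.
#'
#' @param X A [feature_matrix()] or numeric matrix (samples x features).
#' @param labels Class labels (ignored if `X` is a `feature_matrix`).
#' @param kind `"linear"` or `"quadratic"`.
#' @param ridge Non-negative ridge added as `ridge * I`; the default
#'   `1e-8 * mean(diag(cov))` only guards numerical rank. Pass `0` to
#'   disable (singular covariances then raise an error suggesting a ridge).
#' @return An object of class `discriminant_model`.
#' @export
#' @examples
#' X <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 3), 20))
#' m <- fit_discriminant(X, rep(c("normal", "tumor"), each = 20), "linear")
#' table(predict_discriminant(m, X))
fit_discriminant <- function(X, labels = NULL,
                             kind = c("linear", "quadratic"), ridge = NULL) {
  kind <- match.arg(kind)
  M <- fm_values(X)
  if (inherits(X, "feature_matrix")) labels <- X$labels
  labels <- factor(labels)
  if (nlevels(labels) < 2)
    of_stop("invalid_spec", "need at least 2 classes, got %d", nlevels(labels))
  if (length(labels) != nrow(M))
    of_stop("invalid_spec", "one label per sample required")
  classes <- sort(levels(labels))  # lexicographic order fixes tie-breaking
  counts <- table(factor(labels, levels = classes))
  if (any(counts < 2))
    of_stop("invalid_spec", "every class needs >= 2 samples (got %s)",
            paste(counts, collapse = ", "))
  p <- ncol(M)
  n <- nrow(M)
  means <- lapply(classes, function(cl) colMeans(M[labels == cl, , drop = FALSE]))
  names(means) <- classes

  # degenerate geometry: coincident class means give an undefined boundary
  mu_mat <- do.call(rbind, means)
  spread <- max(dist(mu_mat))
  scale <- max(apply(M, 2, sd), 1e-12)
  if (spread < 1e-10 * scale)
    of_stop("degenerate_input",
            "class means coincide; the discriminant boundary is undefined")

  centered <- M - mu_mat[as.integer(factor(labels, levels = classes)), ,
                         drop = FALSE]
  covs <- if (kind == "linear") {
    pooled <- crossprod(centered) / (n - length(classes))
    stats::setNames(rep(list(pooled), length(classes)), classes)
  } else {
    stats::setNames(lapply(classes, function(cl) {
      Xi <- centered[labels == cl, , drop = FALSE]
      crossprod(Xi) / (nrow(Xi) - 1)
    }), classes)
  }

  if (is.null(ridge)) ridge <- 1e-8 * mean(vapply(covs, function(S)
    mean(diag(as.matrix(S))), 0))
  chols <- lapply(covs, function(S) {
    S <- as.matrix(S) + diag(ridge, p)
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch))
      of_stop("singular_covariance",
              "covariance matrix is singular; supply a ridge > 0")
    ch
  })

  structure(
    list(kind = kind, classes = classes, means = means,
         covariances = covs, chol = chols,
         log_dets = vapply(chols, function(ch) 2 * sum(log(diag(ch))), 0),
         priors = as.numeric(counts) / n, ridge = ridge, p = p),
    class = "discriminant_model"
  )
}

#' @export
print.discriminant_model <- function(x, ...) {
  cat(sprintf("<discriminant_model> %s, %d classes (%s), %d features\n",
              x$kind, length(x$classes), paste(x$classes, collapse = ", "),
              x$p))
  invisible(x)
}

#' Per-class discriminant scores
#'
#' Returns the exact Gaussian log-density plus log-prior for every sample
#' and class: `log N(x; mu_c, Sigma_c) + log pi_c` (pooled `Sigma` for the
#' linear kind). Classification is the argmax over columns.
#'
#' @param model A `discriminant_model`.
#' @param X A [feature_matrix()] or numeric matrix.
#' @return Numeric matrix, samples x classes.
#' @export
discriminant_scores <- function(model, X) {
  stopifnot(inherits(model, "discriminant_model"))
  M <- fm_values(X)
  if (ncol(M) != model$p)
    of_stop("dimension_mismatch", "model expects %d features, input has %d",
            model$p, ncol(M))
  out <- matrix(0, nrow(M), length(model$classes),
                dimnames = list(rownames(M), model$classes))
  for (j in seq_along(model$classes)) {
    cl <- model$classes[j]
    dev <- sweep(M, 2, model$means[[cl]])
    # Mahalanobis via triangular solve against the stored Cholesky factor
    z <- backsolve(model$chol[[cl]], t(dev), transpose = TRUE)
    maha <- colSums(z^2)
    out[, j] <- -0.5 * (model$p * log(2 * pi) + model$log_dets[j] + maha) +
      log(model$priors[j])
  }
  out
}

#' Predict class labels with a discriminant model
#'
#' Argmax of the per-class discriminant scores; exact ties resolve to the
#' lexicographically first class label.
#'
#' @inheritParams discriminant_scores
#' @return Factor of predicted labels with the model's class levels.
#' @export
predict_discriminant <- function(model, X) {
  sc <- discriminant_scores(model, X)
  # which.max returns the first maximum; columns are in lexicographic order
  idx <- apply(sc, 1, which.max)
  factor(model$classes[idx], levels = model$classes)
}
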