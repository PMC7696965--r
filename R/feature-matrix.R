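#' Construct a feature matrix
#'
#' The common container moved between pipeline stages: a numeric samples x
#' features matrix with per-sample class labels, sample ids and a modality
#' tag (`"raman"`, `"velscope"` or `"fused"`).
#'
#' @param values Numeric matrix, samples in rows; no missing values.
#' @param labels Tissue class per sample (character or factor).
#' @param sample_ids Character sample identifiers (default: rownames).
#' @param modality One of `"raman"`, `"velscope"`, `"fused"`.
#'
#' @return An object of class `feature_matrix` with elements `values`
#'   (rownames set to `sample_ids`), `labels` (factor) and `modality`.
#' @export
feature_matrix <- function(values, labels, sample_ids = rownames(values),
                           modality = c("raman", "velscope", "fused")) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  if (anyNA(values) || !all(is.finite(values)))
    of_stop("invalid_features", "feature values must be finite and non-missing")
  if (length(labels) != nrow(values))
    of_stop("invalid_features", "one label per sample required (%d vs %d rows)",
            length(labels), nrow(values))
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(nrow(values)))
  if (length(sample_ids) != nrow(values) || anyDuplicated(sample_ids))
    of_stop("invalid_features", "sample_ids must be unique, one per row")
  rownames(values) <- sample_ids
  structure(list(values = values, labels = factor(labels),
                 sample_ids = as.character(sample_ids), modality = modality),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %s: %d samples x %d features (%s)\n",
              x$modality, nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", levels(x$labels), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

# pull the numeric matrix out of a feature_matrix or pass a matrix through
fm_values <- function(x) {
  if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
}
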