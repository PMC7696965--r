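#' Fuse principal-component scores of two modalities
#'
#' Feature-level fusion: the score matrices of the two modalities are
#' aligned by sample id and concatenated column-wise. With the default two
#' components per modality this yields the 4-feature fused representation
#' (PC1, PC2 of the spectra plus PC1, PC2 of the images) that the combined
#' classifier is trained on. Scores are fused raw; set `standardize = TRUE`
#' to divide each column by its SD first (sensitivity analysis).
#'
#' @param raman_scores,velscope_scores [feature_matrix()] objects sharing
#'   the same sample ids (any row order).
#' @param standardize Standardize columns to unit SD before concatenation.
#' @return A [feature_matrix()] with modality `"fused"`, rows in the order
#'   of `raman_scores`.
#' @export
#' @examples
#' co <- generate_cohort(cohort_spec(n_patients = 4, seed = 1))
#' rs <- transform_pca(fit_pca(preprocess_cohort(co), 2), preprocess_cohort(co))
#' vs <- transform_pca(fit_pca(quantify_cohort(co), 2), quantify_cohort(co))
#' dim(fuse_features(rs, vs)$values)  # 8 x 4
fuse_features <- function(raman_scores, velscope_scores,
                          standardize = FALSE) {
  stopifnot(inherits(raman_scores, "feature_matrix"),
            inherits(velscope_scores, "feature_matrix"))
  a <- raman_scores; b <- velscope_scores
  extra_a <- setdiff(a$sample_ids, b$sample_ids)
  extra_b <- setdiff(b$sample_ids, a$sample_ids)
  if (length(extra_a) || length(extra_b))
    of_stop("sample_mismatch",
            "sample ids do not match; only in first: [%s]; only in second: [%s]",
            paste(extra_a, collapse = ", "), paste(extra_b, collapse = ", "))
  ord <- match(a$sample_ids, b$sample_ids)
  bv <- b$values[ord, , drop = FALSE]
  if (!all(as.character(a$labels) == as.character(b$labels[ord])))
    of_stop("sample_mismatch", "labels disagree between modalities")
  tag <- function(v, modality) {
    nm <- colnames(v)
    if (is.null(nm)) nm <- sprintf("V%d", seq_len(ncol(v)))
    colnames(v) <- paste(modality, nm, sep = "_")
    v
  }
  va <- tag(a$values, a$modality)
  bv <- tag(bv, b$modality)
  values <- cbind(va, bv)
  if (standardize) {
    sds <- apply(values, 2, sd)
    sds[sds == 0] <- 1
    values <- sweep(values, 2, sds, "/")
  }
  feature_matrix(values, a$labels, a$sample_ids, modality = "fused")
}
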