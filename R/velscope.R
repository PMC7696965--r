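#' Boolean mask of a circular ROI
#'
#' A pixel belongs to the disc iff its center lies within the radius
#' (inclusive) of the ROI center; coordinates are 0-based with `cx` the
#' column and `cy` the row.
#'
#' @param image An `roi_image`.
#' @param roi One row of `image$rois` (or any list with `cx`, `cy`, `r`).
#' @return Logical H x W matrix.
#' @export
roi_mask <- function(image, roi) {
  stopifnot(inherits(image, "roi_image"))
  d <- dim(image$pixels)
  if (roi$cx - roi$r < 0 || roi$cx + roi$r > d[2] - 1 ||
      roi$cy - roi$r < 0 || roi$cy + roi$r > d[1] - 1)
    of_stop("roi_out_of_bounds", "ROI disc extends outside the image")
  disc_mask(d[1], d[2], roi$cx, roi$cy, roi$r)
}

# selected channel as an H x W numeric matrix
channel_matrix <- function(image, channel_mode = c("green", "luminance")) {
  channel_mode <- match.arg(channel_mode)
  px <- image$pixels
  if (channel_mode == "green") {
    matrix(as.numeric(px[, , 2]), dim(px)[1], dim(px)[2])
  } else {
    # Rec. 709 luma weights
    0.2126 * px[, , 1] + 0.7152 * px[, , 2] + 0.0722 * px[, , 3]
  }
}

#' Raw pixel statistics of an ROI
#'
#' Mean and population standard deviation (divisor n, deterministic even for
#' one-pixel ROIs) of the selected channel under a mask.
#'
#' @param image An `roi_image`.
#' @param mask Logical matrix from [roi_mask()].
#' @param channel_mode `"green"` (default; autofluorescence is dominated by
#'   the green channel) or `"luminance"`.
#' @return List with `mean`, `sd` and `n_pixels`.
#' @export
roi_raw_stats <- function(image, mask, channel_mode = "green") {
  stopifnot(inherits(image, "roi_image"))
  vals <- channel_matrix(image, channel_mode)[mask]
  if (length(vals) == 0) of_stop("empty_mask", "ROI mask selects no pixels")
  m <- mean(vals)
  list(mean = m, sd = sqrt(mean((vals - m)^2)), n_pixels = length(vals))
}

#' Normalize ROI statistics against the whole image
#'
#' Dividing by the whole-image mean neutralizes global autofluorescence
#' level differences caused by content outside the ROI (teeth, devices,
#' prostheses): `norm_intensity = ROI mean / image mean` and
#' `norm_heterogeneity = ROI SD / image mean`. Both features are exactly
#' invariant under global linear rescaling of pixel intensities.
#'
#' @param roi_stats List from [roi_raw_stats()].
#' @param global_stats List with at least `mean` for the same channel over
#'   the reference region (whole image by default).
#' @return List with `norm_intensity` and `norm_heterogeneity`.
#' @export
normalize_roi_features <- function(roi_stats, global_stats) {
  if (!is.finite(global_stats$mean) || global_stats$mean <= 0)
    of_stop("degenerate_image", "whole-image mean must be positive")
  list(norm_intensity = roi_stats$mean / global_stats$mean,
       norm_heterogeneity = roi_stats$sd / global_stats$mean)
}

#' Quantify every ROI of an image
#'
#' @param image An `roi_image`.
#' @param channel_mode Channel passed to [roi_raw_stats()].
#' @param include_roi_in_global If `TRUE` (default) the normalization
#'   denominator is the mean over the whole image; otherwise the ROI's own
#'   pixels are excluded from the denominator.
#' @return Data frame with one row per ROI: `patient_id`, `tissue_class`,
#'   `norm_intensity`, `norm_heterogeneity`, `n_pixels`.
#' @export
quantify_image <- function(image, channel_mode = "green",
                           include_roi_in_global = TRUE) {
  stopifnot(inherits(image, "roi_image"))
  ch <- channel_matrix(image, channel_mode)
  out <- lapply(seq_len(nrow(image$rois)), function(i) {
    roi <- image$rois[i, ]
    mask <- roi_mask(image, roi)
    rs <- roi_raw_stats(image, mask, channel_mode)
    gvals <- if (include_roi_in_global) ch else ch[!mask]
    feats <- normalize_roi_features(rs, list(mean = mean(gvals)))
    data.frame(patient_id = roi$patient_id, tissue_class = roi$class,
               norm_intensity = feats$norm_intensity,
               norm_heterogeneity = feats$norm_heterogeneity,
               n_pixels = rs$n_pixels, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Quantify the autofluorescence features of a cohort
#'
#' @param cohort A `dual_cohort` (or any list with an `images` element).
#' @inheritParams quantify_image
#' @param as_matrix If `TRUE` (default) return a [feature_matrix()] with
#'   columns `norm_intensity` and `norm_heterogeneity`, rows sorted by
#'   (patient, class) to align with [preprocess_cohort()]; otherwise return
#'   the long data frame.
#' @return A [feature_matrix()] (modality `"velscope"`) or a data frame.
#' @export
#' @examples
#' co <- generate_cohort(cohort_spec(n_patients = 3, seed = 1))
#' quantify_cohort(co, as_matrix = FALSE)
quantify_cohort <- function(cohort, channel_mode = "green",
                            include_roi_in_global = TRUE, as_matrix = TRUE) {
  if (length(cohort$images) == 0)
    of_stop("invalid_spec", "cohort contains no images")
  df <- do.call(rbind, lapply(cohort$images, quantify_image,
                              channel_mode = channel_mode,
                              include_roi_in_global = include_roi_in_global))
  rownames(df) <- NULL
  if (!as_matrix) return(df)
  ids <- paste(df$patient_id, df$tissue_class, sep = "_")
  ord <- order(ids)
  values <- as.matrix(df[ord, c("norm_intensity", "norm_heterogeneity")])
  feature_matrix(values, df$tissue_class[ord], ids[ord],
                 modality = "velscope")
}
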