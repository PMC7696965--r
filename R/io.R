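# Plain-text interchange: two-column spectrum CSVs plus a manifest CSV,
# 8-bit PNG images plus an ROI JSON, and JSON model serialization.

#' Write / read a spectrum as a two-column CSV
#'
#' Columns `wavenumber,intensity`; metadata travels in the manifest, not in
#' the file.
#'
#' @param s A [raman_spectrum()].
#' @param path File path.
#' @return `write_spectrum_csv` returns `path` invisibly;
#'   `read_spectrum_csv` returns a [raman_spectrum()].
#' @export
write_spectrum_csv <- function(s, path) {
  stopifnot(inherits(s, "raman_spectrum"))
  write.csv(data.frame(wavenumber = s$wavenumber, intensity = s$intensity),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @param patient_id,tissue_class,replicate Metadata attached to the read
#'   spectrum (usually from the manifest).
#' @export
read_spectrum_csv <- function(path, patient_id = "P00",
                              tissue_class = "normal",
                              replicate = NA_integer_) {
  df <- read.csv(path)
  if (!all(c("wavenumber", "intensity") %in% names(df)))
    of_stop("invalid_spec", "%s lacks wavenumber/intensity columns", path)
  raman_spectrum(df$wavenumber, df$intensity, patient_id, tissue_class,
                 replicate)
}

#' Write a cohort to disk
#'
#' Spectra as per-replicate CSVs plus `manifest.csv` (columns `patient_id`,
#' `tissue_class`, `replicate`, `path`), images as 8-bit RGB PNGs plus
#' `rois.json` (a list of `{patient_id, class, cx, cy, r}` records with
#' 0-based pixel coordinates).
#'
#' @param cohort A `dual_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "dual_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec_dir <- file.path(dir, "spectra")
  dir.create(spec_dir, showWarnings = FALSE)
  manifest <- cohort$manifest
  manifest$path <- file.path("spectra", paste0(manifest$spectrum_id, ".csv"))
  for (i in seq_along(cohort$spectra))
    write_spectrum_csv(cohort$spectra[[i]], file.path(dir, manifest$path[i]))
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)

  if (length(cohort$images)) {
    img_dir <- file.path(dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    rois <- list()
    for (img in cohort$images) {
      pid <- img$rois$patient_id[1]
      png::writePNG(img$pixels / 255, file.path(img_dir, paste0(pid, ".png")))
      for (i in seq_len(nrow(img$rois)))
        rois[[length(rois) + 1L]] <- list(
          patient_id = pid, class = img$rois$class[i],
          cx = img$rois$cx[i], cy = img$rois$cy[i], r = img$rois$r[i])
    }
    jsonlite::write_json(rois, file.path(dir, "rois.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.csv` and optionally
#'   `images/` + `rois.json`.
#' @return A `dual_cohort` (with `spec = NULL`).
#' @export
read_cohort <- function(dir) {
  manifest_path <- file.path(dir, "manifest.csv")
  if (!file.exists(manifest_path))
    of_stop("invalid_spec", "no manifest.csv under %s", dir)
  manifest <- read.csv(manifest_path, stringsAsFactors = FALSE)
  spectra <- lapply(seq_len(nrow(manifest)), function(i)
    read_spectrum_csv(file.path(dir, manifest$path[i]),
                      manifest$patient_id[i], manifest$tissue_class[i],
                      manifest$replicate[i]))
  images <- list()
  roi_path <- file.path(dir, "rois.json")
  if (file.exists(roi_path)) {
    rois_all <- jsonlite::fromJSON(roi_path)
    for (pid in unique(rois_all$patient_id)) {
      px01 <- png::readPNG(file.path(dir, "images", paste0(pid, ".png")))
      px <- array(as.integer(round(px01 * 255)), dim = dim(px01))
      rr <- rois_all[rois_all$patient_id == pid, ]
      images[[length(images) + 1L]] <- structure(
        list(pixels = px[, , 1:3, drop = FALSE],
             rois = data.frame(patient_id = rr$patient_id, class = rr$class,
                               cx = rr$cx, cy = rr$cy, r = rr$r,
                               stringsAsFactors = FALSE)),
        class = "roi_image")
    }
  }
  structure(list(spectra = spectra, images = images,
                 manifest = manifest[, c("patient_id", "tissue_class",
                                         "replicate", "spectrum_id")],
                 spec = NULL),
            class = "dual_cohort")
}

#' Serialize fitted models to JSON
#'
#' Means, loadings and covariances as nested arrays, for audit and replay.
#'
#' @param model A `pca_model` or `discriminant_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
model_to_json <- function(model, path) {
  obj <- if (inherits(model, "pca_model")) {
    list(type = "pca", mean = model$mean,
         loadings = unclass(model$loadings),
         explained_variance_ratio = model$explained_variance_ratio,
         sdev = model$sdev)
  } else if (inherits(model, "discriminant_model")) {
    list(type = "discriminant", kind = model$kind, classes = model$classes,
         means = model$means,
         covariances = lapply(model$covariances, unclass),
         priors = model$priors, ridge = model$ridge)
  } else of_stop("invalid_spec", "unsupported model class")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# write a feature matrix as a wide CSV: sample_id, tissue_class, features
write_feature_csv <- function(fm, path) {
  df <- data.frame(sample_id = fm$sample_ids,
                   tissue_class = as.character(fm$labels),
                   fm$values, check.names = FALSE, row.names = NULL)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
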