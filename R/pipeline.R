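#' Pipeline configuration
#'
#' One object carrying every knob of the end-to-end analysis: cohort
#' generation, preprocessing, ROI quantification, dimension reduction,
#' classification and cross-validation.
#'
#' @param cohort A [cohort_spec()].
#' @param preprocess A [preprocess_config()].
#' @param channel_mode Image channel for ROI statistics (`"green"` or
#'   `"luminance"`).
#' @param k_components Principal components kept per modality (default 2:
#'   PC1 and PC2 of each modality, four fused features).
#' @param classifiers Classifier kinds to run.
#' @param cv_k Folds for k-fold cross-validation (default 10, stratified).
#' @param cv_seed Seed for the fold assignment (defaults to the cohort seed).
#' @param paper_mode If `TRUE`, cross-validation reuses a single PCA fitted
#'   on all samples (dimension reduction outside the validation loop)
#'   instead of refitting it per training fold. [run_pipeline()] reports
#'   both variants regardless; this flag selects which one populates the
#'   headline `cv` block.
#' @param out_dir Optional directory; when set, feature tables, models and
#'   the report are written there.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            preprocess = preprocess_config(),
                            channel_mode = "green",
                            k_components = 2,
                            classifiers = c("linear", "quadratic"),
                            cv_k = 10, cv_seed = NULL,
                            paper_mode = FALSE, out_dir = NULL) {
  stopifnot(inherits(cohort, "cohort_spec"),
            inherits(preprocess, "preprocess_config"))
  classifiers <- match.arg(classifiers, c("linear", "quadratic"),
                           several.ok = TRUE)
  if (is.null(cv_seed)) cv_seed <- cohort$seed
  structure(
    list(cohort = cohort, preprocess = preprocess,
         channel_mode = channel_mode, k_components = k_components,
         classifiers = classifiers, cv_k = cv_k,
         cv_seed = as.integer(cv_seed), paper_mode = paper_mode,
         out_dir = out_dir),
    class = "pipeline_config"
  )
}

# one analysis block: resubstitution + cross-validated performance of the
# PCA -> discriminant chain on one modality (or the fused pair)
analyse_block <- function(features, labels, cfg, stage) {
  single <- !is.list(features) || inherits(features, "feature_matrix")
  feats <- if (single) list(features) else features
  res <- list()

  # full-data PCA for the resubstitution fit and for reporting
  pcas <- lapply(feats, function(f) fit_pca(f, cfg$k_components))
  scores <- lapply(seq_along(feats), function(i)
    transform_pca(pcas[[i]], feats[[i]]))
  X <- if (length(scores) == 1) scores[[1]] else
    fuse_features(scores[[1]], scores[[2]])
  res$explained_variance_ratio <- lapply(pcas, `[[`,
                                         "explained_variance_ratio")
  res$n_samples <- length(labels)

  for (kind in cfg$classifiers) {
    model <- fit_discriminant(X, labels, kind)
    cm <- confusion(as.character(labels),
                    as.character(predict_discriminant(model, X)))
    blk <- list(confusion = cm, metrics = performance(cm))
    blk$cv <- list(
      loocv = cross_validate(feats, labels, kind = kind,
                             k_components = cfg$k_components,
                             scheme = "loocv",
                             refit_pca = !cfg$paper_mode),
      kfold = cross_validate(feats, labels, kind = kind,
                             k_components = cfg$k_components,
                             scheme = "kfold", k = cfg$cv_k,
                             seed = cfg$cv_seed,
                             refit_pca = !cfg$paper_mode),
      # the statistically sound variant and the reduce-then-validate
      # shortcut are both reported; `alt_loocv` is whichever the headline
      # `loocv` is not
      alt_loocv = cross_validate(feats, labels, kind = kind,
                                 k_components = cfg$k_components,
                                 scheme = "loocv",
                                 refit_pca = cfg$paper_mode))
    res[[kind]] <- blk
  }
  res$pca <- pcas
  res$scores <- X
  res
}

#' Run the full dual-modality pipeline
#'
#' Generate (or accept) a cohort, preprocess the Raman replicates, quantify
#' the autofluorescence ROIs, then run three analyses — Raman-only,
#' VELscope-only and fused — each with PCA, the configured discriminant
#' classifiers, resubstitution confusion matrices and LOOCV / stratified
#' k-fold error rates. The report carries a provenance block (seed, config
#' checksum, package version) and contains no timestamps, so identical
#' configurations yield identical reports.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optionally a pre-built `dual_cohort`; by default one is
#'   generated from `config$cohort`.
#' @return A list of class `pipeline_report` with elements `provenance`,
#'   `counts`, `features` (per-modality [feature_matrix()] objects) and
#'   `analyses` (blocks `raman`, `velscope`, `fused`).
#' @export
#' @examples
#' cfg <- pipeline_config(cohort_spec(n_patients = 6, seed = 3))
#' rep <- run_pipeline(cfg)
#' rep$analyses$fused$linear$metrics$accuracy
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "generate"
  report <- tryCatch({
    if (is.null(cohort)) cohort <- generate_cohort(config$cohort)

    stage <- "preprocess"
    raman_fm <- preprocess_cohort(cohort, config$preprocess)

    stage <- "quantify"
    velscope_fm <- quantify_cohort(cohort, config$channel_mode)

    stage <- "classify"
    labels <- raman_fm$labels
    if (!identical(raman_fm$sample_ids, velscope_fm$sample_ids))
      of_stop("sample_mismatch",
              "modality sample ids disagree after alignment")
    analyses <- list(
      raman = analyse_block(raman_fm, labels, config, stage),
      velscope = analyse_block(velscope_fm, labels, config, stage),
      fused = analyse_block(list(raman = raman_fm, velscope = velscope_fm),
                            labels, config, stage))

    stage <- "report"
    cfg_json <- jsonlite::toJSON(config_summary(config), auto_unbox = TRUE,
                                 digits = NA)
    list(
      provenance = list(
        package = "oralfusion",
        version = as.character(utils::packageVersion("oralfusion")),
        seed = config$cohort$seed, cv_seed = config$cv_seed,
        config = config_summary(config),
        config_hash = content_hash(charToRaw(as.character(cfg_json)))),
      counts = list(
        n_patients = config$cohort$n_patients,
        n_raw_spectra = length(cohort$spectra),
        n_samples = nrow(raman_fm$values),
        n_roi_feature_rows = nrow(velscope_fm$values)),
      features = list(raman = raman_fm, velscope = velscope_fm),
      analyses = analyses)
  }, oralfusion_error = function(e) {
    of_stop("stage_failure", "pipeline stage '%s' failed: %s", stage,
            conditionMessage(e))
  })
  class(report) <- "pipeline_report"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_csv(report$features$raman,
                      file.path(config$out_dir, "raman_features.csv"))
    write_feature_csv(report$features$velscope,
                      file.path(config$out_dir, "velscope_features.csv"))
    for (mod in names(report$analyses)) {
      pcas <- report$analyses[[mod]]$pca
      for (i in seq_along(pcas))
        model_to_json(pcas[[i]],
                      file.path(config$out_dir,
                                sprintf("pca_%s_%d.json", mod, i)))
    }
    jsonlite::write_json(report_summary(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

# flat, JSON-friendly echo of the configuration (no environments/closures)
config_summary <- function(config) {
  list(
    n_patients = config$cohort$n_patients,
    replicates_per_sample = config$cohort$replicates_per_sample,
    seed = config$cohort$seed,
    effect = unclass(config$cohort$effect),
    preprocess = unclass(config$preprocess),
    channel_mode = config$channel_mode,
    k_components = config$k_components,
    classifiers = config$classifiers,
    cv_k = config$cv_k, cv_seed = config$cv_seed,
    paper_mode = config$paper_mode)
}

# numbers-only view of a report, suitable for JSON emission
report_summary <- function(report) {
  an <- lapply(report$analyses, function(blk) {
    out <- list(explained_variance_ratio = blk$explained_variance_ratio)
    for (kind in intersect(c("linear", "quadratic"), names(blk))) {
      b <- blk[[kind]]
      out[[kind]] <- list(
        confusion = b$confusion[c("tp", "fp", "tn", "fn")],
        metrics = b$metrics,
        loocv_error_rate = b$cv$loocv$error_rate,
        kfold_error_rate = b$cv$kfold$error_rate,
        alt_loocv_error_rate = b$cv$alt_loocv$error_rate)
    }
    out
  })
  list(provenance = report$provenance, counts = report$counts,
       analyses = an)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d patients, %d samples (seed %d)\n",
              x$counts$n_patients, x$counts$n_samples, x$provenance$seed))
  for (mod in names(x$analyses)) {
    blk <- x$analyses[[mod]]
    for (kind in intersect(c("linear", "quadratic"), names(blk))) {
      m <- blk[[kind]]$metrics
      cat(sprintf(
        "  %-8s %-9s acc %5.1f%%  sens %5.1f%%  spec %5.1f%%  LOOCV err %5.1f%%\n",
        mod, kind, m$accuracy, m$sensitivity, m$specificity,
        blk[[kind]]$cv$loocv$error_rate))
    }
  }
  invisible(x)
}

#' Reference confusion tables for the oral-cancer benchmark
#'
#' Published benchmark confusion counts from a 35-patient oral-cancer study
#' (35 tumor and 35 adjacent-normal samples) of the same dual-modality
#' design this package implements, under the tumor-positive convention: the
#' single-modality autofluorescence and Raman analyses and their fused
#' combination, each classified with PCA-LDA and PCA-QDA. Used as a
#' regression fixture for [performance()].
#'
#' @return Data frame with columns `modality`, `classifier`, `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
reference_confusion_counts <- function() {
  path <- system.file("extdata", "reference_confusion_counts.csv",
                      package = "oralfusion")
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write a small fixture bundle
#'
#' A 4-patient synthetic cohort (spectra CSVs, PNG images, ROI JSON,
#' manifest) plus the benchmark confusion-count table, for regression tests
#' and examples. Deterministic: the same seed yields a bundle with the same
#' content hash.
#'
#' @param seed Cohort seed.
#' @param dir Output directory.
#' @param n_patients Cohort size (default 4).
#' @return List with `dir`, `n_spectra`, `n_images` and `hash` (checksum
#'   over all file contents, file names sorted).
#' @export
make_fixtures <- function(seed = 1, dir = tempfile("fixtures"),
                          n_patients = 4) {
  co <- generate_cohort(cohort_spec(n_patients = n_patients, seed = seed))
  write_cohort(co, dir)
  file.copy(system.file("extdata", "reference_confusion_counts.csv",
                        package = "oralfusion"),
            file.path(dir, "reference_confusion_counts.csv"),
            overwrite = TRUE)
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  bytes <- unlist(lapply(files, function(f)
    readBin(f, "raw", file.info(f)$size)))
  list(dir = dir, n_spectra = length(co$spectra),
       n_images = length(co$images), hash = content_hash(bytes))
}
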