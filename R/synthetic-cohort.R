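#' Effect parameters for the synthetic dual-modality cohort
#'
#' Bundles every knob that controls how strongly tumor tissue differs from
#' adjacent-normal tissue in the synthetic cohort, for both modalities.
#'
#' Raman side: a synthetic spectrum is a smooth polynomial fluorescence
#' baseline plus Gaussian peaks at the fingerprint-region bands that
#' discriminate oral tumor from normal mucosa (1004, 1156, 1339, 1450, 1523,
#' 1656 cm^-1, plus the class-neutral 1123 cm^-1 band), plus iid Gaussian
#' noise. Tumor tissue multiplies the amplitude of the discriminating bands
#' by `tumor_amplitude_ratio`. Biological sample-to-sample variability is
#' modelled by two log-normal jitters drawn once per tissue sample (shared by
#' its replicates): a common factor applied to every band
#' (`sample_factor_sd`, overall scattering cross-section) and an independent
#' per-band jitter (`peak_jitter_sd`, composition differences).
#'
#' VELscope side: tumor ROIs lose green autofluorescence
#' (`roi_intensity_drop`, as a fraction of the background level) and become
#' more heterogeneous (`roi_heterogeneity_gain`, multiplier on the pixel SD).
#' Patient-to-patient variability is a truncated-normal jitter on the drop
#' (`roi_drop_sd`) and a log-normal jitter on the gain (`roi_gain_log_sd`).
#'
#' @param peak_centers Band positions in cm^-1.
#' @param normal_amplitude Peak amplitude (a.u.) of each band in normal
#'   tissue; same length as `peak_centers`.
#' @param tumor_amplitude_ratio Per-band tumor/normal amplitude ratio
#'   (dimensionless, >= 0). The default elevates the six discriminating
#'   bands by 1.5 and leaves 1123 cm^-1 unchanged.
#' @param peak_fwhm Full width at half maximum of every band, cm^-1.
#' @param baseline_poly_coeffs Polynomial coefficients (ascending order) of
#'   the fluorescence baseline, evaluated on the axis rescaled to \[-1, 1\].
#' @param noise_sd SD of the iid per-point acquisition noise, a.u.
#' @param sample_factor_sd SD of the per-sample common log-amplitude factor.
#' @param peak_jitter_sd SD of the per-sample, per-band log-amplitude jitter.
#' @param roi_intensity_drop Mean fractional loss of green fluorescence in
#'   tumor ROIs, in \[0, 1\].
#' @param roi_drop_sd Patient-level SD of the drop (truncated to \[0, 1\]).
#' @param roi_heterogeneity_gain Mean multiplier (>= 1) on tumor ROI pixel SD.
#' @param roi_gain_log_sd Patient-level SD of `log(roi_heterogeneity_gain)`.
#'
#' @return An object of class `effect_params`.
#' @export
#' @examples
#' eff <- effect_params()                     # study-default effect sizes
#' null_eff <- null_effect()                  # no class difference at all
#' strong <- scale_effect(effect_params(), 10)
effect_params <- function(peak_centers = c(1004, 1123, 1156, 1339, 1450, 1523, 1656),
                          normal_amplitude = c(1.00, 0.45, 0.85, 0.55, 0.90, 0.70, 0.95),
                          tumor_amplitude_ratio = c(1.5, 1.0, 1.5, 1.5, 1.5, 1.5, 1.5),
                          peak_fwhm = 8,
                          baseline_poly_coeffs = c(5, -1, 0.6),
                          noise_sd = 0.05,
                          sample_factor_sd = 0.20,
                          peak_jitter_sd = 0.10,
                          roi_intensity_drop = 0.35,
                          roi_drop_sd = 0.16,
                          roi_heterogeneity_gain = 2,
                          roi_gain_log_sd = 0.45) {
  np <- length(peak_centers)
  if (length(normal_amplitude) != np || length(tumor_amplitude_ratio) != np)
    of_stop("invalid_spec",
            "normal_amplitude and tumor_amplitude_ratio must match peak_centers in length")
  if (any(peak_fwhm <= 0)) of_stop("invalid_spec", "peak widths must be > 0")
  if (any(tumor_amplitude_ratio < 0))
    of_stop("invalid_spec", "tumor_amplitude_ratio must be >= 0")
  if (noise_sd < 0) of_stop("invalid_spec", "noise_sd must be >= 0")
  if (roi_intensity_drop < 0 || roi_intensity_drop > 1)
    of_stop("invalid_spec", "roi_intensity_drop must lie in [0, 1]")
  if (roi_heterogeneity_gain < 0)
    of_stop("invalid_spec", "roi_heterogeneity_gain must be >= 0")
  structure(
    list(peak_centers = peak_centers,
         normal_amplitude = normal_amplitude,
         tumor_amplitude_ratio = tumor_amplitude_ratio,
         peak_fwhm = peak_fwhm,
         baseline_poly_coeffs = baseline_poly_coeffs,
         noise_sd = noise_sd,
         sample_factor_sd = sample_factor_sd,
         peak_jitter_sd = peak_jitter_sd,
         roi_intensity_drop = roi_intensity_drop,
         roi_drop_sd = roi_drop_sd,
         roi_heterogeneity_gain = roi_heterogeneity_gain,
         roi_gain_log_sd = roi_gain_log_sd),
    class = "effect_params"
  )
}

#' @rdname effect_params
#' @export
null_effect <- function() {
  eff <- effect_params()
  eff$tumor_amplitude_ratio[] <- 1
  eff$roi_intensity_drop <- 0
  eff$roi_heterogeneity_gain <- 1
  eff
}

#' @rdname effect_params
#' @param eff An `effect_params` object.
#' @param factor Multiplier applied to every class-contrast parameter:
#'   amplitude log-ratios, intensity drop (capped at 0.95) and
#'   heterogeneity log-gain. Patient/sample jitters are left untouched.
#' @export
scale_effect <- function(eff, factor) {
  stopifnot(inherits(eff, "effect_params"), factor >= 0)
  eff$tumor_amplitude_ratio <- exp(factor * log(eff$tumor_amplitude_ratio))
  eff$roi_intensity_drop <- min(0.95, factor * eff$roi_intensity_drop)
  eff$roi_heterogeneity_gain <- exp(factor * log(eff$roi_heterogeneity_gain))
  eff
}

#' Specify a synthetic cohort
#'
#' The defaults reproduce the study design the package targets: 35 patients,
#' one tumor and one adjacent-normal tissue sample each, five replicate
#' Raman spectra per sample (350 raw spectra, 70 averaged), and one
#' autofluorescence image per patient carrying a tumor and a normal ROI.
#'
#' @param n_patients Number of patients (>= 1).
#' @param replicates_per_sample Replicate spectra per tissue sample (>= 1).
#' @param seed Integer root seed; the whole cohort is a pure function of the
#'   spec, independent of the caller's RNG state.
#' @param effect [effect_params()] controlling the class contrast.
#'
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 35, replicates_per_sample = 5,
                        seed = 1, effect = effect_params()) {
  if (!is.numeric(n_patients) || n_patients < 1 ||
      n_patients != round(n_patients))
    of_stop("invalid_spec", "n_patients must be a positive integer, got %s",
            deparse(n_patients))
  if (!is.numeric(replicates_per_sample) || replicates_per_sample < 1 ||
      replicates_per_sample != round(replicates_per_sample))
    of_stop("invalid_spec",
            "replicates_per_sample must be a positive integer, got %s",
            deparse(replicates_per_sample))
  stopifnot(inherits(effect, "effect_params"))
  structure(
    list(n_patients = as.integer(n_patients),
         replicates_per_sample = as.integer(replicates_per_sample),
         seed = as.integer(seed), effect = effect),
    class = "cohort_spec"
  )
}

# default acquisition grid: 600-1900 cm^-1 at the instrument's 1 cm^-1 step
default_grid <- function() seq(600, 1900, by = 1)

# evaluate the baseline polynomial on an axis rescaled to [-1, 1]
eval_baseline <- function(wavenumber, coeffs) {
  u <- (wavenumber - mean(range(wavenumber))) / (diff(range(wavenumber)) / 2)
  drop(outer(u, seq_along(coeffs) - 1, "^") %*% coeffs)
}

# Gaussian basis matrix: one column per band, unit amplitude
peak_basis <- function(wavenumber, centers, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  exp(-outer(wavenumber, centers, "-")^2 / (2 * sigma^2))
}

#' Synthesize one Raman spectrum
#'
#' Deterministic signal model: polynomial fluorescence baseline plus a sum of
#' Gaussian bands plus iid Gaussian noise drawn from the current RNG stream.
#' Tumor tissue multiplies the amplitude of each band by its
#' `tumor_amplitude_ratio`. Per-sample biological jitter is applied by
#' [generate_cohort()], not here: given the same `effect` and zero
#' `noise_sd`, this function is a pure function of `tissue_class`.
#'
#' @param tissue_class `"normal"` or `"tumor"`.
#' @param effect An [effect_params()] object.
#' @param wavenumber Acquisition grid; must cover 600-1900 cm^-1 and contain
#'   every band center.
#' @param patient_id,replicate Metadata carried into the returned spectrum.
#' @param log_amp_shift Optional per-band additive shift on the log
#'   amplitudes (the per-sample biological jitter).
#'
#' @return A [raman_spectrum()].
#' @export
#' @examples
#' eff <- effect_params()
#' eff$noise_sd <- 0
#' s <- synth_raman_spectrum("tumor", eff)
synth_raman_spectrum <- function(tissue_class = c("normal", "tumor"),
                                 effect = effect_params(),
                                 wavenumber = default_grid(),
                                 patient_id = "P00", replicate = 1L,
                                 log_amp_shift = 0) {
  tissue_class <- match.arg(tissue_class)
  stopifnot(inherits(effect, "effect_params"))
  rng <- range(wavenumber)
  if (rng[1] > 600 || rng[2] < 1900)
    of_stop("invalid_spec",
            "acquisition grid must cover at least 600-1900 cm^-1 (got %.0f-%.0f)",
            rng[1], rng[2])
  if (any(effect$peak_centers < rng[1] | effect$peak_centers > rng[2]))
    of_stop("invalid_spec", "peak center outside the acquisition grid")
  amps <- exp(log(effect$normal_amplitude) + log_amp_shift)
  if (tissue_class == "tumor") amps <- amps * effect$tumor_amplitude_ratio
  B <- peak_basis(wavenumber, effect$peak_centers, effect$peak_fwhm)
  y <- eval_baseline(wavenumber, effect$baseline_poly_coeffs) +
    drop(B %*% amps)
  if (effect$noise_sd > 0)
    y <- y + rnorm(length(y), 0, effect$noise_sd)
  raman_spectrum(wavenumber, y, patient_id, tissue_class, replicate)
}

#' Synthesize one autofluorescence image with two circular ROIs
#'
#' Emulates a VELscope field of view: a green-dominant background (the pale
#' green fluorescence of healthy mucosa), a normal ROI drawn at background
#' level with low pixel SD, and a tumor ROI at `background * (1 -
#' roi_intensity_drop)` with pixel SD multiplied by
#' `roi_heterogeneity_gain` — the fluorescence loss and heterogeneity gain
#' that mark malignant mucosa. Red and blue channels carry correlated
#' low-amplitude versions of the green signal. Optional bright out-of-ROI
#' artifacts ("teeth") exercise the whole-image normalization downstream.
#'
#' @param effect An [effect_params()] object.
#' @param patient_id Metadata for the ROI records.
#' @param width,height Image size in pixels; must be at least 4x the ROI
#'   radius.
#' @param roi_radius ROI radius in pixels (>= 2).
#' @param bg_green Mean green level of the background (0-255 scale).
#' @param bg_sd Pixel SD of the background green level.
#' @param roi_sd Pixel SD inside a normal ROI.
#' @param artifacts If `TRUE`, draw two bright discs outside the ROIs.
#' @param drop,gain Optional per-patient overrides of
#'   `effect$roi_intensity_drop` / `effect$roi_heterogeneity_gain` (used by
#'   [generate_cohort()] to inject patient-level variability).
#' @param normal_drop,normal_gain Fractional intensity drop and SD gain of
#'   the normal ROI (defaults 0 and 1); [generate_cohort()] draws iid
#'   patient-level jitter for both ROIs so that a null effect is exactly
#'   class-symmetric.
#'
#' @return An object of class `roi_image`: `pixels` (H x W x 3 integer array,
#'   0-255) and `rois` (data frame with 0-based `cx`, `cy` and radius `r`).
#' @export
synth_velscope_image <- function(effect = effect_params(), patient_id = "P00",
                                 width = 160L, height = 160L, roi_radius = 20,
                                 bg_green = 150, bg_sd = 6, roi_sd = 5,
                                 artifacts = FALSE,
                                 drop = NULL, gain = NULL,
                                 normal_drop = 0, normal_gain = 1) {
  stopifnot(inherits(effect, "effect_params"))
  if (roi_radius < 2) of_stop("invalid_spec", "ROI radius must be >= 2 px")
  if (width < 4 * roi_radius || height < 4 * roi_radius)
    of_stop("invalid_spec", "image dimensions must be >= 4x the ROI radius")
  if (is.null(drop)) drop <- effect$roi_intensity_drop
  if (is.null(gain)) gain <- effect$roi_heterogeneity_gain

  # normal ROI on the left, tumor on the right, both on the horizontal
  # midline; coordinates are 0-based (cx = column, cy = row)
  cy <- floor((height - 1) / 2)
  cx_normal <- floor(width * 0.28)
  cx_tumor <- floor(width * 0.72)
  rois <- data.frame(
    patient_id = patient_id,
    class = c("normal", "tumor"),
    cx = c(cx_normal, cx_tumor), cy = cy, r = roi_radius,
    stringsAsFactors = FALSE
  )
  check_rois(rois, width, height)

  G <- matrix(rnorm(height * width, bg_green, bg_sd), height, width)
  for (i in seq_len(nrow(rois))) {
    m <- disc_mask(height, width, rois$cx[i], rois$cy[i], rois$r[i])
    n <- sum(m)
    if (rois$class[i] == "tumor") {
      G[m] <- rnorm(n, bg_green * (1 - drop), roi_sd * gain)
    } else {
      G[m] <- rnorm(n, bg_green * (1 - normal_drop), roi_sd * normal_gain)
    }
  }
  if (artifacts) {
    # two bright "teeth" discs near the top corners, far from the midline ROIs
    for (cx_a in c(floor(width * 0.15), floor(width * 0.85))) {
      m <- disc_mask(height, width, cx_a, floor(height * 0.12),
                     max(2, floor(roi_radius * 0.6)))
      G[m] <- rnorm(sum(m), 240, 4)
    }
  }
  R <- 0.45 * G + rnorm(height * width, 0, 3)
  B <- 0.30 * G + rnorm(height * width, 0, 3)
  px <- array(0L, dim = c(height, width, 3))
  px[, , 1] <- clamp8(R)
  px[, , 2] <- clamp8(G)
  px[, , 3] <- clamp8(B)
  structure(list(pixels = px, rois = rois), class = "roi_image")
}

clamp8 <- function(x) as.integer(pmin(255, pmax(0, round(x))))

# membership: a pixel belongs to the disc iff its center lies within the
# radius (inclusive); 0-based (cx = column, cy = row) convention
disc_mask <- function(height, width, cx, cy, r) {
  col0 <- matrix(rep(0:(width - 1), each = height), height, width)
  row0 <- matrix(rep(0:(height - 1), times = width), height, width)
  (col0 - cx)^2 + (row0 - cy)^2 <= r^2
}

check_rois <- function(rois, width, height) {
  for (i in seq_len(nrow(rois))) {
    if (rois$cx[i] - rois$r[i] < 0 || rois$cx[i] + rois$r[i] > width - 1 ||
        rois$cy[i] - rois$r[i] < 0 || rois$cy[i] + rois$r[i] > height - 1)
      of_stop("roi_out_of_bounds", "ROI %d (%s) extends outside the image",
              i, rois$class[i])
  }
  if (nrow(rois) >= 2) {
    for (i in seq_len(nrow(rois) - 1)) for (j in (i + 1):nrow(rois)) {
      d <- sqrt((rois$cx[i] - rois$cx[j])^2 + (rois$cy[i] - rois$cy[j])^2)
      if (d <= rois$r[i] + rois$r[j])
        of_stop("roi_overlap", "ROIs %d and %d overlap", i, j)
    }
  }
  invisible(rois)
}

#' @export
print.roi_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<roi_image> %dx%d RGB, %d ROIs (%s)\n", d[1], d[2],
              nrow(x$rois), paste(x$rois$class, collapse = ", ")))
  invisible(x)
}

#' Generate a full synthetic dual-modality cohort
#'
#' Produces, for every patient, one tumor and one adjacent-normal tissue
#' sample with `replicates_per_sample` raw Raman spectra each, and one
#' autofluorescence image carrying one tumor and one normal ROI. Per-sample
#' biological jitter (shared across a sample's replicates) and per-patient
#' ROI effect jitter are drawn from patient-specific child RNG streams
#' derived from the root seed, so the cohort is bit-identical for identical
#' specs and stable under subsetting of patients.
#'
#' @param spec A [cohort_spec()].
#' @param modalities Which modalities to generate; generating only one is
#'   cheaper for simulation studies that do not use the other.
#'
#' @return An object of class `dual_cohort`: `spectra` (list of
#'   [raman_spectrum()]), `images` (list of `roi_image`), `manifest` (data
#'   frame linking every spectrum to patient, class, replicate and sample id)
#'   and the originating `spec`.
#' @export
#' @examples
#' co <- generate_cohort(cohort_spec(n_patients = 2, seed = 7))
#' nrow(co$manifest)  # 2 patients x 2 classes x 5 replicates = 20
generate_cohort <- function(spec, modalities = c("raman", "velscope")) {
  stopifnot(inherits(spec, "cohort_spec"))
  modalities <- match.arg(modalities, several.ok = TRUE)
  eff <- spec$effect
  grid <- default_grid()
  B <- peak_basis(grid, eff$peak_centers, eff$peak_fwhm)
  base <- eval_baseline(grid, eff$baseline_poly_coeffs)
  np <- length(eff$peak_centers)

  spectra <- list()
  images <- list()
  manifest <- NULL
  pat_ids <- sprintf("P%02d", seq_len(spec$n_patients))

  for (p in seq_len(spec$n_patients)) {
    child <- (as.double(spec$seed) * 48271 + p * 1664525) %% 2147483647
    with_seed(as.integer(child), {
      for (cls in c("normal", "tumor")) {
        # biological jitter, drawn once per tissue sample
        shift <- rnorm(1, 0, eff$sample_factor_sd) +
          rnorm(np, 0, eff$peak_jitter_sd)
        amps <- exp(log(eff$normal_amplitude) + shift)
        if (cls == "tumor") amps <- amps * eff$tumor_amplitude_ratio
        for (rep_i in seq_len(spec$replicates_per_sample)) {
          y <- base + drop(B %*% amps)
          if (eff$noise_sd > 0) y <- y + rnorm(length(y), 0, eff$noise_sd)
          if ("raman" %in% modalities) {
            s <- raman_spectrum(grid, y, pat_ids[p], cls, rep_i)
            spectra[[length(spectra) + 1L]] <- s
            manifest <- rbind(manifest, data.frame(
              patient_id = pat_ids[p], tissue_class = cls,
              replicate = rep_i,
              spectrum_id = sprintf("%s_%s_r%d", pat_ids[p], cls, rep_i),
              stringsAsFactors = FALSE))
          }
        }
      }
      if ("velscope" %in% modalities) {
        # iid patient-level jitter on both ROIs; the tumor ROI additionally
        # carries the systematic drop/gain, so a zero effect is exactly
        # class-symmetric
        drop_t <- min(1, rnorm(1, eff$roi_intensity_drop, eff$roi_drop_sd))
        drop_n <- min(1, rnorm(1, 0, eff$roi_drop_sd))
        gain_t <- exp(log(max(eff$roi_heterogeneity_gain, 1e-8)) +
                        rnorm(1, 0, eff$roi_gain_log_sd))
        gain_n <- exp(rnorm(1, 0, eff$roi_gain_log_sd))
        images[[p]] <- synth_velscope_image(eff, pat_ids[p],
                                            drop = drop_t, gain = gain_t,
                                            normal_drop = drop_n,
                                            normal_gain = gain_n)
      }
    })
  }
  if (!is.null(manifest)) rownames(manifest) <- NULL
  structure(list(spectra = spectra, images = images, manifest = manifest,
                 spec = spec),
            class = "dual_cohort")
}

#' @export
print.dual_cohort <- function(x, ...) {
  cat(sprintf(
    "<dual_cohort> %d patients, %d raw spectra, %d images (seed %d)\n",
    x$spec$n_patients, length(x$spectra), length(x$images), x$spec$seed))
  invisible(x)
}
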