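#' Raman preprocessing configuration
#'
#' Controls the fixed preprocessing chain applied to each raw spectrum:
#' Savitzky-Golay smoothing, iterative polynomial baseline correction,
#' cropping/resampling to the 700-1800 cm^-1 fingerprint grid, per-spectrum
#' normalization, then replicate averaging with renormalization.
#'
#' @param sg_window Odd Savitzky-Golay window length in points (>= 5). The
#'   default 11 points at the 1 cm^-1 step denoises without flattening the
#'   ~8 cm^-1-wide fingerprint bands.
#' @param sg_order Polynomial order of the smoother (< `sg_window`).
#' @param baseline_poly_order Order of the iteratively refitted baseline
#'   polynomial.
#' @param baseline_iterations Maximum clamp-and-refit iterations.
#' @param fingerprint_lo,fingerprint_hi Fingerprint-region bounds in cm^-1.
#' @param normalization One of `"minmax"` (span exactly \[0, 1\]),
#'   `"unit_area"` (trapezoidal integral 1) or `"unit_norm"` (Euclidean
#'   length 1).
#' @param average_before_normalize If `TRUE`, replicates are averaged on the
#'   cropped grid before normalization; the default normalizes each
#'   replicate first and renormalizes the average, which is robust to
#'   per-acquisition laser-power drift.
#'
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(sg_window = 11, sg_order = 3,
                              baseline_poly_order = 5,
                              baseline_iterations = 50,
                              fingerprint_lo = 700, fingerprint_hi = 1800,
                              normalization = c("minmax", "unit_area", "unit_norm"),
                              average_before_normalize = FALSE) {
  normalization <- match.arg(normalization)
  if (sg_window < 5 || sg_window %% 2 == 0)
    of_stop("invalid_spec", "sg_window must be an odd integer >= 5")
  if (sg_order >= sg_window)
    of_stop("invalid_spec", "sg_order must be smaller than sg_window")
  if (fingerprint_lo >= fingerprint_hi)
    of_stop("invalid_spec", "fingerprint_lo must be below fingerprint_hi")
  structure(
    list(sg_window = as.integer(sg_window), sg_order = as.integer(sg_order),
         baseline_poly_order = as.integer(baseline_poly_order),
         baseline_iterations = as.integer(baseline_iterations),
         fingerprint_lo = fingerprint_lo, fingerprint_hi = fingerprint_hi,
         normalization = normalization,
         average_before_normalize = average_before_normalize),
    class = "preprocess_config"
  )
}

# central Savitzky-Golay kernel: first row of (A'A)^-1 A' for the local
# polynomial design A over offsets -h..h
sg_kernel <- function(window, order) {
  h <- (window - 1L) / 2L
  A <- outer(seq(-h, h), 0:order, "^")
  solve(crossprod(A), t(A))[1L, ]
}

# smooth the columns of Y with mirror padding (no edge shortening)
sg_smooth_matrix <- function(Y, window, order) {
  n <- nrow(Y)
  h <- (window - 1L) / 2L
  if (n <= window)
    of_stop("invalid_spec", "spectrum length (%d) must exceed sg_window (%d)",
            n, window)
  w <- sg_kernel(window, order)
  Ypad <- rbind(Y[(h + 1L):2L, , drop = FALSE], Y,
                Y[(n - 1L):(n - h), , drop = FALSE])
  out <- matrix(0, n, ncol(Y))
  for (j in seq_len(window))
    out <- out + w[j] * Ypad[j:(j + n - 1L), , drop = FALSE]
  out
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing on a uniform wavenumber grid,
#' with mirror padding at the edges so the axis keeps its length. Exact on
#' polynomials of degree up to `sg_order`.
#'
#' @param s A [raman_spectrum()] on a uniformly spaced grid.
#' @param cfg A [preprocess_config()].
#' @return The smoothed [raman_spectrum()]; axis unchanged.
#' @export
savitzky_golay_smooth <- function(s, cfg = preprocess_config()) {
  stopifnot(inherits(s, "raman_spectrum"), inherits(cfg, "preprocess_config"))
  if (!is_uniform_grid(s$wavenumber))
    of_stop("nonuniform_grid",
            "Savitzky-Golay smoothing needs a uniform wavenumber grid; resample first (see crop_and_resample)")
  y <- sg_smooth_matrix(matrix(s$intensity, ncol = 1),
                        cfg$sg_window, cfg$sg_order)
  spectrum_update(s, intensity = drop(y))
}

# iterative polynomial baseline (modified-polyfit): fit, clamp the working
# spectrum to min(spectrum, fit), refit; converges onto the lower envelope
# that fluorescence backgrounds follow. Returns list(baseline, corrected).
baseline_matrix <- function(Y, x, order, iterations, tol = 1e-8) {
  n <- nrow(Y)
  if (order + 1L >= n)
    of_stop("invalid_spec",
            "baseline polynomial order (%d) must be below the number of points (%d)",
            order, n)
  u <- (x - mean(range(x))) / (diff(range(x)) / 2)
  Q <- qr.Q(qr(outer(u, 0:order, "^")))
  work <- Y
  fitted <- Q %*% crossprod(Q, work)
  scale <- max(apply(Y, 2, function(col) diff(range(col))), 1e-12)
  for (it in seq_len(max(iterations - 1L, 0L))) {
    work <- pmin(work, fitted)
    new_fit <- Q %*% crossprod(Q, work)
    delta <- max(abs(new_fit - fitted))
    fitted <- new_fit
    if (delta < tol * scale) break
  }
  list(baseline = fitted, corrected = Y - fitted)
}

#' Baseline correction by iterative polynomial fitting
#'
#' Estimates the slowly varying fluorescence background as the converged
#' lower-envelope polynomial (clamp-to-minimum refitting) and subtracts it.
#'
#' @inheritParams savitzky_golay_smooth
#' @return The baseline-corrected [raman_spectrum()].
#' @export
baseline_correct <- function(s, cfg = preprocess_config()) {
  stopifnot(inherits(s, "raman_spectrum"), inherits(cfg, "preprocess_config"))
  res <- baseline_matrix(matrix(s$intensity, ncol = 1), s$wavenumber,
                         cfg$baseline_poly_order, cfg$baseline_iterations)
  spectrum_update(s, intensity = drop(res$corrected))
}

# canonical fingerprint grid (1 cm^-1 step, bounds inclusive)
fingerprint_grid <- function(cfg) {
  seq(cfg$fingerprint_lo, cfg$fingerprint_hi, by = 1)
}

#' Crop and resample onto the canonical fingerprint grid
#'
#' Linear interpolation onto the 1 cm^-1 grid from `fingerprint_lo` to
#' `fingerprint_hi` inclusive (1101 points with the defaults).
#'
#' @inheritParams savitzky_golay_smooth
#' @return The cropped, resampled [raman_spectrum()].
#' @export
crop_and_resample <- function(s, cfg = preprocess_config()) {
  stopifnot(inherits(s, "raman_spectrum"), inherits(cfg, "preprocess_config"))
  lo <- cfg$fingerprint_lo; hi <- cfg$fingerprint_hi
  if (min(s$wavenumber) > lo || max(s$wavenumber) < hi) {
    missing_lo <- if (min(s$wavenumber) > lo)
      sprintf("%.1f-%.1f", lo, min(s$wavenumber)) else NULL
    missing_hi <- if (max(s$wavenumber) < hi)
      sprintf("%.1f-%.1f", max(s$wavenumber), hi) else NULL
    of_stop("coverage",
            "spectrum does not cover the fingerprint region; missing %s cm^-1",
            paste(c(missing_lo, missing_hi), collapse = " and "))
  }
  grid <- fingerprint_grid(cfg)
  y <- approx(s$wavenumber, s$intensity, xout = grid)$y
  spectrum_update(s, wavenumber = grid, intensity = y)
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

normalize_vector <- function(x, y, mode) {
  switch(mode,
    minmax = {
      rng <- range(y)
      if (diff(rng) <= 0)
        of_stop("degenerate_input",
                "constant spectrum cannot be min-max normalized")
      (y - rng[1]) / diff(rng)
    },
    unit_area = {
      a <- trapz(x, y)
      if (abs(a) < 1e-12)
        of_stop("degenerate_input", "spectrum has (near-)zero area")
      y / a
    },
    unit_norm = {
      nrm <- sqrt(sum(y^2))
      if (nrm < 1e-12)
        of_stop("degenerate_input", "spectrum has (near-)zero Euclidean norm")
      y / nrm
    },
    of_stop("invalid_spec", "unknown normalization mode '%s'", mode)
  )
}

#' Normalize a spectrum
#'
#' @inheritParams savitzky_golay_smooth
#' @param mode Overrides `cfg$normalization` if given.
#' @return The normalized [raman_spectrum()].
#' @export
normalize_spectrum <- function(s, cfg = preprocess_config(), mode = NULL) {
  stopifnot(inherits(s, "raman_spectrum"))
  if (is.null(mode)) mode <- cfg$normalization
  spectrum_update(s, intensity = normalize_vector(s$wavenumber, s$intensity,
                                                  mode))
}

#' Average replicate spectra of one tissue sample
#'
#' Pointwise mean of replicate spectra sharing patient, class and grid,
#' renormalized under the configured mode (set `renormalize = FALSE` for the
#' raw mean).
#'
#' @param replicates List of [raman_spectrum()] objects.
#' @param cfg A [preprocess_config()].
#' @param renormalize Renormalize the mean spectrum (default `TRUE`).
#' @return A single averaged [raman_spectrum()] with `replicate = NA`.
#' @export
average_replicates <- function(replicates, cfg = preprocess_config(),
                               renormalize = TRUE) {
  stopifnot(length(replicates) >= 1,
            all(vapply(replicates, inherits, TRUE, "raman_spectrum")))
  first <- replicates[[1]]
  for (s in replicates) {
    if (s$patient_id != first$patient_id ||
        s$tissue_class != first$tissue_class)
      of_stop("mixed_replicates",
              "replicates mix samples: %s/%s vs %s/%s",
              first$patient_id, first$tissue_class, s$patient_id,
              s$tissue_class)
    if (length(s$wavenumber) != length(first$wavenumber) ||
        any(s$wavenumber != first$wavenumber))
      of_stop("mixed_replicates", "replicates are not on a common grid")
  }
  ymat <- vapply(replicates, function(s) s$intensity,
                 numeric(length(first$intensity)))
  y <- rowMeans(as.matrix(ymat))
  if (renormalize) y <- normalize_vector(first$wavenumber, y, cfg$normalization)
  raman_spectrum(first$wavenumber, y, first$patient_id, first$tissue_class,
                 NA_integer_)
}

#' Preprocess a whole cohort of raw spectra
#'
#' Runs the fixed chain smooth -> baseline -> crop/resample -> normalize ->
#' average replicates -> renormalize over every raw spectrum in a cohort
#' (vectorized across spectra), and returns one fingerprint-region spectrum
#' per (patient, tissue class) sample as a [feature_matrix()].
#'
#' @param cohort A `dual_cohort` from [generate_cohort()], or any list with
#'   `spectra` and `manifest` in the same layout.
#' @param cfg A [preprocess_config()].
#' @return A [feature_matrix()] with one row per sample (sorted by patient,
#'   then class), 1101 wavenumber columns under the default fingerprint
#'   bounds, and modality `"raman"`.
#' @export
#' @examples
#' co <- generate_cohort(cohort_spec(n_patients = 3, seed = 1))
#' fm <- preprocess_cohort(co)
#' dim(fm$values)  # 6 x 1101
preprocess_cohort <- function(cohort, cfg = preprocess_config()) {
  stopifnot(inherits(cfg, "preprocess_config"))
  spectra <- cohort$spectra
  manifest <- cohort$manifest
  if (length(spectra) == 0)
    of_stop("invalid_spec", "cohort contains no spectra")
  grid0 <- spectra[[1]]$wavenumber
  same_grid <- all(vapply(
    spectra, function(s) length(s$wavenumber) == length(grid0) &&
      all(s$wavenumber == grid0), TRUE))
  if (!same_grid)
    of_stop("invalid_spec", "all raw spectra must share one acquisition grid")
  if (!is_uniform_grid(grid0))
    of_stop("nonuniform_grid",
            "raw spectra must be on a uniform grid; resample first")

  Y <- vapply(spectra, function(s) s$intensity, numeric(length(grid0)))
  Y <- sg_smooth_matrix(as.matrix(Y), cfg$sg_window, cfg$sg_order)
  Y <- baseline_matrix(Y, grid0, cfg$baseline_poly_order,
                       cfg$baseline_iterations)$corrected

  grid <- fingerprint_grid(cfg)
  if (min(grid0) > min(grid) || max(grid0) < max(grid))
    of_stop("coverage", "acquisition grid does not cover %.0f-%.0f cm^-1",
            min(grid), max(grid))
  idx <- match(grid, grid0)
  if (anyNA(idx)) {
    Y <- apply(Y, 2, function(col) approx(grid0, col, xout = grid)$y)
  } else {
    Y <- Y[idx, , drop = FALSE]
  }

  if (!cfg$average_before_normalize)
    Y <- apply(Y, 2, normalize_vector, x = grid, mode = cfg$normalization)

  key <- paste(manifest$patient_id, manifest$tissue_class, sep = "_")
  sample_ids <- sort(unique(key))
  avg <- vapply(sample_ids, function(k) {
    m <- rowMeans(Y[, key == k, drop = FALSE])
    normalize_vector(grid, m, cfg$normalization)
  }, numeric(length(grid)))

  values <- t(avg)
  colnames(values) <- sprintf("wn_%d", grid)
  labels <- vapply(strsplit(sample_ids, "_"), `[`, "", 2)
  feature_matrix(values, labels, sample_ids, modality = "raman")
}
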