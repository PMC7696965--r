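#' Construct a Raman spectrum
#'
#' A `raman_spectrum` couples a strictly increasing wavenumber axis (cm^-1)
#' with intensities (arbitrary units) and the sample metadata needed to track
#' it through preprocessing: patient, tissue class and replicate index.
#'
#' @param wavenumber Numeric vector of Raman shifts in cm^-1, strictly
#'   increasing.
#' @param intensity Numeric vector of intensities (a.u.), same length as
#'   `wavenumber`, all finite.
#' @param patient_id Character scalar identifying the patient.
#' @param tissue_class Either `"normal"` or `"tumor"`.
#' @param replicate Integer replicate index (`NA` for averaged spectra).
#'
#' @return An object of class `raman_spectrum`.
#' @export
#' @examples
#' s <- raman_spectrum(600:1900, rnorm(1301), "P01", "tumor", 1L)
#' range(s$wavenumber)
raman_spectrum <- function(wavenumber, intensity, patient_id = "P00",
                           tissue_class = c("normal", "tumor"),
                           replicate = NA_integer_) {
  tissue_class <- match.arg(tissue_class)
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.numeric(intensity)
  if (length(wavenumber) != length(intensity))
    of_stop("invalid_spectrum", "wavenumber and intensity lengths differ (%d vs %d)",
            length(wavenumber), length(intensity))
  if (length(wavenumber) < 2L)
    of_stop("invalid_spectrum", "a spectrum needs at least 2 points")
  if (any(diff(wavenumber) <= 0))
    of_stop("invalid_spectrum", "wavenumbers must be strictly increasing")
  if (!all(is.finite(intensity)))
    of_stop("invalid_spectrum", "intensities must all be finite")
  structure(
    list(wavenumber = wavenumber, intensity = intensity,
         patient_id = as.character(patient_id), tissue_class = tissue_class,
         replicate = as.integer(replicate)),
    class = "raman_spectrum"
  )
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf(
    "<raman_spectrum> %s / %s / replicate %s: %d points, %.0f-%.0f cm^-1\n",
    x$patient_id, x$tissue_class,
    ifelse(is.na(x$replicate), "avg", x$replicate),
    length(x$wavenumber), min(x$wavenumber), max(x$wavenumber)))
  invisible(x)
}

# TRUE when the axis is uniformly spaced (relative tolerance on the step)
is_uniform_grid <- function(wavenumber, tol = 1e-8) {
  d <- diff(wavenumber)
  max(abs(d - d[1])) <= tol * abs(d[1])
}

# rebuild a spectrum with new values, keeping metadata
spectrum_update <- function(s, wavenumber = s$wavenumber, intensity) {
  raman_spectrum(wavenumber, intensity, s$patient_id, s$tissue_class,
                 s$replicate)
}
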