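#' Spectral axis of a hyperspectral data cube
#'
#' A spectral axis is the list of band-center wavelengths shared by all cubes
#' in one acquisition. Wavelengths must be strictly increasing.
#'
#' @param wavelengths_nm Numeric vector of band-center wavelengths in
#'   nanometres, strictly increasing.
#' @return An object of class `phsi_axis` with fields `wavelengths_nm` and
#'   `n_bands`.
#' @examples
#' ax <- spectral_axis(c(470, 540, 610))
#' ax$n_bands
#' @export
spectral_axis <- function(wavelengths_nm) {
  if (!is.numeric(wavelengths_nm) || length(wavelengths_nm) < 1L) {
    stop("wavelengths_nm must be a non-empty numeric vector")
  }
  if (any(!is.finite(wavelengths_nm))) {
    stop("wavelengths_nm must be finite")
  }
  w <- as.numeric(wavelengths_nm)
  if (length(w) > 1L && any(diff(w) <= 0)) {
    stop("wavelengths_nm must be strictly increasing")
  }
  structure(
    list(wavelengths_nm = w, n_bands = length(w)),
    class = "phsi_axis"
  )
}

#' Instrument-resolution spectral axis (470-750 nm, 97 bands)
#'
#' The full spectral grid of the hyperspectral camera the toolkit models:
#' 470 to 750 nm sampled in 97 bands.
#'
#' @return A `phsi_axis`.
#' @export
default_spectral_axis <- function() {
  spectral_axis(seq(470, 750, length.out = 97))
}

#' Coarse working axis (470-750 nm, 14 nm steps, 21 bands)
#'
#' A reduced 21-band grid over the same range, convenient for simulation
#' studies where full spectral resolution is unnecessary.
#'
#' @return A `phsi_axis`.
#' @export
coarse_spectral_axis <- function() {
  spectral_axis(seq(470, 750, by = 14))
}

#' @export
print.phsi_axis <- function(x, ...) {
  cat(sprintf(
    "<phsi_axis> %d bands, %.1f-%.1f nm\n",
    x$n_bands, min(x$wavelengths_nm), max(x$wavelengths_nm)
  ))
  invisible(x)
}

# Nearest band index for a requested wavelength; warns when the snap is not
# exact (beyond numeric fuzz).
nearest_band <- function(axis, wavelength_nm) {
  stopifnot(inherits(axis, "phsi_axis"), length(wavelength_nm) == 1L)
  d <- abs(axis$wavelengths_nm - wavelength_nm)
  i <- which.min(d)
  if (d[i] > 1e-6) {
    warning(sprintf(
      "wavelength %.1f nm is not a band center; snapping to nearest band %.1f nm",
      wavelength_nm, axis$wavelengths_nm[i]
    ), call. = FALSE)
  }
  i
}

same_axis <- function(a, b) {
  a$n_bands == b$n_bands && all(a$wavelengths_nm == b$wavelengths_nm)
}
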