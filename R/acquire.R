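#' Illumination and generator specification
#'
#' The polarization state generator is an unpolarized broadband source behind
#' a linear polarizer (45 deg by default), so the light reaching the sample at
#' band `b` is `0.5 * spectrum[b] * (1, cos 2phi, sin 2phi, 0)`.
#'
#' @param axis A [spectral_axis()].
#' @param spectrum Per-band source intensity, all `>= 0`; defaults to
#'   [halogen_spectrum()].
#' @param generator_axis_deg Transmission axis of the generator polarizer.
#' @return A `phsi_illumination`.
#' @export
illumination_spec <- function(axis, spectrum = halogen_spectrum(axis),
                              generator_axis_deg = 45) {
  stopifnot(inherits(axis, "phsi_axis"))
  if (length(spectrum) != axis$n_bands) {
    stop("spectrum length must equal the number of bands")
  }
  if (any(!is.finite(spectrum)) || any(spectrum < 0)) {
    stop("spectrum must be finite and non-negative")
  }
  structure(list(axis = axis, spectrum = as.numeric(spectrum),
                 generator_axis_deg = generator_axis_deg),
            class = "phsi_illumination")
}

#' Smooth halogen-like source spectrum
#'
#' A 3200 K Planck curve over the axis, normalized to peak 1 — a smooth,
#' red-leaning broadband shape typical of halogen microscope illumination.
#' Normalized Stokes quantities are independent of this shape; it only sets
#' the radiometric scale per band.
#'
#' @param axis A [spectral_axis()].
#' @param temperature_k Color temperature in kelvin.
#' @return Numeric vector of per-band intensities with maximum 1.
#' @export
halogen_spectrum <- function(axis, temperature_k = 3200) {
  stopifnot(inherits(axis, "phsi_axis"))
  lam <- axis$wavelengths_nm
  b <- lam^-5 / (exp(1.4388e7 / (lam * temperature_k)) - 1)
  b / max(b)
}

#' Detector noise specification
#'
#' @param model `"poisson_gaussian"` (shot noise at `photon_scale` expected
#'   counts per unit intensity plus Gaussian read noise; the default),
#'   `"gaussian"` (read noise only) or `"none"`.
#' @param read_sigma Read-noise standard deviation in intensity units.
#' @param photon_scale Expected photon counts at unit intensity.
#' @param seed Integer seed; identical spec and seed give identical noise.
#'   `NULL` draws from the ambient RNG stream.
#' @return A `phsi_noise`.
#' @export
noise_spec <- function(model = c("poisson_gaussian", "gaussian", "none"),
                       read_sigma = 1e-3, photon_scale = 1e4, seed = 0L) {
  model <- match.arg(model)
  stopifnot(read_sigma >= 0, photon_scale > 0)
  structure(list(model = model, read_sigma = read_sigma,
                 photon_scale = photon_scale,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "phsi_noise")
}

apply_noise <- function(x, noise) {
  switch(noise$model,
    none = x,
    gaussian = x + stats::rnorm(length(x), 0, noise$read_sigma),
    poisson_gaussian = {
      counts <- stats::rpois(length(x), noise$photon_scale * pmax(x, 0))
      array(counts / noise$photon_scale +
              stats::rnorm(length(x), 0, noise$read_sigma), dim = dim(x))
    }
  )
}

#' Simulate acquisition of the four analyzer element images
#'
#' Propagates the generator light through the scene's per-pixel Mueller field
#' and the analyzer train for each of the four canonical states, producing
#' the element-image cubes Ih, Iv, I45, Irc. Noise is injected after the
#' ideal intensities, per the noise specification.
#'
#' @param scn A [scene()].
#' @param illum An [illumination_spec()] on the same axis; defaults to the
#'   halogen generator at 45 deg.
#' @param states The four analyzer states, as from [analyzer_states()].
#' @param noise A [noise_spec()].
#' @return A [element_image_set()].
#' @examples
#' ax <- coarse_spectral_axis()
#' scn <- make_qwp_scene(30, c(8, 8), ax)
#' imgs <- simulate_acquisition(scn, noise = noise_spec("none"))
#' st <- normalize_stokes(compute_stokes(imgs))
#' st$s3[1, 1, 1]  # -cos(60 deg) = -0.5
#' @export
simulate_acquisition <- function(scn, illum = NULL,
                                 states = analyzer_states(),
                                 noise = noise_spec()) {
  stopifnot(inherits(scn, "phsi_scene"), inherits(noise, "phsi_noise"))
  if (is.null(illum)) illum <- illumination_spec(scn$axis)
  stopifnot(inherits(illum, "phsi_illumination"))
  if (!same_axis(scn$axis, illum$axis)) {
    stop("scene and illumination have different spectral axes")
  }
  stopifnot(is.list(states), length(states) == 4L)

  exit <- scene_exit_stokes(scn, illum)  # [rows x cols x bands x 4]
  d <- dim(exit)
  ideal <- lapply(states, function(st) {
    w <- analyzer_weights(st)
    array(exit[, , , 1L] * w[1L] + exit[, , , 2L] * w[2L] +
            exit[, , , 3L] * w[3L] + exit[, , , 4L] * w[4L],
          dim = d[1:3])
  })

  inject <- function() {
    lapply(ideal, apply_noise, noise = noise)
  }
  noisy <- if (noise$model != "none" && !is.null(noise$seed)) {
    withr::with_seed(noise$seed, inject())
  } else {
    inject()
  }
  element_image_set(noisy[[1L]], noisy[[2L]], noisy[[3L]], noisy[[4L]],
                    scn$axis)
}

#' Sample-exit Stokes field of a scene under given illumination
#'
#' The ground-truth Stokes vector leaving the sample at every pixel and band,
#' before the analyzer: `M_scene(x, y, lambda) . S_generator(lambda)`. This is
#' the field a noiseless acquisition plus Stokes reconstruction recovers.
#'
#' @param scn A [scene()].
#' @param illum An [illumination_spec()]; defaults to the halogen generator.
#' @return Numeric array `[rows x cols x n_bands x 4]`.
#' @export
scene_exit_stokes <- function(scn, illum = NULL) {
  stopifnot(inherits(scn, "phsi_scene"))
  if (is.null(illum)) illum <- illumination_spec(scn$axis)
  phi <- illum$generator_axis_deg * pi / 180
  gpol <- c(1, cos(2 * phi), sin(2 * phi), 0)
  rows <- scn$dims[1L]; cols <- scn$dims[2L]; nb <- scn$axis$n_bands
  out <- array(0, dim = c(rows, cols, nb, 4L))
  for (b in seq_len(nb)) {
    s <- if (scn$n_slices == 1L) 1L else b
    g <- 0.5 * illum$spectrum[b] * gpol
    for (k in 1:4) {
      acc <- matrix(0, rows, cols)
      for (j in 1:4) {
        if (g[j] != 0) {
          acc <- acc + scn$mueller[, , s, (j - 1L) * 4L + k] * g[j]
        }
      }
      out[, , b, k] <- acc
    }
  }
  out
}
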