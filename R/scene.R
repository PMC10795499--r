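#' Construct a sample scene (per-pixel Mueller field)
#'
#' A scene describes a phantom sample as a field of 4x4 Mueller matrices, one
#' per pixel, optionally varying with wavelength. Scenes stand in for the
#' physical slide: they are propagated through the polarization train by
#' [simulate_acquisition()].
#'
#' @param mueller Numeric array of Mueller entries, either
#'   `[rows x cols x 4 x 4]` (achromatic) or `[rows x cols x n_bands x 4 x 4]`.
#' @param axis A [spectral_axis()].
#' @param description Free-text description of the phantom.
#' @param labels Optional integer matrix `[rows x cols]` of region labels
#'   (0 = background) used to derive ROI masks for phantom features.
#' @return A `phsi_scene`. Matrices are checked for passivity on a sample of
#'   pixels (applying the matrix to physical Stokes vectors must not create
#'   energy or over-polarized states).
#' @export
scene <- function(mueller, axis, description = "", labels = NULL) {
  stopifnot(inherits(axis, "phsi_axis"), is.array(mueller))
  d <- dim(mueller)
  if (length(d) == 4L) {
    mueller <- array(mueller, dim = c(d[1:2], 1L, d[3:4]))
    d <- dim(mueller)
  }
  if (length(d) != 5L || d[4L] != 4L || d[5L] != 4L) {
    stop("mueller must be [rows x cols x 4 x 4] or [rows x cols x bands x 4 x 4]")
  }
  if (!d[3L] %in% c(1L, axis$n_bands)) {
    stop(sprintf("mueller has %d spectral slices; expected 1 or %d",
                 d[3L], axis$n_bands))
  }
  if (!is.null(labels)) {
    stopifnot(is.matrix(labels), identical(dim(labels), d[1:2]))
  }
  # flatten the 4x4 block (column-major) for fast vectorized propagation
  flat <- array(mueller, dim = c(d[1L], d[2L], d[3L], 16L))
  obj <- structure(
    list(mueller = flat, axis = axis, dims = d[1:2],
         n_slices = d[3L], description = description, labels = labels),
    class = "phsi_scene"
  )
  check_scene_passivity(obj)
  obj
}

#' @export
print.phsi_scene <- function(x, ...) {
  cat(sprintf("<phsi_scene> %dx%d pixels, %s%s\n",
              x$dims[1L], x$dims[2L],
              if (x$n_slices == 1L) "achromatic" else
                sprintf("%d spectral slices", x$n_slices),
              if (nzchar(x$description)) paste0(" - ", x$description) else ""))
  invisible(x)
}

#' Mueller matrix of a scene at one pixel and band
#'
#' @param x A `phsi_scene`.
#' @param row,col Pixel indices (1-based, row 1 at image top).
#' @param band Band index; ignored for achromatic scenes.
#' @return A 4x4 numeric matrix.
#' @export
scene_mueller <- function(x, row, col, band = 1L) {
  stopifnot(inherits(x, "phsi_scene"))
  s <- if (x$n_slices == 1L) 1L else band
  matrix(x$mueller[row, col, s, ], 4L, 4L)
}

# Sampled passivity check: random physical Stokes inputs through a sample of
# pixel matrices must keep s0 >= 0 and s1^2+s2^2+s3^2 <= s0^2 (within fuzz).
check_scene_passivity <- function(x, n_sample = 32L, tol = 1e-9) {
  d <- x$dims
  idx <- cbind(
    row = ((seq_len(n_sample) * 7L) %% d[1L]) + 1L,
    col = ((seq_len(n_sample) * 13L) %% d[2L]) + 1L,
    slice = ((seq_len(n_sample) * 3L) %% x$n_slices) + 1L
  )
  # deterministic probe vectors (fully and partially polarized)
  probes <- rbind(
    c(1, 0, 0, 0), c(1, 1, 0, 0), c(1, 0, 1, 0), c(1, 0, 0, 1),
    c(1, -1, 0, 0), c(1, 0, -0.6, 0.8), c(1, 0.5, 0.5, 0.5),
    c(2, 0.9, -0.9, 0.9)
  )
  for (i in seq_len(nrow(idx))) {
    m <- matrix(x$mueller[idx[i, 1L], idx[i, 2L], idx[i, 3L], ], 4L, 4L)
    out <- probes %*% t(m)
    if (any(out[, 1L] < -tol) ||
        any(rowSums(out[, 2:4]^2) > out[, 1L]^2 * (1 + 1e-9) + tol)) {
      stop("scene contains a non-passive Mueller matrix")
    }
  }
  invisible(TRUE)
}

#' Uniform quarter-wave-plate calibration scene
#'
#' Every pixel carries the Mueller matrix of an ideal quarter-wave retarder at
#' the given fast-axis angle. This is the calibration target: rotated between
#' a 45 deg generator and the four-state analyzer it traces analytically
#' known Stokes curves ([theoretical_qwp_stokes()]).
#'
#' @param fast_axis_deg Fast-axis angle of the plate in degrees.
#' @param shape Integer vector `c(rows, cols)`.
#' @param axis A [spectral_axis()].
#' @param dispersion `"achromatic"` (default: retardance constant in
#'   wavelength) or `"inverse_wavelength"` (retardance
#'   `pi/2 * reference_nm / lambda`, a simple first-order chromatic model).
#' @param reference_nm Wavelength at which the plate is exactly quarter-wave
#'   under the dispersive model; defaults to the axis midpoint.
#' @return A `phsi_scene`.
#' @export
make_qwp_scene <- function(fast_axis_deg, shape = c(32L, 32L), axis,
                           dispersion = c("achromatic", "inverse_wavelength"),
                           reference_nm = NULL) {
  dispersion <- match.arg(dispersion)
  stopifnot(length(shape) == 2L, all(shape >= 1L), inherits(axis, "phsi_axis"))
  shape <- as.integer(shape)
  if (dispersion == "achromatic") {
    delta <- pi / 2
    ent <- retarder_elements(fast_axis_deg * pi / 180, delta)  # 1 x 16
    flat <- array(rep(ent, each = prod(shape)),
                  dim = c(shape, 1L, 4L, 4L))
  } else {
    if (is.null(reference_nm)) {
      reference_nm <- mean(range(axis$wavelengths_nm))
    }
    delta <- pi / 2 * reference_nm / axis$wavelengths_nm
    ent <- retarder_elements(rep(fast_axis_deg * pi / 180, axis$n_bands), delta)
    flat <- aperm(array(rep(t(ent), each = prod(shape)),
                        dim = c(shape, 16L, axis$n_bands)), c(1, 2, 4, 3))
    dim(flat) <- c(shape, axis$n_bands, 4L, 4L)
  }
  scene(flat, axis,
        description = sprintf("quarter-wave plate, fast axis %g deg (%s)",
                              fast_axis_deg, dispersion))
}

#' Parameters of the birefringent-fiber phantom
#'
#' The fiber phantom emulates collagen: thin birefringent capsules with the
#' retarder fast axis aligned along the local fiber direction, over a weakly
#' absorbing background. With `fiber_transmittance` equal to
#' `background_transmittance` the fibers are invisible in total intensity
#' (S0) and appear only through their polarization signature, mirroring the
#' sparse-collagen situation the polarized channel is designed to reveal.
#'
#' @param n_fibers Number of fibers; defaults to 24 for `density = "dense"`,
#'   6 for `"sparse"`.
#' @param retardance_max_rad Peak single-pass retardance at a fiber core
#'   (radians). Default 0.6.
#' @param fiber_width_px,length_px Capsule geometry in pixels.
#' @param background_transmittance,fiber_transmittance Intensity transmittance
#'   in `[0, 1]`; scalars (achromatic) or per-band vectors.
#' @param density `"dense"` or `"sparse"`; sets `n_fibers` when unspecified.
#' @param preferred_orientation_deg Optional mean fiber orientation; when
#'   `NULL` orientations are uniform on `[0, 180)`.
#' @param orientation_spread_deg Half-spread around the preferred orientation.
#' @return A `phsi_fiber_params` list.
#' @export
fiber_phantom_params <- function(n_fibers = NULL,
                                 retardance_max_rad = 0.6,
                                 fiber_width_px = 3,
                                 length_px = 40,
                                 background_transmittance = 0.92,
                                 fiber_transmittance = 0.92,
                                 density = c("dense", "sparse"),
                                 preferred_orientation_deg = NULL,
                                 orientation_spread_deg = 20) {
  density <- match.arg(density)
  if (is.null(n_fibers)) n_fibers <- if (density == "dense") 24L else 6L
  stopifnot(retardance_max_rad >= 0, fiber_width_px > 0, length_px > 0,
            all(background_transmittance >= 0 & background_transmittance <= 1),
            all(fiber_transmittance >= 0 & fiber_transmittance <= 1))
  structure(list(
    n_fibers = as.integer(n_fibers),
    retardance_max_rad = retardance_max_rad,
    fiber_width_px = fiber_width_px,
    length_px = length_px,
    background_transmittance = background_transmittance,
    fiber_transmittance = fiber_transmittance,
    density = density,
    preferred_orientation_deg = preferred_orientation_deg,
    orientation_spread_deg = orientation_spread_deg
  ), class = "phsi_fiber_params")
}

#' Birefringent-fiber phantom scene (collagen analog)
#'
#' Places `params$n_fibers` anti-aliased straight capsules at seeded random
#' positions and orientations. Fiber pixels carry an attenuator times a
#' linear retarder with fast axis along the fiber; background pixels are pure
#' attenuators. Fibers extending beyond the image are clipped. Where fibers
#' overlap the locally strongest (largest effective retardance) fiber wins.
#'
#' @param params A [fiber_phantom_params()].
#' @param shape `c(rows, cols)`.
#' @param axis A [spectral_axis()].
#' @param seed Integer seed; identical seeds give identical scenes.
#' @return A `phsi_scene` whose `labels` matrix marks fiber cores (label 1
#'   where fiber coverage exceeds one half).
#' @export
make_fiber_scene <- function(params, shape = c(64L, 64L), axis, seed = 0L) {
  stopifnot(inherits(params, "phsi_fiber_params"),
            length(shape) == 2L, all(shape >= 1L),
            inherits(axis, "phsi_axis"))
  shape <- as.integer(shape)
  rows <- shape[1L]; cols <- shape[2L]
  px_r <- matrix(seq_len(rows), rows, cols)
  px_c <- matrix(seq_len(cols), rows, cols, byrow = TRUE)

  cover <- matrix(0, rows, cols)   # anti-aliased fiber coverage in [0,1]
  theta <- matrix(0, rows, cols)   # fast-axis angle (deg) of winning fiber

  withr::with_seed(seed, {
    for (i in seq_len(params$n_fibers)) {
      cr <- stats::runif(1, 1, rows)
      cc <- stats::runif(1, 1, cols)
      ang <- if (is.null(params$preferred_orientation_deg)) {
        stats::runif(1, 0, 180)
      } else {
        params$preferred_orientation_deg +
          stats::runif(1, -1, 1) * params$orientation_spread_deg
      }
      # direction in (col, -row) coordinates so that angle is measured CCW
      # from the horizontal image axis, matching polarization angles
      ux <- cos(ang * pi / 180); uy <- sin(ang * pi / 180)
      half <- params$length_px / 2
      # signed coordinates of pixels relative to the segment
      dx <- px_c - cc; dy <- -(px_r - cr)
      t_par <- pmax(pmin(dx * ux + dy * uy, half), -half)
      d <- sqrt((dx - t_par * ux)^2 + (dy - t_par * uy)^2)
      aa <- pmin(pmax(params$fiber_width_px / 2 + 0.5 - d, 0), 1)
      win <- aa > cover
      cover[win] <- aa[win]
      theta[win] <- ang
    }
  })

  nb <- max(length(params$background_transmittance),
            length(params$fiber_transmittance))
  chromatic <- nb > 1L
  if (chromatic && nb != axis$n_bands) {
    stop("per-band transmittances must have length n_bands")
  }
  n_slices <- if (chromatic) axis$n_bands else 1L
  delta <- params$retardance_max_rad * cover
  ent <- retarder_elements(as.vector(theta) * pi / 180, as.vector(delta))
  flat <- array(0, dim = c(rows, cols, n_slices, 16L))
  bg <- rep(params$background_transmittance, length.out = n_slices)
  fb <- rep(params$fiber_transmittance, length.out = n_slices)
  for (s in seq_len(n_slices)) {
    trans <- bg[s] + (fb[s] - bg[s]) * as.vector(cover)
    flat[, , s, ] <- ent * trans
  }
  dim(flat) <- c(rows, cols, n_slices, 4L, 4L)
  labels <- matrix(as.integer(cover > 0.5), rows, cols)
  scene(flat, axis,
        description = sprintf("%s fiber phantom, %d fibers, max retardance %.2f rad",
                              params$density, params$n_fibers,
                              params$retardance_max_rad),
        labels = labels)
}

#' Parameters of the absorbing-cell phantom
#'
#' Stylized stained-cell field: absorbing nucleus and cytoplasm disks with
#' wavelength-dependent transmittance (Gaussian absorption bands, by default
#' peaking at 590 nm for the nucleus and 525 nm for the cytoplasm — a
#' hematoxylin/eosin analog, not a dye model) and a small residual nucleus
#' retardance.
#'
#' @param n_cells Number of cells.
#' @param nucleus_radius_px,cytoplasm_radius_px Disk radii in pixels.
#' @param nucleus_peak_absorbance,cytoplasm_peak_absorbance Peak attenuation
#'   in `[0, 1]` at the respective absorption peak.
#' @param nucleus_peak_nm,cytoplasm_peak_nm Absorption peak wavelengths.
#' @param band_width_nm Gaussian sigma of the absorption bands.
#' @param nucleus_absorbance_spectrum,cytoplasm_absorbance_spectrum Optional
#'   explicit per-band attenuations in `[0, 1]`, overriding the Gaussian
#'   defaults.
#' @param nucleus_retardance_rad Residual nucleus retardance (radians).
#' @param nucleus_fast_axis_deg Fast-axis orientation of the nucleus
#'   retardance; `NULL` (default) draws one uniform angle per cell.
#' @param fragmentation Logical; `TRUE` renders each nucleus as several
#'   disjoint lobes (a coarse analog of nuclear fragmentation in poorly
#'   differentiated tumor cells).
#' @param background_transmittance Background transmittance (scalar).
#' @return A `phsi_cell_params` list.
#' @export
cell_phantom_params <- function(n_cells = 5L,
                                nucleus_radius_px = 4,
                                cytoplasm_radius_px = 8,
                                nucleus_peak_absorbance = 0.6,
                                cytoplasm_peak_absorbance = 0.3,
                                nucleus_peak_nm = 590,
                                cytoplasm_peak_nm = 525,
                                band_width_nm = 45,
                                nucleus_absorbance_spectrum = NULL,
                                cytoplasm_absorbance_spectrum = NULL,
                                nucleus_retardance_rad = 0.05,
                                nucleus_fast_axis_deg = NULL,
                                fragmentation = FALSE,
                                background_transmittance = 0.96) {
  stopifnot(n_cells >= 0, nucleus_radius_px > 0,
            cytoplasm_radius_px >= nucleus_radius_px,
            nucleus_retardance_rad >= 0,
            background_transmittance >= 0, background_transmittance <= 1)
  for (a in list(nucleus_peak_absorbance, cytoplasm_peak_absorbance,
                 nucleus_absorbance_spectrum, cytoplasm_absorbance_spectrum)) {
    if (!is.null(a) && any(a < 0 | a > 1)) stop("attenuations must lie in [0, 1]")
  }
  structure(list(
    n_cells = as.integer(n_cells),
    nucleus_radius_px = nucleus_radius_px,
    cytoplasm_radius_px = cytoplasm_radius_px,
    nucleus_peak_absorbance = nucleus_peak_absorbance,
    cytoplasm_peak_absorbance = cytoplasm_peak_absorbance,
    nucleus_peak_nm = nucleus_peak_nm,
    cytoplasm_peak_nm = cytoplasm_peak_nm,
    band_width_nm = band_width_nm,
    nucleus_absorbance_spectrum = nucleus_absorbance_spectrum,
    cytoplasm_absorbance_spectrum = cytoplasm_absorbance_spectrum,
    nucleus_retardance_rad = nucleus_retardance_rad,
    nucleus_fast_axis_deg = nucleus_fast_axis_deg,
    fragmentation = isTRUE(fragmentation),
    background_transmittance = background_transmittance
  ), class = "phsi_cell_params")
}

gaussian_absorbance <- function(axis, peak_nm, peak_abs, sigma_nm) {
  peak_abs * exp(-(axis$wavelengths_nm - peak_nm)^2 / (2 * sigma_nm^2))
}

#' Absorbing-cell phantom scene (stained-cell analog)
#'
#' Places `params$n_cells` cells at seeded random positions. Each cell is a
#' cytoplasm disk with wavelength-dependent attenuation containing a nucleus
#' (one disk, or several disjoint lobes when `params$fragmentation` is TRUE)
#' with stronger attenuation and a small residual retardance at a random fast
#' axis. Cells overflowing the image are clipped.
#'
#' @param params A [cell_phantom_params()].
#' @param shape `c(rows, cols)`.
#' @param axis A [spectral_axis()].
#' @param seed Integer seed.
#' @return A `phsi_scene` whose `labels` matrix holds the nucleus region of
#'   cell `i` as label `i` (0 = background/cytoplasm).
#' @export
make_cell_scene <- function(params, shape = c(64L, 64L), axis, seed = 0L) {
  stopifnot(inherits(params, "phsi_cell_params"),
            length(shape) == 2L, all(shape >= 1L),
            inherits(axis, "phsi_axis"))
  shape <- as.integer(shape)
  rows <- shape[1L]; cols <- shape[2L]
  px_r <- matrix(seq_len(rows), rows, cols)
  px_c <- matrix(seq_len(cols), rows, cols, byrow = TRUE)

  nuc_abs <- params$nucleus_absorbance_spectrum %||%
    gaussian_absorbance(axis, params$nucleus_peak_nm,
                        params$nucleus_peak_absorbance, params$band_width_nm)
  cyt_abs <- params$cytoplasm_absorbance_spectrum %||%
    gaussian_absorbance(axis, params$cytoplasm_peak_nm,
                        params$cytoplasm_peak_absorbance, params$band_width_nm)
  nuc_abs <- rep(nuc_abs, length.out = axis$n_bands)
  cyt_abs <- rep(cyt_abs, length.out = axis$n_bands)

  in_cyt <- matrix(FALSE, rows, cols)
  labels <- matrix(0L, rows, cols)
  theta <- matrix(0, rows, cols)

  withr::with_seed(seed, {
    for (i in seq_len(params$n_cells)) {
      cr <- stats::runif(1, 1, rows)
      cc <- stats::runif(1, 1, cols)
      d2 <- (px_r - cr)^2 + (px_c - cc)^2
      in_cyt <- in_cyt | (d2 <= params$cytoplasm_radius_px^2)
      ax_deg <- params$nucleus_fast_axis_deg %||% stats::runif(1, 0, 180)
      if (params$fragmentation) {
        n_lobes <- sample(2:4, 1)
        lobe_r <- params$nucleus_radius_px / 1.8
        angles <- stats::runif(1, 0, 2 * pi) +
          seq(0, 2 * pi, length.out = n_lobes + 1L)[seq_len(n_lobes)]
        sep <- lobe_r + 2.5  # keeps lobes disjoint after pixelation
        for (a in angles) {
          lr <- cr + sep * sin(a); lc <- cc + sep * cos(a)
          nd2 <- (px_r - lr)^2 + (px_c - lc)^2
          sel <- nd2 <= lobe_r^2
          labels[sel] <- i
          theta[sel] <- ax_deg
        }
      } else {
        sel <- d2 <= params$nucleus_radius_px^2
        labels[sel] <- i
        theta[sel] <- ax_deg
      }
    }
  })

  in_nuc <- labels > 0L
  delta <- ifelse(in_nuc, params$nucleus_retardance_rad, 0)
  ent <- retarder_elements(as.vector(theta) * pi / 180, as.vector(delta))
  flat <- array(0, dim = c(rows, cols, axis$n_bands, 16L))
  for (b in seq_len(axis$n_bands)) {
    trans <- params$background_transmittance *
      ifelse(in_cyt, 1 - cyt_abs[b], 1) *
      ifelse(in_nuc, 1 - nuc_abs[b], 1)
    flat[, , b, ] <- ent * as.vector(trans)
  }
  dim(flat) <- c(rows, cols, axis$n_bands, 4L, 4L)
  scene(flat, axis,
        description = sprintf("cell phantom, %d cells%s", params$n_cells,
                              if (params$fragmentation) " (fragmented nuclei)" else ""),
        labels = labels)
}
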