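#' Quarter-wave-plate calibration protocol
#'
#' Defines the fast-axis sweep of the rotating quarter-wave-plate calibration
#' target and the wavelengths at which RMSE is reported.
#'
#' @param angles_deg Fast-axis positions in degrees within `[0, 180]`;
#'   default 0 to 180 in 10-degree increments (19 positions).
#' @param wavelengths_nm Reporting wavelengths; snapped to the nearest band
#'   center of the data (with a warning when not exact). Default
#'   `c(470, 525, 626)`.
#' @return A `phsi_protocol`.
#' @export
calibration_protocol <- function(angles_deg = seq(0, 180, by = 10),
                                 wavelengths_nm = c(470, 525, 626)) {
  stopifnot(is.numeric(angles_deg), length(angles_deg) >= 2L,
            all(angles_deg >= 0 & angles_deg <= 180),
            is.numeric(wavelengths_nm), length(wavelengths_nm) >= 1L)
  structure(list(angles_deg = as.numeric(angles_deg),
                 wavelengths_nm = as.numeric(wavelengths_nm)),
            class = "phsi_protocol")
}

#' Theoretical quarter-wave-plate Stokes curves
#'
#' Normalized Stokes parameters of light leaving an ideal quarter-wave plate
#' with fast axis at `theta_deg`, illuminated by +45 deg linear polarized
#' light:
#' \deqn{S_1 = \sin 2\theta \cos 2\theta,\quad S_2 = \sin^2 2\theta,\quad
#'       S_3 = -\cos 2\theta.}
#'
#' @param theta_deg Fast-axis angle(s) in degrees; vectorized.
#' @return A matrix with columns `s1`, `s2`, `s3` (one row per angle), or a
#'   named vector for a single angle.
#' @examples
#' theoretical_qwp_stokes(45)  # (0, 1, 0)
#' @export
theoretical_qwp_stokes <- function(theta_deg) {
  t2 <- 2 * theta_deg * pi / 180
  out <- cbind(s1 = sin(t2) * cos(t2), s2 = sin(t2)^2, s3 = -cos(t2))
  if (length(theta_deg) == 1L) out[1L, ] else out
}

#' Root-mean-square error between two equal-length curves
#'
#' \deqn{\mathrm{RMSE} = \sqrt{\tfrac{1}{N}\sum_{n=1}^{N}(x_n - y_n)^2}.}
#' Symmetric in its arguments and invariant to reordering applied to both.
#'
#' @param experimental,theoretical Numeric vectors of equal length `N >= 1`.
#' @return Non-negative scalar.
#' @export
rmse <- function(experimental, theoretical) {
  stopifnot(is.numeric(experimental), is.numeric(theoretical))
  if (length(experimental) != length(theoretical) ||
      length(experimental) < 1L) {
    stop("experimental and theoretical must have equal length N >= 1")
  }
  sqrt(mean((experimental - theoretical)^2))
}

#' Simulate a quarter-wave-plate calibration sweep
#'
#' Produces one element-image set per protocol angle by simulating the
#' uniform quarter-wave-plate scene at that fast-axis position.
#'
#' @param protocol A [calibration_protocol()].
#' @param shape `c(rows, cols)` of the simulated field of view.
#' @param axis A [spectral_axis()].
#' @param illum Optional [illumination_spec()].
#' @param noise A [noise_spec()]; its `seed` field is ignored in favor of
#'   `seed` below so that the sweep draws independent noise per angle from
#'   one stream.
#' @param seed Integer seed for the whole sweep; `NULL` uses the ambient RNG.
#' @param angle_offset_deg Systematic angular misalignment added to every
#'   plate position (the protocol still labels sets by the nominal angle) —
#'   useful for studying calibration sensitivity.
#' @return Named list of [element_image_set()]s keyed by nominal angle.
#' @export
simulate_qwp_sweep <- function(protocol = calibration_protocol(),
                               shape = c(64L, 64L),
                               axis = coarse_spectral_axis(),
                               illum = NULL,
                               noise = noise_spec(),
                               seed = 0L,
                               angle_offset_deg = 0) {
  stopifnot(inherits(protocol, "phsi_protocol"))
  noise_local <- noise
  noise_local$seed <- NULL
  run <- function() {
    sets <- lapply(protocol$angles_deg, function(a) {
      scn <- make_qwp_scene(a + angle_offset_deg, shape, axis)
      simulate_acquisition(scn, illum = illum, noise = noise_local)
    })
    names(sets) <- as.character(protocol$angles_deg)
    sets
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

sweep_key <- function(sweep, angle) {
  keys <- sub("^angle_", "", names(sweep))
  match(as.character(angle), keys)
}

#' Run the quarter-wave-plate calibration analysis
#'
#' For each protocol angle: reconstruct the Stokes cube from the element
#' images, normalize by S0, and spatially average the normalized parameters
#' over valid pixels (the calibration target is uniform, so the field mean is
#' the natural per-angle estimate). Experimental curves are compared per band
#' against [theoretical_qwp_stokes()] and RMSE is reported for S1, S2, S3 at
#' each protocol wavelength.
#'
#' @param sweep Named list of [element_image_set()]s keyed by angle (names
#'   `"0", "10", ...` or `"angle_0", ...`), one per protocol angle.
#' @param protocol A [calibration_protocol()].
#' @return A `phsi_calibration` with `rmse` (data frame: `wavelength_nm`,
#'   `parameter`, `rmse`) and `curves` (data frame: `angle_deg`,
#'   `wavelength_nm`, `parameter`, `experimental`, `theoretical`).
#' @export
run_calibration <- function(sweep, protocol = calibration_protocol()) {
  stopifnot(inherits(protocol, "phsi_protocol"), is.list(sweep))
  idx <- vapply(protocol$angles_deg, function(a) {
    i <- sweep_key(sweep, a)
    if (is.na(i)) stop(sprintf("sweep is missing angle %g deg", a))
    i
  }, integer(1))

  first <- sweep[[idx[1L]]]
  stopifnot(inherits(first, "phsi_element_images"))
  axis <- first$axis
  bands <- vapply(protocol$wavelengths_nm, nearest_band, integer(1),
                  axis = axis)

  n_ang <- length(protocol$angles_deg)
  # experimental field-averaged normalized parameters [angle x band x 3]
  exp_curves <- array(NA_real_, dim = c(n_ang, axis$n_bands, 3L))
  for (i in seq_len(n_ang)) {
    st <- normalize_stokes(compute_stokes(sweep[[idx[i]]]))
    for (p in 1:3) {
      cube <- st[[c("s1", "s2", "s3")[p]]]
      exp_curves[i, , p] <- apply(cube, 3L, mean, na.rm = TRUE)
    }
  }
  theo <- theoretical_qwp_stokes(protocol$angles_deg)

  params <- c("s1", "s2", "s3")
  grid <- expand.grid(band = seq_along(bands), p = 1:3)
  rmse_df <- data.frame(
    wavelength_nm = axis$wavelengths_nm[bands[grid$band]],
    parameter = toupper(params[grid$p]),
    rmse = mapply(function(b, p) rmse(exp_curves[, bands[b], p], theo[, p]),
                  grid$band, grid$p)
  )
  curves_df <- do.call(rbind, lapply(seq_along(bands), function(b) {
    do.call(rbind, lapply(1:3, function(p) {
      data.frame(
        angle_deg = protocol$angles_deg,
        wavelength_nm = axis$wavelengths_nm[bands[b]],
        parameter = toupper(params[p]),
        experimental = exp_curves[, bands[b], p],
        theoretical = theo[, p]
      )
    }))
  }))
  structure(list(rmse = rmse_df, curves = curves_df, protocol = protocol),
            class = "phsi_calibration")
}

#' @export
print.phsi_calibration <- function(x, ...) {
  cat("<phsi_calibration> quarter-wave-plate sweep,",
      length(x$protocol$angles_deg), "angles\n")
  print(x$rmse, row.names = FALSE)
  invisible(x)
}

#' Plot calibration curves at one wavelength
#'
#' Theoretical curves (lines) and experimental field-averaged values (points)
#' for S1, S2, S3 against the quarter-wave-plate fast-axis position.
#'
#' @param x A `phsi_calibration`.
#' @param wavelength_nm Which reporting wavelength to plot; defaults to the
#'   first in the protocol.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.phsi_calibration <- function(x, wavelength_nm = NULL, ...) {
  wl <- x$curves$wavelength_nm
  target <- if (is.null(wavelength_nm)) wl[1L] else {
    wl[which.min(abs(unique(wl) - wavelength_nm))]
  }
  cur <- x$curves[abs(x$curves$wavelength_nm - target) < 1e-9, ]
  fine <- seq(0, 180, by = 1)
  theo_fine <- theoretical_qwp_stokes(fine)
  cols <- c(S1 = "#1b6ca8", S2 = "#2e7d32", S3 = "#c62828")
  graphics::plot(NA, xlim = c(0, 180), ylim = c(-1.05, 1.05),
                 xlab = "fast-axis position (deg)",
                 ylab = "normalized Stokes parameter",
                 main = sprintf("QWP calibration at %.0f nm", target), ...)
  for (p in 1:3) {
    nm <- c("S1", "S2", "S3")[p]
    graphics::lines(fine, theo_fine[, p], col = cols[[nm]])
    sel <- cur$parameter == nm
    graphics::points(cur$angle_deg[sel], cur$experimental[sel],
                     col = cols[[nm]], pch = 16, cex = 0.7)
  }
  graphics::legend("topright", legend = names(cols), col = cols,
                   lty = 1, pch = 16, bty = "n", cex = 0.8)
  invisible(x)
}
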