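#' Spectral response curves for RGB synthesis
#'
#' Per-band weights for the red, green and blue channels. Weights must be
#' non-negative; each curve is normalized to unit sum on construction, so
#' channel values are convex combinations of band values.
#'
#' @param axis A [spectral_axis()].
#' @param r_weights,g_weights,b_weights Non-negative numeric vectors of
#'   length `axis$n_bands` with positive sum.
#' @return A `phsi_response_curves`.
#' @export
response_curves <- function(axis, r_weights, g_weights, b_weights) {
  stopifnot(inherits(axis, "phsi_axis"))
  norm1 <- function(w, nm) {
    if (length(w) != axis$n_bands) {
      stop(sprintf("%s must have one weight per band (%d)", nm, axis$n_bands))
    }
    if (any(!is.finite(w)) || any(w < 0)) {
      stop(sprintf("%s must be finite and non-negative", nm))
    }
    s <- sum(w)
    if (s <= 0) stop(sprintf("%s must have positive sum", nm))
    w / s
  }
  structure(list(axis = axis,
                 r_weights = norm1(r_weights, "r_weights"),
                 g_weights = norm1(g_weights, "g_weights"),
                 b_weights = norm1(b_weights, "b_weights")),
            class = "phsi_response_curves")
}

#' Built-in RGB spectral response curves
#'
#' Smooth unimodal raised-cosine lobes peaking near 610 nm (R), 540 nm (G)
#' and 470 nm (B), normalized to unit sum. These are parametric stand-ins
#' shaped like camera/eye response curves — qualitative, not colorimetric.
#' Supply measured curves via [read_response_curves()] to override.
#'
#' @param axis A [spectral_axis()].
#' @param peaks_nm Channel peak wavelengths `c(r, g, b)`.
#' @param half_width_nm Half-width of each lobe (weight reaches zero at
#'   `peak +/- half_width_nm`).
#' @return A `phsi_response_curves`.
#' @export
default_response_curves <- function(axis, peaks_nm = c(610, 540, 470),
                                    half_width_nm = 90) {
  stopifnot(inherits(axis, "phsi_axis"), length(peaks_nm) == 3L)
  lobe <- function(peak) {
    x <- (axis$wavelengths_nm - peak) / half_width_nm
    ifelse(abs(x) < 1, cos(pi * x / 2)^2, 0)
  }
  response_curves(axis, lobe(peaks_nm[1L]), lobe(peaks_nm[2L]),
                  lobe(peaks_nm[3L]))
}

#' Read response curves from a CSV table
#'
#' The table needs columns `wavelength_nm`, `r`, `g`, `b`. Weights are
#' linearly interpolated onto the target axis (flat extrapolation at the
#' ends) and validated: negative weights are rejected.
#'
#' @param path CSV file path.
#' @param axis A [spectral_axis()] to interpolate onto.
#' @return A `phsi_response_curves`.
#' @export
read_response_curves <- function(path, axis) {
  tab <- utils::read.csv(path)
  need <- c("wavelength_nm", "r", "g", "b")
  if (!all(need %in% names(tab))) {
    stop("response-curve CSV must have columns wavelength_nm, r, g, b")
  }
  if (any(!is.finite(as.matrix(tab[, c("r", "g", "b")]))) ||
      any(tab$r < 0 | tab$g < 0 | tab$b < 0)) {
    stop("response-curve weights must be finite and non-negative")
  }
  interp <- function(w) {
    stats::approx(tab$wavelength_nm, w, xout = axis$wavelengths_nm,
                  rule = 2)$y
  }
  response_curves(axis, interp(tab$r), interp(tab$g), interp(tab$b))
}

#' Synthesize an RGB image from one Stokes-parameter data cube
#'
#' Each channel is the per-pixel weighted sum over bands with the channel's
#' response curve. Signed cubes (S1, S2, S3) are first mapped to a
#' non-negative range per the scaling mode; the result is clipped to `[0, 1]`.
#'
#' @param x A `phsi_stokes_cube` (select with `parameter`) or a plain
#'   `[rows x cols x bands]` array.
#' @param parameter For a Stokes cube: `"s0"`, `"s1"`, `"s2"` or `"s3"`.
#' @param curves A [response_curves()]; defaults to
#'   [default_response_curves()] on the cube's axis.
#' @param scaling How signed values are mapped before synthesis:
#'   * `"symmetric"` — affine map of `[-a, a]` to `[0, 1]` with
#'     `a = max(abs(x))`; zero maps to mid-gray. Default for S1, S2, S3.
#'   * `"minmax"` — affine map of the observed range to `[0, 1]`.
#'   * `"identity"` — values used as-is (then clipped). Default for S0, which
#'     is first divided by its maximum.
#' @param clip Clip the result to `[0, 1]` (default). `clip = FALSE` exposes
#'   the unclipped linear synthesis.
#' @return A `phsi_rgb`: `[rows x cols x 3]` array with a `provenance`
#'   attribute recording the source parameter, scaling mode and scale
#'   constants.
#' @export
synthesize_rgb <- function(x, parameter = NULL, curves = NULL,
                           scaling = NULL, clip = TRUE) {
  if (inherits(x, "phsi_stokes_cube")) {
    parameter <- tolower(parameter %||% "s0")
    stopifnot(parameter %in% c("s0", "s1", "s2", "s3"))
    cube <- x[[parameter]]
    axis <- x$axis
    if (is.null(scaling)) {
      scaling <- if (parameter == "s0") "identity" else "symmetric"
    }
    if (parameter == "s0" && scaling == "identity") {
      top <- suppressWarnings(max(abs(cube), na.rm = TRUE))
      if (is.finite(top) && top > 0) cube <- cube / top
    }
  } else {
    stopifnot(is.array(x), length(dim(x)) == 3L)
    cube <- x
    axis <- NULL
    parameter <- parameter %||% "cube"
    scaling <- scaling %||% "symmetric"
  }
  scaling <- match.arg(scaling, c("symmetric", "minmax", "identity"))
  if (all(!is.finite(cube))) {
    stop("cube contains no finite values")
  }
  if (is.null(curves)) {
    if (is.null(axis)) stop("curves must be supplied for a plain array")
    curves <- default_response_curves(axis)
  }
  stopifnot(inherits(curves, "phsi_response_curves"))
  nb <- dim(cube)[3L]
  if (nb != length(curves$r_weights)) {
    stop(sprintf("cube has %d bands but curves have %d", nb,
                 length(curves$r_weights)))
  }

  scale_info <- list(mode = scaling)
  scaled <- switch(scaling,
    symmetric = {
      a <- suppressWarnings(max(abs(cube), na.rm = TRUE))
      scale_info$max_abs <- a
      if (!is.finite(a) || a == 0) array(0.5, dim = dim(cube))
      else (cube + a) / (2 * a)
    },
    minmax = {
      lo <- suppressWarnings(min(cube, na.rm = TRUE))
      hi <- suppressWarnings(max(cube, na.rm = TRUE))
      scale_info$min <- lo; scale_info$max <- hi
      if (!is.finite(hi - lo) || hi == lo) array(0.5, dim = dim(cube))
      else (cube - lo) / (hi - lo)
    },
    identity = cube
  )

  chan <- function(w) {
    acc <- matrix(0, dim(cube)[1L], dim(cube)[2L])
    for (b in seq_len(nb)) acc <- acc + scaled[, , b] * w[b]
    acc
  }
  out <- array(c(chan(curves$r_weights), chan(curves$g_weights),
                 chan(curves$b_weights)),
               dim = c(dim(cube)[1:2], 3L))
  if (clip) out <- pmin(pmax(out, 0), 1)
  structure(out, class = "phsi_rgb",
            provenance = list(parameter = parameter, scaling = scale_info,
                              clipped = clip))
}

#' @export
print.phsi_rgb <- function(x, ...) {
  d <- dim(x)
  pv <- attr(x, "provenance")
  cat(sprintf("<phsi_rgb> %dx%d, from %s (scaling: %s)\n",
              d[1L], d[2L], pv$parameter, pv$scaling$mode))
  invisible(x)
}

#' Write an RGB image as 8-bit PNG
#'
#' @param image A `phsi_rgb` or `[rows x cols x 3]` array in `[0, 1]`;
#'   non-finite pixels are written as black.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_rgb_png <- function(image, path) {
  stopifnot(is.array(image), length(dim(image)) == 3L, dim(image)[3L] == 3L)
  m <- unclass(image)
  m[!is.finite(m)] <- 0
  png::writePNG(pmin(pmax(m, 0), 1), path)
  invisible(path)
}
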