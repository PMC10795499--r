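#' Bundle the four analyzer element-image cubes
#'
#' An element-image set holds the four co-registered intensity cubes recorded
#' under the horizontal (Ih), vertical (Iv), +45 deg (I45) and right-circular
#' (Irc) analyzer states, sharing one field of view and one spectral axis.
#'
#' @param ih,iv,i45,irc Numeric arrays `[rows x cols x n_bands]` (a matrix is
#'   accepted for a single-band axis).
#' @param axis A [spectral_axis()] whose `n_bands` matches the cubes.
#' @return A `phsi_element_images` object.
#' @export
element_image_set <- function(ih, iv, i45, irc, axis) {
  stopifnot(inherits(axis, "phsi_axis"))
  cubes <- list(ih = ih, iv = iv, i45 = i45, irc = irc)
  cubes <- lapply(cubes, as_cube, n_bands = axis$n_bands)
  ref <- dim(cubes$ih)
  for (nm in names(cubes)) {
    d <- dim(cubes[[nm]])
    if (!identical(d, ref)) {
      stop(sprintf("cube '%s' has shape %s; expected %s",
                   nm, paste(d, collapse = "x"), paste(ref, collapse = "x")))
    }
    if (d[3L] != axis$n_bands) {
      stop(sprintf("cube '%s' has %d bands but the spectral axis has %d",
                   nm, d[3L], axis$n_bands))
    }
  }
  structure(c(cubes, list(axis = axis)), class = "phsi_element_images")
}

as_cube <- function(x, n_bands) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L) {
    stop("element images must be [rows x cols x bands] arrays")
  }
  storage.mode(x) <- "double"
  x
}

#' @export
print.phsi_element_images <- function(x, ...) {
  d <- dim(x$ih)
  cat(sprintf("<phsi_element_images> %dx%d pixels, %d bands (Ih, Iv, I45, Irc)\n",
              d[1L], d[2L], d[3L]))
  invisible(x)
}

#' Reconstruct the Stokes data cubes from the four element images
#'
#' Per pixel and band:
#' \deqn{S_0 = I_h + I_v,\quad S_1 = I_h - I_v,\quad
#'       S_2 = 2 I_{45} - (I_h + I_v),\quad S_3 = 2 I_{rc} - (I_h + I_v).}
#'
#' The returned cube is un-normalized. Pixels whose reconstructed vector is
#' non-physical (\eqn{S_1^2+S_2^2+S_3^2 > S_0^2}, which noise can produce) are
#' retained, not clipped; their count is available from `summary()` and the
#' `n_nonphysical` attribute.
#'
#' @param images A [element_image_set()].
#' @return A `phsi_stokes_cube` with fields `s0..s3`, `axis`, `normalized`
#'   (FALSE) and `valid` (logical cube).
#' @examples
#' ax <- spectral_axis(550)
#' imgs <- element_image_set(matrix(1, 2, 2), matrix(0, 2, 2),
#'                           matrix(0.5, 2, 2), matrix(0.5, 2, 2), ax)
#' st <- compute_stokes(imgs)
#' st$s1[1, 1, 1]  # 1: pure horizontal light
#' @export
compute_stokes <- function(images) {
  stopifnot(inherits(images, "phsi_element_images"))
  s0 <- images$ih + images$iv
  s1 <- images$ih - images$iv
  s2 <- 2 * images$i45 - s0
  s3 <- 2 * images$irc - s0
  valid <- is.finite(s0) & is.finite(s1) & is.finite(s2) & is.finite(s3)
  cube <- stokes_cube(s0, s1, s2, s3, images$axis,
                      normalized = FALSE, valid = valid)
  nonphys <- valid & (s1^2 + s2^2 + s3^2 > s0^2 * (1 + 1e-12))
  attr(cube, "n_nonphysical") <- sum(nonphys)
  cube
}

#' Construct a Stokes data cube
#'
#' Container for the four co-registered Stokes-parameter cubes. Usually
#' produced by [compute_stokes()] rather than called directly.
#'
#' @param s0,s1,s2,s3 Numeric arrays `[rows x cols x n_bands]`.
#' @param axis A [spectral_axis()].
#' @param normalized Logical; `TRUE` when `s1..s3` are S0-normalized ratios.
#' @param valid Logical cube marking pixels usable in downstream statistics;
#'   defaults to all finite entries.
#' @return A `phsi_stokes_cube`.
#' @export
stokes_cube <- function(s0, s1, s2, s3, axis, normalized = FALSE,
                        valid = NULL) {
  stopifnot(inherits(axis, "phsi_axis"))
  cubes <- lapply(list(s0 = s0, s1 = s1, s2 = s2, s3 = s3),
                  as_cube, n_bands = axis$n_bands)
  ref <- dim(cubes$s0)
  for (nm in names(cubes)) {
    if (!identical(dim(cubes[[nm]]), ref)) {
      stop(sprintf("cube '%s' has a different shape from 's0'", nm))
    }
  }
  if (ref[3L] != axis$n_bands) {
    stop(sprintf("cubes have %d bands but the spectral axis has %d",
                 ref[3L], axis$n_bands))
  }
  if (is.null(valid)) {
    valid <- is.finite(cubes$s0) & is.finite(cubes$s1) &
      is.finite(cubes$s2) & is.finite(cubes$s3)
  }
  stopifnot(is.logical(valid), identical(dim(valid), ref))
  structure(
    c(cubes, list(axis = axis, normalized = isTRUE(normalized), valid = valid)),
    class = "phsi_stokes_cube"
  )
}

#' Normalize a Stokes cube by its total intensity
#'
#' Divides `s1`, `s2`, `s3` elementwise by `s0` where `|s0|` exceeds
#' `epsilon`; pixels at or below the threshold are flagged invalid (set to
#' `NA` and removed from the `valid` mask) rather than producing infinities.
#' After normalization `s0` is identically 1 at valid pixels.
#'
#' @param cube An un-normalized `phsi_stokes_cube`.
#' @param epsilon Positive threshold on `|s0|`. Default
#'   `1e-9 * max(s0)` (with a machine-epsilon floor), so that the cutoff
#'   scales with the cube's radiometric level.
#' @return A normalized `phsi_stokes_cube`.
#' @export
normalize_stokes <- function(cube, epsilon = NULL) {
  stopifnot(inherits(cube, "phsi_stokes_cube"))
  if (cube$normalized) {
    stop("cube is already normalized")
  }
  if (is.null(epsilon)) {
    top <- suppressWarnings(max(cube$s0[cube$valid], na.rm = TRUE))
    epsilon <- max(1e-9 * abs(top), .Machine$double.eps)
  }
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, epsilon > 0)
  ok <- cube$valid & is.finite(cube$s0) & (abs(cube$s0) > epsilon)
  div <- ifelse(ok, cube$s0, NA_real_)
  s0 <- array(ifelse(ok, 1, NA_real_), dim = dim(cube$s0))
  out <- stokes_cube(s0, cube$s1 / div, cube$s2 / div, cube$s3 / div,
                     cube$axis, normalized = TRUE, valid = ok)
  attr(out, "n_invalid") <- sum(cube$valid & !ok)
  out
}

#' @export
print.phsi_stokes_cube <- function(x, ...) {
  d <- dim(x$s0)
  cat(sprintf("<phsi_stokes_cube> %dx%d pixels, %d bands (%s)\n",
              d[1L], d[2L], d[3L],
              if (x$normalized) "S0-normalized" else "un-normalized"))
  np <- attr(x, "n_nonphysical")
  if (!is.null(np) && np > 0) {
    cat(sprintf("  %d non-physical pixels retained (S1^2+S2^2+S3^2 > S0^2)\n", np))
  }
  invisible(x)
}

#' @export
summary.phsi_stokes_cube <- function(object, ...) {
  d <- dim(object$s0)
  out <- list(
    dim = d,
    normalized = object$normalized,
    n_valid = sum(object$valid),
    n_invalid = prod(d) - sum(object$valid),
    n_nonphysical = attr(object, "n_nonphysical") %||% NA_integer_
  )
  class(out) <- "summary.phsi_stokes_cube"
  out
}

#' @export
print.summary.phsi_stokes_cube <- function(x, ...) {
  cat(sprintf("Stokes cube %s, %s\n", paste(x$dim, collapse = "x"),
              if (x$normalized) "normalized" else "un-normalized"))
  cat(sprintf("  valid pixels: %d; invalid: %d; non-physical retained: %s\n",
              x$n_valid, x$n_invalid, as.character(x$n_nonphysical)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
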