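#' Write a hyperspectral cube
#'
#' Two container formats are supported:
#' * **ENVI** (default): raw binary data file plus a plain-text `.hdr` header
#'   carrying the geometry, interleave, data type and the wavelength list.
#'   `float64` round-trips bit-exactly; `float32` rounds values once.
#' * **multi-page TIFF**: one 32-bit float page per band. Because the TIFF
#'   writer stores samples in `[0, 1]`, values are affinely mapped to that
#'   range; the offset/scale and the wavelength list live in a JSON sidecar
#'   (`<path>.json`) and the mapping is inverted on read.
#'
#' @param x Numeric array `[rows x cols x bands]`.
#' @param path Output path. For ENVI, `<path>.dat` and `<path>.hdr` are
#'   written (any `.hdr`/`.dat` extension given is stripped).
#' @param axis A [spectral_axis()] with `n_bands` matching the cube.
#' @param format `"envi"` or `"tiff"`; inferred from a `.tif`/`.tiff`
#'   extension when missing.
#' @param interleave ENVI interleave: `"bsq"` (default), `"bil"` or `"bip"`.
#' @param dtype ENVI element type: `"float64"` (default) or `"float32"`.
#' @return Invisibly, the data-file path.
#' @export
write_cube <- function(x, path, axis, format = NULL, interleave = "bsq",
                       dtype = c("float64", "float32")) {
  stopifnot(is.array(x), length(dim(x)) == 3L, inherits(axis, "phsi_axis"))
  if (dim(x)[3L] != axis$n_bands) {
    stop("cube band count does not match the spectral axis")
  }
  format <- format %||%
    (if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "envi")
  format <- match.arg(format, c("envi", "tiff"))
  if (format == "envi") {
    write_envi(x, path, axis, interleave = interleave,
               dtype = match.arg(dtype))
  } else {
    write_tiff_cube(x, path, axis)
  }
}

#' Read a hyperspectral cube
#'
#' Counterpart of [write_cube()]. Headers are validated against the data
#' (inconsistent band counts or file sizes are rejected, naming the offending
#' field); cubes stored with unsorted wavelengths are reordered ascending
#' with a warning.
#'
#' @param path Path to the ENVI header/data basename or the TIFF file.
#' @param format `"envi"` or `"tiff"`; inferred from the extension.
#' @return List with `cube` (`[rows x cols x bands]` array) and `axis`.
#' @export
read_cube <- function(path, format = NULL) {
  format <- format %||%
    (if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "envi")
  format <- match.arg(format, c("envi", "tiff"))
  if (format == "envi") read_envi(path) else read_tiff_cube(path)
}

envi_base <- function(path) sub("\\.(hdr|dat)$", "", path)

# interleave permutations: ENVI streams are written with the listed dimension
# order, last index fastest
interleave_perm <- list(
  bsq = c(3L, 1L, 2L),  # band, line, sample
  bil = c(1L, 3L, 2L),  # line, band, sample
  bip = c(1L, 2L, 3L)   # line, sample, band
)

write_envi <- function(x, path, axis, interleave = "bsq", dtype = "float64") {
  interleave <- match.arg(interleave, names(interleave_perm))
  size <- if (dtype == "float32") 4L else 8L
  base <- envi_base(path)
  d <- dim(x)
  # stream order: fastest index last in the permutation; R fills column-major
  # (first fastest), so write aperm with the order reversed
  perm <- rev(interleave_perm[[interleave]])
  con <- file(paste0(base, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(aperm(x, perm)), con, size = size)
  hdr <- c(
    "ENVI",
    sprintf("samples = %d", d[2L]),
    sprintf("lines = %d", d[1L]),
    sprintf("bands = %d", d[3L]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", if (dtype == "float32") 4L else 5L),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("wavelength = { %s }",
            paste(format(axis$wavelengths_nm, digits = 17), collapse = ", "))
  )
  writeLines(hdr, paste0(base, ".hdr"))
  invisible(paste0(base, ".dat"))
}

parse_envi_header <- function(path) {
  lines <- readLines(path, warn = FALSE)[-1L]
  entries <- list()
  # logical entries: key = value, with brace lists possibly spanning lines
  out <- character(0)
  depth <- 0L
  for (ln in lines) {
    if (depth > 0L) {
      out[length(out)] <- paste(out[length(out)], ln)
    } else {
      out <- c(out, ln)
    }
    chars <- strsplit(ln, "")[[1L]]
    depth <- max(depth + sum(chars == "{") - sum(chars == "}"), 0L)
  }
  for (ln in out) {
    if (!grepl("=", ln)) next
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    entries[[tolower(key)]] <- val
  }
  entries
}

read_envi <- function(path) {
  base <- envi_base(path)
  hdr_path <- paste0(base, ".hdr")
  dat_path <- paste0(base, ".dat")
  if (!file.exists(hdr_path)) stop(sprintf("ENVI header not found: %s", hdr_path))
  if (!file.exists(dat_path)) stop(sprintf("ENVI data file not found: %s", dat_path))
  h <- parse_envi_header(hdr_path)
  need_int <- function(key) {
    if (is.null(h[[key]])) stop(sprintf("ENVI header missing field '%s'", key))
    as.integer(h[[key]])
  }
  samples <- need_int("samples")
  lines_n <- need_int("lines")
  bands <- need_int("bands")
  dtype_code <- need_int("data type")
  if (!dtype_code %in% c(4L, 5L)) {
    stop(sprintf("unsupported ENVI data type %d (field 'data type')", dtype_code))
  }
  size <- if (dtype_code == 4L) 4L else 8L
  interleave <- tolower(h[["interleave"]] %||% "bsq")
  if (!interleave %in% names(interleave_perm)) {
    stop(sprintf("unsupported interleave '%s' (field 'interleave')", interleave))
  }
  n <- samples * lines_n * bands
  actual <- file.info(dat_path)$size
  if (actual != n * size) {
    stop(sprintf(
      "ENVI data size %d bytes does not match samples x lines x bands (field 'bands'): expected %d",
      actual, n * size))
  }
  if (is.null(h[["wavelength"]])) {
    stop("ENVI header missing field 'wavelength'")
  }
  w <- as.numeric(strsplit(gsub("[{}]", "", h[["wavelength"]]), ",")[[1L]])
  if (length(w) != bands) {
    stop(sprintf("ENVI field 'wavelength' has %d entries but 'bands' = %d",
                 length(w), bands))
  }
  con <- file(dat_path, "rb")
  on.exit(close(con))
  raw_vals <- readBin(con, "numeric", n = n, size = size)
  perm <- rev(interleave_perm[[interleave]])
  cube <- aperm(array(raw_vals, dim = c(lines_n, samples, bands)[perm]),
                order(perm))
  ord <- order(w)
  if (any(diff(w) <= 0)) {
    warning("wavelengths not strictly increasing; reordering bands", call. = FALSE)
    w <- w[ord]
    cube <- cube[, , ord, drop = FALSE]
  }
  list(cube = cube, axis = spectral_axis(w))
}

write_tiff_cube <- function(x, path, axis) {
  fin <- x[is.finite(x)]
  lo <- if (length(fin)) min(fin) else 0
  hi <- if (length(fin)) max(fin) else 1
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(x)[3L]), function(b) {
    m <- (x[, , b] - lo) / scale
    m[!is.finite(m)] <- 0
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(wavelengths_nm = axis$wavelengths_nm, offset = lo, scale = scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_tiff_cube <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) {
    stop(sprintf("wavelength sidecar not found: %s", side))
  }
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  w <- as.numeric(meta$wavelengths_nm)
  if (length(pages) != length(w)) {
    stop(sprintf("TIFF has %d pages but sidecar lists %d wavelengths",
                 length(pages), length(w)))
  }
  cube <- array(unlist(pages), dim = c(dim(pages[[1L]]), length(pages)))
  cube <- cube * meta$scale + meta$offset
  ord <- order(w)
  if (any(diff(w) <= 0)) {
    warning("wavelengths not strictly increasing; reordering bands", call. = FALSE)
    w <- w[ord]
    cube <- cube[, , ord, drop = FALSE]
  }
  list(cube = cube, axis = spectral_axis(w))
}

#' Read / write a binary ROI mask
#'
#' Masks are stored as PNG (or TIFF) images; any nonzero pixel is `TRUE`.
#' Multichannel images are collapsed with a per-pixel maximum over the color
#' channels. An all-zero mask is rejected (empty ROI).
#'
#' @param path Image file path (`.png`, `.tif`, `.tiff`).
#' @param label ROI label passed to [roi_mask()].
#' @return A [roi_mask()].
#' @export
read_mask <- function(path, label = "other") {
  img <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 3L) {
    ch <- seq_len(min(3L, dim(img)[3L]))  # drop alpha
    img <- apply(img[, , ch, drop = FALSE], c(1, 2), max)
  }
  roi_mask(img > 0, label = label)
}

#' @rdname read_mask
#' @param mask Logical matrix or [roi_mask()].
#' @return `write_mask()`: invisibly, the path.
#' @export
write_mask <- function(mask, path) {
  m <- unclass(mask) != 0
  png::writePNG(m * 1.0, path)
  invisible(path)
}

element_names <- c("ih", "iv", "i45", "irc")

#' Write / read an element-image set as a directory of cubes
#'
#' The four cubes are stored in one directory under the fixed basenames
#' `ih`, `iv`, `i45`, `irc` (plus the format's own sidecars).
#'
#' @param images A [element_image_set()].
#' @param dir Directory (created if missing).
#' @param format,interleave,dtype Passed to [write_cube()].
#' @return Invisibly, `dir`.
#' @export
write_element_images <- function(images, dir, format = "envi",
                                 interleave = "bsq", dtype = "float64") {
  stopifnot(inherits(images, "phsi_element_images"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "tiff") ".tif" else ""
  for (nm in element_names) {
    write_cube(images[[nm]], file.path(dir, paste0(nm, ext)), images$axis,
               format = format, interleave = interleave, dtype = dtype)
  }
  invisible(dir)
}

#' @rdname write_element_images
#' @return `read_element_images()`: a [element_image_set()].
#' @export
read_element_images <- function(dir) {
  read_one <- function(nm) {
    if (file.exists(file.path(dir, paste0(nm, ".hdr")))) {
      read_cube(file.path(dir, nm), format = "envi")
    } else if (file.exists(file.path(dir, paste0(nm, ".tif")))) {
      read_cube(file.path(dir, paste0(nm, ".tif")), format = "tiff")
    } else {
      stop(sprintf("element cube '%s' not found in %s", nm, dir))
    }
  }
  cubes <- lapply(element_names, read_one)
  element_image_set(cubes[[1L]]$cube, cubes[[2L]]$cube, cubes[[3L]]$cube,
                    cubes[[4L]]$cube, cubes[[1L]]$axis)
}

#' Write / read a calibration sweep as `angle_<deg>` subdirectories
#'
#' @param sweep Named list of element-image sets keyed by angle.
#' @param dir Sweep directory.
#' @param ... Passed to [write_element_images()].
#' @return Invisibly, `dir`.
#' @export
write_qwp_sweep <- function(sweep, dir, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (key in names(sweep)) {
    ang <- sub("^angle_", "", key)
    write_element_images(sweep[[key]], file.path(dir, paste0("angle_", ang)),
                         ...)
  }
  invisible(dir)
}

#' @rdname write_qwp_sweep
#' @return `read_qwp_sweep()`: named list of element-image sets.
#' @export
read_qwp_sweep <- function(dir) {
  sub_dirs <- list.dirs(dir, recursive = FALSE)
  sub_dirs <- sub_dirs[grepl("^angle_", basename(sub_dirs))]
  if (length(sub_dirs) == 0L) {
    stop(sprintf("no angle_<deg> subdirectories found in %s", dir))
  }
  sets <- lapply(sub_dirs, read_element_images)
  names(sets) <- sub("^angle_", "", basename(sub_dirs))
  sets[order(as.numeric(names(sets)))]
}

#' Write / read a run-configuration snapshot
#'
#' Run configurations are plain YAML lists (spectral axis, phantom and noise
#' parameters, seeds, output options). Every CLI run writes one alongside its
#' outputs so the run can be reproduced exactly.
#'
#' @param config Named list.
#' @param path YAML file path.
#' @return Invisibly, `path`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @return `read_run_config()`: the configuration list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}
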