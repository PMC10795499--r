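#' GLCM contrast of a single-channel image
#'
#' Quantizes the image to `n_levels` gray levels, builds the co-occurrence
#' probability matrix `p(i, j)` over the configured pixel offsets, and
#' returns
#' \deqn{\mathrm{Contrast} = \sum_{i,j} r(i,j)^2 \, p(i,j),\qquad
#'       r(i,j) = \frac{|i - j|}{n_\mathrm{levels} - 1},}
#' the squared gray-level difference of adjacent pixel pairs weighted by
#' their probability. The level difference is normalized by the level range
#' so a full-range image scores in `[0, 1]`: a constant image scores 0 and a
#' two-level checkerboard scores 1 along an offset where all pairs differ.
#'
#' @param image Numeric matrix with finite values in `[0, 1]` (`NA` marks
#'   excluded pixels; pairs touching an `NA` are dropped).
#' @param n_levels Number of gray levels (`>= 2`); default 8.
#' @param offsets List of `c(row, col)` displacements; contrast is averaged
#'   over offsets. Default: the four standard neighbors
#'   `(0,1), (1,0), (1,1), (1,-1)`.
#' @param symmetric Count each pair in both orders (default `TRUE`; contrast
#'   is unchanged, but the co-occurrence matrix is symmetric).
#' @return Scalar contrast in `[0, 1]`.
#' @examples
#' glcm_contrast(matrix(0.5, 8, 8))  # 0
#' cb <- outer(1:8, 1:8, function(r, c) (r + c) %% 2)
#' glcm_contrast(cb, n_levels = 2, offsets = list(c(0, 1)))  # 1
#' @export
glcm_contrast <- function(image, n_levels = 8L,
                          offsets = list(c(0L, 1L), c(1L, 0L),
                                         c(1L, 1L), c(1L, -1L)),
                          symmetric = TRUE) {
  stopifnot(is.matrix(image), is.numeric(image), n_levels >= 2L)
  fin <- image[is.finite(image)]
  if (length(fin) && (min(fin) < -1e-9 || max(fin) > 1 + 1e-9)) {
    stop("image values must lie in [0, 1]")
  }
  n_levels <- as.integer(n_levels)
  lev <- floor(pmin(pmax(image, 0), 1) * n_levels)
  lev[lev == n_levels] <- n_levels - 1L
  lev[!is.finite(image)] <- NA_integer_
  nr <- nrow(image); nc <- ncol(image)

  per_offset <- vapply(offsets, function(off) {
    dr <- as.integer(off[1L]); dc <- as.integer(off[2L])
    if (dr == 0L && dc == 0L) stop("offsets must be nonzero")
    r0 <- max(1L, 1L - dr); r1 <- min(nr, nr - dr)
    c0 <- max(1L, 1L - dc); c1 <- min(nc, nc - dc)
    if (r0 > r1 || c0 > c1) {
      stop(sprintf("image is smaller than offset (%d, %d)", dr, dc))
    }
    a <- lev[r0:r1, c0:c1, drop = FALSE]
    b <- lev[(r0 + dr):(r1 + dr), (c0 + dc):(c1 + dc), drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) stop("no valid pixel pair for offset")
    da <- a[ok]; db <- b[ok]
    # symmetric counting doubles every pair, leaving probabilities (and
    # contrast) unchanged; integer sums keep the ratio exact
    d <- da - db
    sum(d * d) / (length(d) * (n_levels - 1)^2)
  }, numeric(1))
  mean(per_offset)
}

#' Collapse an RGB image to a luminance channel
#'
#' @param image A `phsi_rgb` or `[rows x cols x 3]` array in `[0, 1]`.
#' @param weights Channel weights; normalized to unit sum. Default Rec. 601
#'   luminance `(0.299, 0.587, 0.114)`.
#' @return Numeric matrix in `[0, 1]`.
#' @export
rgb_to_gray <- function(image, weights = c(0.299, 0.587, 0.114)) {
  stopifnot(is.array(image), length(dim(image)) == 3L, dim(image)[3L] == 3L,
            length(weights) == 3L, all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)
  m <- unclass(image)
  m[, , 1L] * w[1L] + m[, , 2L] * w[2L] + m[, , 3L] * w[3L]
}

#' Region-of-interest mask
#'
#' @param mask Logical (or 0/1 numeric) matrix; `TRUE`/nonzero marks ROI
#'   pixels. At least one pixel must be set.
#' @param label ROI class label: `"collagen"`, `"normal_cell"`,
#'   `"tumor_cell"` or `"other"`.
#' @return A `phsi_roi_mask` (logical matrix with a `label` attribute).
#' @export
roi_mask <- function(mask, label = c("other", "collagen", "normal_cell",
                                     "tumor_cell")) {
  label <- match.arg(label)
  stopifnot(is.matrix(mask))
  m <- mask != 0 & !is.na(mask)
  if (!any(m)) stop("ROI mask is empty")
  structure(m, class = "phsi_roi_mask", label = label)
}

#' Per-band mean and standard deviation over an ROI
#'
#' Summarizes one Stokes parameter over the masked pixels, band by band.
#' Pixels flagged invalid during normalization are excluded; the standard
#' deviation uses the population convention (divide by `n`). Because the four
#' Stokes cubes share one field of view, the same mask applies to any
#' parameter.
#'
#' @param cube A `phsi_stokes_cube`.
#' @param mask A [roi_mask()] or logical matrix matching the cube's spatial
#'   shape.
#' @param parameter `"s0"`, `"s1"`, `"s2"` or `"s3"`.
#' @return A `phsi_spectral_summary` data frame with columns `band`,
#'   `wavelength_nm`, `mean`, `sd`, `n_pixels`, and attributes `parameter`
#'   and `label`.
#' @export
extract_roi_spectra <- function(cube, mask, parameter = "s0") {
  stopifnot(inherits(cube, "phsi_stokes_cube"))
  parameter <- tolower(parameter)
  stopifnot(parameter %in% c("s0", "s1", "s2", "s3"))
  label <- if (inherits(mask, "phsi_roi_mask")) attr(mask, "label") else "other"
  m <- unclass(mask) != 0
  d <- dim(cube$s0)
  if (!is.matrix(m) || !identical(dim(m), d[1:2])) {
    stop("mask shape must match the cube's spatial shape")
  }
  x <- cube[[parameter]]
  sel <- which(m)
  if (length(sel) == 0L) stop("ROI mask is empty")
  stats_band <- vapply(seq_len(d[3L]), function(b) {
    vals <- x[sel + (b - 1L) * prod(d[1:2])]
    ok <- cube$valid[sel + (b - 1L) * prod(d[1:2])] & is.finite(vals)
    vals <- vals[ok]
    if (length(vals) == 0L) return(c(NA_real_, NA_real_, 0))
    mu <- mean(vals)
    c(mu, sqrt(mean((vals - mu)^2)), length(vals))
  }, numeric(3))
  if (all(stats_band[3L, ] == 0)) {
    stop("ROI mask has no valid pixels")
  }
  out <- data.frame(
    band = seq_len(d[3L]),
    wavelength_nm = cube$axis$wavelengths_nm,
    mean = stats_band[1L, ],
    sd = stats_band[2L, ],
    n_pixels = as.integer(stats_band[3L, ])
  )
  structure(out, class = c("phsi_spectral_summary", "data.frame"),
            parameter = parameter, label = label)
}

as_spectra_matrix <- function(group) {
  if (is.matrix(group)) return(group)
  if (is.data.frame(group)) return(as.matrix(group))
  if (is.list(group)) {
    rows <- lapply(group, function(g) {
      if (inherits(g, "phsi_spectral_summary")) g$mean else as.numeric(g)
    })
    n <- unique(vapply(rows, length, integer(1)))
    if (length(n) != 1L) stop("group spectra have unequal band counts")
    return(do.call(rbind, rows))
  }
  stop("group must be a matrix, data frame, or list of spectra")
}

#' Per-band two-sample comparison of ROI-average spectra
#'
#' For every band, a two-sample t test between the groups' per-ROI average
#' values (Welch's unequal-variance test by default; set `var_equal = TRUE`
#' for Student's pooled test). Raw p values are reported; a
#' Benjamini-Hochberg column is added when `adjust = TRUE`. When both groups
#' are constant at a band (zero variance) the test is undefined; `p = 1` and
#' `t = 0` are reported there with a note.
#'
#' @param group_a,group_b Matrices (one row per ROI, one column per band),
#'   data frames, or lists of per-ROI mean spectra /
#'   [extract_roi_spectra()] summaries. Each group needs at least 2 rows.
#' @param wavelengths_nm Optional band-center wavelengths for the output.
#' @param var_equal Use the pooled-variance (Student) test instead of Welch.
#' @param adjust Add a `p_bh` Benjamini-Hochberg adjusted column.
#' @return A `phsi_band_test` data frame with columns `band`
#'   (`wavelength_nm` when supplied), `t`, `df`, `p`, `n_a`, `n_b`.
#' @export
per_band_ttest <- function(group_a, group_b, wavelengths_nm = NULL,
                           var_equal = FALSE, adjust = FALSE) {
  a <- as_spectra_matrix(group_a)
  b <- as_spectra_matrix(group_b)
  if (nrow(a) < 2L || nrow(b) < 2L) {
    stop("each group needs at least 2 spectra")
  }
  if (ncol(a) != ncol(b)) {
    stop("groups must share one band grid")
  }
  nb <- ncol(a)
  if (!is.null(wavelengths_nm)) stopifnot(length(wavelengths_nm) == nb)
  t_stat <- df <- p <- numeric(nb)
  degenerate <- 0L
  for (j in seq_len(nb)) {
    res <- tryCatch(
      stats::t.test(a[, j], b[, j], var.equal = var_equal),
      error = function(e) NULL
    )
    if (is.null(res)) {  # constant data: test undefined
      t_stat[j] <- 0; df[j] <- NA_real_; p[j] <- 1
      degenerate <- degenerate + 1L
    } else {
      t_stat[j] <- unname(res$statistic)
      df[j] <- unname(res$parameter)
      p[j] <- res$p.value
    }
  }
  if (degenerate > 0L) {
    message(sprintf(
      "per_band_ttest: %d band(s) with zero variance in both groups; p = 1 reported",
      degenerate))
  }
  out <- data.frame(band = seq_len(nb))
  if (!is.null(wavelengths_nm)) out$wavelength_nm <- wavelengths_nm
  out$t <- t_stat; out$df <- df; out$p <- p
  out$n_a <- nrow(a); out$n_b <- nrow(b)
  if (adjust) out$p_bh <- stats::p.adjust(p, method = "BH")
  structure(out, class = c("phsi_band_test", "data.frame"),
            variant = if (var_equal) "student" else "welch")
}
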