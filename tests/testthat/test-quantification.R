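test_that("GLCM contrast anchors: constant image and full-range checkerboard", {
  expect_equal(glcm_contrast(matrix(0.4, 8, 8)), 0)
  cb <- outer(1:8, 1:8, function(r, c) (r + c) %% 2)
  expect_equal(glcm_contrast(cb, n_levels = 2, offsets = list(c(0L, 1L))), 1)
  # averaged over the 4 standard neighbors the diagonals contribute 0
  expect_equal(glcm_contrast(cb, n_levels = 2), 0.5)
})

test_that("GLCM contrast equals brute-force pair enumeration on random images", {
  set.seed(2024)
  for (i in 1:50) {
    img <- matrix(stats::runif(64), 8, 8)
    n_levels <- sample(c(2L, 4L, 8L), 1)
    offs <- sample(list(list(c(0L, 1L)), list(c(1L, 0L), c(1L, 1L)),
                        list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))), 1)[[1]]
    expect_identical(glcm_contrast(img, n_levels = n_levels, offsets = offs),
                     brute_glcm(img, n_levels = n_levels, offsets = offs))
  }
})

test_that("GLCM contrast is invariant to gray-level inversion and rejects bad input", {
  set.seed(5)
  img <- matrix(stats::runif(100), 10, 10)
  expect_equal(glcm_contrast(img), glcm_contrast(1 - img), tolerance = 1e-12)
  expect_error(glcm_contrast(matrix(2, 4, 4)), "\\[0, 1\\]")
  expect_error(glcm_contrast(matrix(0.5, 1, 2), offsets = list(c(3L, 0L))),
               "smaller than offset")
  # NA pixels drop their pairs but do not break the estimate
  img[3, ] <- NA
  expect_true(is.finite(glcm_contrast(img)))
})

test_that("luminance collapse behaves on pure and gray inputs", {
  mk <- function(v) array(rep(v, each = 4), c(2, 2, 3))
  expect_equal(rgb_to_gray(mk(c(1, 1, 1))), matrix(1, 2, 2))
  expect_equal(rgb_to_gray(mk(c(0, 0, 0))), matrix(0, 2, 2))
  expect_equal(rgb_to_gray(mk(c(0.3, 0.3, 0.3))), matrix(0.3, 2, 2),
               tolerance = 1e-12)
})

test_that("ROI spectra give per-band means with the population-sd convention", {
  ax <- tiny_axis(3)
  arr <- array(0, c(2, 2, 3))
  arr[1, 1, ] <- c(1, 2, 3)
  arr[2, 2, ] <- c(3, 4, 7)
  st <- stokes_cube(array(1, c(2, 2, 3)), arr, arr, arr, ax,
                    normalized = TRUE)
  one <- matrix(FALSE, 2, 2); one[1, 1] <- TRUE
  s1 <- extract_roi_spectra(st, roi_mask(one), "s1")
  expect_equal(s1$mean, c(1, 2, 3))
  expect_equal(s1$sd, c(0, 0, 0))
  expect_equal(s1$n_pixels, rep(1L, 3))

  two <- one; two[2, 2] <- TRUE
  s2 <- extract_roi_spectra(st, roi_mask(two), "s1")
  expect_equal(s2$mean, c(2, 3, 5))
  expect_equal(s2$sd, c(1, 1, 2))  # |a - b| / 2

  all_mask <- matrix(TRUE, 2, 2)
  s_all <- extract_roi_spectra(st, roi_mask(all_mask), "s1")
  expect_equal(s_all$mean, apply(arr, 3, mean))
})

test_that("ROI spectra exclude invalid pixels and are linear in the cube", {
  ax <- tiny_axis(2)
  set.seed(10)
  s1 <- array(stats::runif(16 * 2), c(4, 4, 2))
  valid <- array(TRUE, c(4, 4, 2)); valid[1, 1, ] <- FALSE
  mk <- function(x) stokes_cube(array(1, c(4, 4, 2)), x, x, x, ax,
                                normalized = TRUE, valid = valid)
  mask <- roi_mask(matrix(TRUE, 4, 4))
  a <- extract_roi_spectra(mk(s1), mask, "s1")
  expect_equal(a$n_pixels, rep(15L, 2))
  b <- extract_roi_spectra(mk(3 * s1), mask, "s1")
  expect_equal(b$mean, 3 * a$mean, tolerance = 1e-12)
  # fully invalid ROI is rejected
  bad <- matrix(FALSE, 4, 4); bad[1, 1] <- TRUE
  expect_error(extract_roi_spectra(mk(s1), roi_mask(bad), "s1"), "valid")
  expect_error(roi_mask(matrix(FALSE, 4, 4)), "empty")
})

test_that("per-band t test matches direct computation and handles edge cases", {
  set.seed(6)
  a <- matrix(stats::rnorm(5 * 4), 5, 4)
  b <- matrix(stats::rnorm(5 * 4), 5, 4)
  res <- per_band_ttest(a, b)
  expect_true(all(res$p >= 0 & res$p <= 1))
  # closed-form Welch t at band 1
  se <- sqrt(stats::var(a[, 1]) / 5 + stats::var(b[, 1]) / 5)
  expect_equal(res$t[1], (mean(a[, 1]) - mean(b[, 1])) / se,
               tolerance = 1e-12)

  same <- per_band_ttest(a, a)
  expect_true(all(same$t == 0))
  expect_true(all(same$p == 1))

  # zero variance in both groups: p reported as 1 with a note
  ca <- matrix(1, 3, 2); cb <- matrix(2, 3, 2)
  expect_message(zres <- per_band_ttest(ca, cb), "zero variance")
  expect_true(all(zres$p == 1))

  expect_error(per_band_ttest(a[1, , drop = FALSE], b), "at least 2")
  expect_error(per_band_ttest(a, b[, 1:3]), "band grid")
})

test_that("a strong single-band shift is detected with small groups", {
  set.seed(9)
  a <- matrix(stats::rnorm(5 * 6), 5, 6)
  b <- matrix(stats::rnorm(5 * 6), 5, 6)
  b[, 3] <- b[, 3] + 10  # ten pooled standard deviations
  res <- per_band_ttest(a, b, adjust = TRUE)
  expect_lt(res$p[3], 0.05)
  expect_equal(which.min(res$p), 3L)
  expect_true(all(res$p_bh >= res$p))
})

test_that("retardance-only group differences surface in S3, not S0", {
  ax <- tiny_axis(4)
  shape <- c(16L, 16L)
  # one cell per field; the two groups differ only in nucleus retardance
  cell_spectra <- function(ret, s) {
    p <- cell_phantom_params(n_cells = 1, nucleus_radius_px = 4,
                             cytoplasm_radius_px = 6,
                             nucleus_retardance_rad = ret,
                             nucleus_fast_axis_deg = 0)
    scn <- make_cell_scene(p, shape, ax, seed = s)
    raw <- compute_stokes(simulate_acquisition(
      scn, noise = noise_spec(seed = s + 5000)))
    mask <- roi_mask(scn$labels > 0)
    list(s0 = extract_roi_spectra(raw, mask, "s0")$mean,
         s3 = extract_roi_spectra(normalize_stokes(raw), mask, "s3")$mean)
  }
  run_group <- function(ret, seeds) lapply(seeds, cell_spectra, ret = ret)
  pick <- function(g, nm) do.call(rbind, lapply(g, `[[`, nm))
  p3_wins <- vapply(1:10, function(rep) {
    ga <- run_group(0.02, rep * 100 + 1:8)
    gb <- run_group(0.5, rep * 100 + 51:58)
    p_s3 <- per_band_ttest(pick(ga, "s3"), pick(gb, "s3"))$p
    p_s0 <- per_band_ttest(pick(ga, "s0"), pick(gb, "s0"))$p
    stats::median(p_s3) < stats::median(p_s0)
  }, logical(1))
  expect_gte(sum(p3_wins), 8)
})
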