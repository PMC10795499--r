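test_that("quarter-wave-plate scenes are uniform with the requested retarder", {
  ax <- tiny_axis(3)
  scn <- make_qwp_scene(30, c(2L, 3L), ax)
  m11 <- scene_mueller(scn, 1, 1)
  m23 <- scene_mueller(scn, 2, 3)
  expect_identical(m11, m23)
  expect_equal(m11, oracle_retarder(30, pi / 2), tolerance = 1e-12)
})

test_that("QWP scene exits match theory at the anchor angles", {
  ax <- tiny_axis(3)
  illum <- illumination_spec(ax, spectrum = rep(2, 3))  # unit input after 0.5
  # fast axis 0: +45 input -> (1, 0, 0, -1) per unit
  ex0 <- scene_exit_stokes(make_qwp_scene(0, c(2L, 2L), ax), illum)
  expect_equal(ex0[1, 1, 1, ], c(1, 0, 0, -1), tolerance = 1e-12)
  # fast axis 45: parallel to input polarization, light unchanged
  ex45 <- scene_exit_stokes(make_qwp_scene(45, c(2L, 2L), ax), illum)
  expect_equal(ex45[2, 2, 2, ], c(1, 0, 1, 0), tolerance = 1e-12)
})

test_that("dispersive QWP is exactly quarter-wave only at the reference band", {
  ax <- tiny_axis(5)
  scn <- make_qwp_scene(0, c(1L, 1L), ax, dispersion = "inverse_wavelength",
                        reference_nm = 610)
  ref_band <- which(ax$wavelengths_nm == 610)
  expect_equal(scene_mueller(scn, 1, 1, band = ref_band),
               oracle_retarder(0, pi / 2), tolerance = 1e-12)
  other <- scene_mueller(scn, 1, 1, band = 1L)
  expect_gt(max(abs(other - oracle_retarder(0, pi / 2))), 1e-3)
})

test_that("zero-retardance fibers leave no polarization signature", {
  ax <- tiny_axis(3)
  params <- fiber_phantom_params(retardance_max_rad = 0,
                                 background_transmittance = 0.8,
                                 fiber_transmittance = 0.5)
  scn <- make_fiber_scene(params, c(24L, 24L), ax, seed = 4)
  st <- normalize_stokes(compute_stokes(
    simulate_acquisition(scn, noise = noise_spec("none"))))
  expect_lt(max(abs(st$s1)), 1e-12)
  expect_lt(max(abs(st$s2 - 1)), 1e-12)
  expect_lt(max(abs(st$s3)), 1e-12)
})

test_that("matched-transmittance fibers are invisible in S0 but not in S1..S3", {
  ax <- tiny_axis(3)
  params <- fiber_phantom_params(retardance_max_rad = 0.8)
  scn <- make_fiber_scene(params, c(32L, 32L), ax, seed = 1)
  expect_gt(sum(scn$labels), 0)  # some fiber pixels landed
  st <- compute_stokes(simulate_acquisition(scn, noise = noise_spec("none")))
  s0_spread <- max(apply(st$s0, 3, function(m) diff(range(m))))
  expect_lt(s0_spread / max(st$s0), 1e-12)
  nn <- normalize_stokes(st)
  expect_gt(diff(range(nn$s2)), 0.01)
  expect_gt(diff(range(nn$s3)), 0.01)
})

test_that("fiber scenes are reproducible under a seed", {
  ax <- tiny_axis(2)
  p <- fiber_phantom_params()
  a <- make_fiber_scene(p, c(16L, 16L), ax, seed = 9)
  b <- make_fiber_scene(p, c(16L, 16L), ax, seed = 9)
  d <- make_fiber_scene(p, c(16L, 16L), ax, seed = 10)
  expect_identical(a$mueller, b$mueller)
  expect_false(identical(a$mueller, d$mueller))
})

test_that("cell phantom geometry follows its contracts", {
  ax <- tiny_axis(3)
  # zero cells -> clear (background attenuation only)
  scn0 <- make_cell_scene(cell_phantom_params(n_cells = 0), c(8L, 8L), ax,
                          seed = 0)
  expect_equal(scene_mueller(scn0, 3, 3, 2), 0.96 * diag(4),
               tolerance = 1e-12)
  # opaque nucleus: S0 = 0 inside
  p1 <- cell_phantom_params(n_cells = 1,
                            nucleus_absorbance_spectrum = rep(1, 3))
  scn1 <- make_cell_scene(p1, c(16L, 16L), ax, seed = 2)
  expect_gt(sum(scn1$labels > 0), 0)
  st <- compute_stokes(simulate_acquisition(scn1, noise = noise_spec("none")))
  inside <- which(scn1$labels > 0, arr.ind = TRUE)[1, ]
  expect_equal(st$s0[inside[1], inside[2], 1], 0, tolerance = 1e-15)
  expect_gt(st$s0[1, 1, 1], 0)
})

test_that("fragmented nuclei form several disjoint lobes", {
  ax <- tiny_axis(2)
  p <- cell_phantom_params(n_cells = 3, fragmentation = TRUE,
                           nucleus_radius_px = 4, cytoplasm_radius_px = 9)
  scn <- make_cell_scene(p, c(48L, 48L), ax, seed = 21)
  for (i in 1:3) {
    if (any(scn$labels == i)) {
      expect_gt(count_components(scn$labels == i), 1L)
    }
  }
  # reproducibility
  scn_b <- make_cell_scene(p, c(48L, 48L), ax, seed = 21)
  expect_identical(scn$mueller, scn_b$mueller)
})

test_that("scenes with over-polarizing matrices are rejected", {
  ax <- tiny_axis(2)
  bad <- diag(c(1, 1.5, 0, 0))
  flat <- array(rep(c(bad), each = 4), dim = c(2L, 2L, 4L, 4L))
  expect_error(scene(flat, ax), "non-passive")
})
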