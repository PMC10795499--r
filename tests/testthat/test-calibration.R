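test_that("theoretical QWP curves match their closed form", {
  expect_equal(unname(theoretical_qwp_stokes(0)), c(0, 0, -1))
  expect_equal(unname(theoretical_qwp_stokes(45)), c(0, 1, 0),
               tolerance = 1e-15)
  expect_equal(unname(theoretical_qwp_stokes(30)),
               c(0.4330127018922193, 0.75, -0.5), tolerance = 1e-12)
})

test_that("rmse is the mean-normalized root error with the expected edge cases", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, 2, 3) + 0.25, c(1, 2, 3)), 0.25)
  expect_equal(rmse(c(0.1, -0.2), c(0, 0)), sqrt(0.025))
  expect_error(rmse(1:3, 1:4), "equal length")
})

test_that("rmse is symmetric and invariant to joint reordering", {
  set.seed(2)
  a <- stats::rnorm(10)
  b <- stats::rnorm(10)
  expect_equal(rmse(a, b), rmse(b, a))
  perm <- sample(10)
  expect_equal(rmse(a[perm], b[perm]), rmse(a, b))
})

test_that("a noiseless sweep interpolates the theoretical curves exactly", {
  ax <- tiny_axis(5)
  protocol <- calibration_protocol(wavelengths_nm = c(470, 610, 750))
  sweep <- simulate_qwp_sweep(protocol, shape = c(8L, 8L), axis = ax,
                              noise = noise_spec("none"), seed = NULL)
  cal <- run_calibration(sweep, protocol)
  expect_equal(nrow(cal$rmse), 9L)
  expect_true(all(cal$rmse$rmse <= 1e-10))
  expect_lt(max(abs(cal$curves$experimental - cal$curves$theoretical)), 1e-10)
})

test_that("a systematic 5-degree plate offset gives equal nonzero RMSE across bands", {
  ax <- tiny_axis(5)
  protocol <- calibration_protocol(wavelengths_nm = c(470, 610, 750))
  sweep <- simulate_qwp_sweep(protocol, shape = c(4L, 4L), axis = ax,
                              noise = noise_spec("none"), seed = NULL,
                              angle_offset_deg = 5)
  cal <- run_calibration(sweep, protocol)
  expect_true(all(cal$rmse$rmse > 0.01))
  for (p in c("S1", "S2", "S3")) {
    v <- cal$rmse$rmse[cal$rmse$parameter == p]
    expect_lt(diff(range(v)), 1e-10)  # achromatic plate: same at all bands
  }
  # oracle: RMSE equals the direct Eq-2 shifted-vs-nominal discrepancy
  th_nom <- theoretical_qwp_stokes(protocol$angles_deg)
  th_off <- theoretical_qwp_stokes(protocol$angles_deg + 5)
  for (p in 1:3) {
    expect_equal(cal$rmse$rmse[cal$rmse$parameter == c("S1", "S2", "S3")[p]][1],
                 rmse(th_off[, p], th_nom[, p]), tolerance = 1e-10)
  }
})

test_that("a missing sweep angle is rejected naming the angle", {
  ax <- tiny_axis(3)
  protocol <- calibration_protocol(angles_deg = c(0, 90),
                                   wavelengths_nm = 470)
  sweep <- simulate_qwp_sweep(protocol, shape = c(2L, 2L), axis = ax,
                              noise = noise_spec("none"), seed = NULL)
  expect_error(run_calibration(sweep["0"], protocol), "90")
})

test_that("calibration RMSE grows monotonically with Gaussian noise scale", {
  ax <- tiny_axis(5)
  protocol <- calibration_protocol(wavelengths_nm = c(470, 610, 750))
  sigmas <- c(0, 1e-3, 1e-2, 1e-1)
  mean_rmse <- vapply(seq_along(sigmas), function(i) {
    vals <- vapply(1:5, function(s) {
      sweep <- simulate_qwp_sweep(
        protocol, shape = c(8L, 8L), axis = ax,
        noise = noise_spec("gaussian", read_sigma = sigmas[i]),
        seed = 100 * i + s)
      max(run_calibration(sweep, protocol)$rmse$rmse)
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(mean_rmse) > 0))
})

test_that("reporting wavelengths snap to the nearest band with a warning", {
  ax <- coarse_spectral_axis()  # no 525 nm band on the 14 nm grid
  protocol <- calibration_protocol(angles_deg = c(0, 45, 90),
                                   wavelengths_nm = 525)
  sweep <- simulate_qwp_sweep(protocol, shape = c(2L, 2L), axis = ax,
                              noise = noise_spec("none"), seed = NULL)
  expect_warning(cal <- run_calibration(sweep, protocol), "snapping")
  expect_equal(unique(cal$rmse$wavelength_nm), 526)
})

test_that("sweep simulation is reproducible under one seed", {
  ax <- tiny_axis(2)
  protocol <- calibration_protocol(angles_deg = c(0, 40, 90),
                                   wavelengths_nm = 470)
  a <- simulate_qwp_sweep(protocol, c(4L, 4L), ax, seed = 5)
  b <- simulate_qwp_sweep(protocol, c(4L, 4L), ax, seed = 5)
  expect_identical(a[["40"]]$ih, b[["40"]]$ih)
  # noise differs between angles (independent draws from one stream)
  expect_false(identical(a[["0"]]$ih, a[["90"]]$ih))
})
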