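test_that("compute_stokes reproduces canonical pure states", {
  ax <- spectral_axis(550)
  cases <- list(
    list(el = c(1, 0, 0.5, 0.5),   s = c(1, 1, 0, 0)),   # horizontal
    list(el = c(0.5, 0.5, 1, 0.5), s = c(1, 0, 1, 0)),   # +45 deg
    list(el = c(0.5, 0.5, 0.5, 1), s = c(1, 0, 0, 1))    # circular
  )
  for (cs in cases) {
    m <- function(v) matrix(v, 2, 2)
    st <- compute_stokes(element_image_set(m(cs$el[1]), m(cs$el[2]),
                                           m(cs$el[3]), m(cs$el[4]), ax))
    expect_equal(c(st$s0[1, 1, 1], st$s1[1, 1, 1],
                   st$s2[1, 1, 1], st$s3[1, 1, 1]), cs$s)
    expect_false(st$normalized)
  }
})

test_that("shape mismatches are rejected naming the offending cube", {
  ax <- tiny_axis(3)
  a <- array(1, c(4, 4, 3))
  expect_error(element_image_set(a, a, array(1, c(4, 5, 3)), a, ax), "i45")
  expect_error(element_image_set(a, array(1, c(3, 4, 3)), a, a, ax), "iv")
})

test_that("normalization divides by S0 and masks degenerate pixels", {
  ax <- spectral_axis(550)
  m <- function(v) matrix(v, 2, 2)
  st <- compute_stokes(element_image_set(m(1.5), m(0.5), m(1), m(0), ax))
  # (s0, s1, s2, s3) = (2, 1, 0, -2)
  nn <- normalize_stokes(st, epsilon = 1e-9)
  expect_equal(nn$s0[1, 1, 1], 1)
  expect_equal(nn$s1[1, 1, 1], 0.5)
  expect_equal(nn$s2[1, 1, 1], 0)
  expect_equal(nn$s3[1, 1, 1], -1)
  expect_true(nn$normalized)
  expect_error(normalize_stokes(nn), "already normalized")

  # zero-intensity pixel: flagged invalid, never infinite
  ih <- m(0.5); ih[2, 2] <- 0
  iv <- m(0.5); iv[2, 2] <- 0
  st2 <- compute_stokes(element_image_set(ih, iv, m(0.5), m(0.5), ax))
  nn2 <- normalize_stokes(st2)
  expect_true(is.na(nn2$s1[2, 2, 1]))
  expect_false(nn2$valid[2, 2, 1])
  expect_true(all(is.finite(nn2$s1[nn2$valid])))
  expect_equal(attr(nn2, "n_invalid"), 1L)
})

test_that("Stokes reconstruction is linear in the element images", {
  ax <- tiny_axis(4)
  set.seed(31)
  arrs <- replicate(4, array(stats::runif(4 * 5 * 4), c(4, 5, 4)),
                    simplify = FALSE)
  imgs <- element_image_set(arrs[[1]], arrs[[2]], arrs[[3]], arrs[[4]], ax)
  a <- 2.7
  scaled <- element_image_set(a * arrs[[1]], a * arrs[[2]], a * arrs[[3]],
                              a * arrs[[4]], ax)
  st <- compute_stokes(imgs)
  st_a <- compute_stokes(scaled)
  for (nm in c("s0", "s1", "s2", "s3")) {
    expect_equal(st_a[[nm]], a * st[[nm]], tolerance = 1e-12)
  }
})

test_that("noiseless roundtrip recovers the sample-exit Stokes field exactly", {
  ax <- tiny_axis(3)
  set.seed(99)
  shape <- c(6L, 7L)
  # random passive scene built from oracle matrices (attenuator x retarder)
  flat <- array(0, dim = c(shape, 1L, 4L, 4L))
  truth <- array(0, dim = c(shape, 16L))
  for (r in seq_len(shape[1])) {
    for (cc in seq_len(shape[2])) {
      m <- stats::runif(1, 0.2, 1) *
        oracle_retarder(stats::runif(1, 0, 180), stats::runif(1, -pi, pi))
      flat[r, cc, 1, , ] <- m
      truth[r, cc, ] <- as.vector(m)
    }
  }
  scn <- scene(flat, ax, description = "random passive test scene")
  illum <- illumination_spec(ax)
  imgs <- simulate_acquisition(scn, illum, noise = noise_spec("none"))
  st <- compute_stokes(imgs)
  gpol <- 0.5 * c(1, 0, 1, 0)
  for (b in 1:3) {
    g <- gpol * illum$spectrum[b]
    for (r in seq_len(shape[1])) {
      for (cc in seq_len(shape[2])) {
        expected <- drop(matrix(truth[r, cc, ], 4, 4) %*% g)
        got <- c(st$s0[r, cc, b], st$s1[r, cc, b],
                 st$s2[r, cc, b], st$s3[r, cc, b])
        expect_lt(max(abs(got - expected)) / max(abs(expected), 1e-12), 1e-10)
      }
    }
  }
})

test_that("a clear scene normalizes to pure +45 light everywhere", {
  ax <- tiny_axis(4)
  shape <- c(5L, 5L)
  scn <- scene(array(rep(c(diag(4)), each = prod(shape)),
                     dim = c(shape, 4L, 4L)), ax, "clear")
  st <- normalize_stokes(compute_stokes(
    simulate_acquisition(scn, noise = noise_spec("none"))))
  expect_lt(max(abs(st$s1)), 1e-12)
  expect_lt(max(abs(st$s2 - 1)), 1e-12)
  expect_lt(max(abs(st$s3)), 1e-12)
})

test_that("non-physical pixels produced by noise are counted, not clipped", {
  ax <- spectral_axis(550)
  m <- function(v) matrix(v, 1, 1)
  # s0 = 0.1 but s1 = 0.3: over-polarized
  st <- compute_stokes(element_image_set(m(0.2), m(-0.1), m(0.05), m(0.05), ax))
  expect_equal(attr(st, "n_nonphysical"), 1L)
  expect_equal(st$s1[1, 1, 1], 0.3)  # value retained
})
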