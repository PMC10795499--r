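# Independent oracles for the Mueller/Stokes tests. These are built by a
# different route than the package (rotation-conjugation of the canonical
# frame matrices rather than closed-form entries), so agreement is a real
# cross-check.

rot_mueller <- function(theta_deg) {
  a <- 2 * theta_deg * pi / 180
  matrix(c(
    1, 0,       0,      0,
    0, cos(a),  sin(a), 0,
    0, -sin(a), cos(a), 0,
    0, 0,       0,      1
  ), 4, 4, byrow = TRUE)
}

oracle_retarder <- function(theta_deg, delta_rad) {
  d0 <- matrix(c(
    1, 0, 0,               0,
    0, 1, 0,               0,
    0, 0, cos(delta_rad),  sin(delta_rad),
    0, 0, -sin(delta_rad), cos(delta_rad)
  ), 4, 4, byrow = TRUE)
  rot_mueller(-theta_deg) %*% d0 %*% rot_mueller(theta_deg)
}

oracle_polarizer <- function(theta_deg) {
  p0 <- 0.5 * matrix(c(
    1, 1, 0, 0,
    1, 1, 0, 0,
    0, 0, 0, 0,
    0, 0, 0, 0
  ), 4, 4, byrow = TRUE)
  rot_mueller(-theta_deg) %*% p0 %*% rot_mueller(theta_deg)
}

# random fully- or partially-polarized physical Stokes vector
random_stokes <- function() {
  s0 <- stats::runif(1, 0.1, 2)
  p <- stats::runif(1)          # degree of polarization
  u <- stats::rnorm(3)
  u <- u / sqrt(sum(u^2))
  c(s0, s0 * p * u)
}

tiny_axis <- function(n = 5L) spectral_axis(seq(470, 750, length.out = n))

# Brute-force GLCM contrast: explicit co-occurrence count matrix via a double
# loop over all in-bounds pixel pairs, then sum((i-j)/(L-1))^2 * p(i,j).
brute_glcm <- function(image, n_levels = 8L,
                       offsets = list(c(0L, 1L), c(1L, 0L),
                                      c(1L, 1L), c(1L, -1L)),
                       symmetric = TRUE) {
  lev <- floor(pmin(pmax(image, 0), 1) * n_levels)
  lev[lev == n_levels] <- n_levels - 1L
  lev[!is.finite(image)] <- NA_integer_
  nr <- nrow(image); nc <- ncol(image)
  vals <- vapply(offsets, function(off) {
    counts <- matrix(0, n_levels, n_levels)
    for (r in seq_len(nr)) {
      for (cc in seq_len(nc)) {
        r2 <- r + off[1L]; c2 <- cc + off[2L]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
            !is.na(lev[r, cc]) && !is.na(lev[r2, c2])) {
          i <- lev[r, cc] + 1L; j <- lev[r2, c2] + 1L
          counts[i, j] <- counts[i, j] + 1
          if (symmetric) counts[j, i] <- counts[j, i] + 1
        }
      }
    }
    # sum r(i,j)^2 p(i,j) with the normalization factored out exactly
    lv <- seq_len(n_levels) - 1L
    diff2 <- outer(lv, lv, function(i, j) (i - j)^2)
    sum(diff2 * counts) / (sum(counts) * (n_levels - 1)^2)
  }, numeric(1))
  mean(vals)
}

# 4-connected component count of a logical matrix (flood fill)
count_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  n <- 0L
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      if (mask[r, cc] && !seen[r, cc]) {
        n <- n + 1L
        queue <- list(c(r, cc))
        seen[r, cc] <- TRUE
        while (length(queue)) {
          cur <- queue[[1L]]; queue <- queue[-1L]
          for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
            rr <- cur[1L] + d[1L]; ccc <- cur[2L] + d[2L]
            if (rr >= 1 && rr <= nr && ccc >= 1 && ccc <= nc &&
                mask[rr, ccc] && !seen[rr, ccc]) {
              seen[rr, ccc] <- TRUE
              queue <- c(queue, list(c(rr, ccc)))
            }
          }
        }
      }
    }
  }
  n
}

# uniform element-image set from one Stokes vector, for reconstruction tests
uniform_elements <- function(s, axis, shape = c(2L, 2L)) {
  st <- analyzer_states()
  mk <- function(state) {
    array(analyzer_intensity(state, s), dim = c(shape, axis$n_bands))
  }
  element_image_set(mk(st$H), mk(st$V), mk(st$P45), mk(st$RC), axis)
}
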