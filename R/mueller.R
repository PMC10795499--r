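#' Mueller matrix of an ideal linear polarizer
#'
#' @param transmission_axis_deg Transmission-axis angle in degrees, measured
#'   from horizontal.
#' @return A 4x4 numeric Mueller matrix.
#' @details The matrix is idempotent (an ideal polarizer applied twice equals
#'   itself) and transmits half of unpolarized light.
#' @examples
#' mueller_linear_polarizer(0) %*% c(1, 0, 0, 0)  # -> (0.5, 0.5, 0, 0)
#' @export
mueller_linear_polarizer <- function(transmission_axis_deg) {
  stopifnot(is.finite(transmission_axis_deg))
  c2 <- cos(2 * transmission_axis_deg * pi / 180)
  s2 <- sin(2 * transmission_axis_deg * pi / 180)
  0.5 * matrix(c(
    1,   c2,      s2,      0,
    c2,  c2 * c2, c2 * s2, 0,
    s2,  c2 * s2, s2 * s2, 0,
    0,   0,       0,       0
  ), 4, 4, byrow = TRUE)
}

#' Mueller matrix of an ideal linear retarder
#'
#' Linear retarder (waveplate) with the given fast-axis orientation and
#' retardance. Zero retardance gives the identity; total intensity (S0) and
#' the degree of polarization are preserved.
#'
#' @param fast_axis_deg Fast-axis angle in degrees from horizontal.
#' @param retardance_rad Retardance in radians.
#' @return A 4x4 numeric Mueller matrix.
#' @section Sign convention:
#' The package uses the convention in which a quarter-wave retarder
#' (retardance pi/2) at fast axis 0 deg maps +45 deg linear light (1,0,1,0)
#' to left-circular (1,0,0,-1). Under this convention the right-circular
#' analyzer state of the dual-LCVR train carries LCVR2 retardance -pi/2 (see
#' [analyzer_states()]), which is the choice that makes the four-state Stokes
#' reconstruction agree with the theoretical quarter-wave-plate calibration
#' curves S3 = -cos(2 theta).
#' @examples
#' mueller_retarder(0, pi / 2) %*% c(1, 0, 1, 0)  # -> (1, 0, 0, -1)
#' @export
mueller_retarder <- function(fast_axis_deg, retardance_rad) {
  stopifnot(is.finite(fast_axis_deg), is.finite(retardance_rad))
  matrix(retarder_elements(fast_axis_deg * pi / 180, retardance_rad),
         4, 4, byrow = FALSE)
}

# Vectorized closed-form entries of the linear-retarder Mueller matrix.
# theta_rad and delta_rad may be equal-length vectors; returns a matrix with
# one column per matrix entry in column-major (R) order, i.e. 16 columns.
retarder_elements <- function(theta_rad, delta_rad) {
  c2 <- cos(2 * theta_rad)
  s2 <- sin(2 * theta_rad)
  cd <- cos(delta_rad)
  sd <- sin(delta_rad)
  one <- rep(1, length(c2) * (length(c2) > 0))
  zero <- one * 0
  # column-major: columns of the 4x4 matrix stacked
  cbind(
    one,  zero,                zero,                zero,
    zero, c2^2 + s2^2 * cd,    c2 * s2 * (1 - cd),  s2 * sd,
    zero, c2 * s2 * (1 - cd),  s2^2 + c2^2 * cd,    -c2 * sd,
    zero, -s2 * sd,            c2 * sd,             cd,
    deparse.level = 0
  )
}

#' The four canonical analyzer states of the dual-LCVR train
#'
#' The analyzer consists of LCVR 1 (fast axis 0 deg, retardance `delta1`),
#' LCVR 2 (fast axis 45 deg, retardance `delta2`) and a horizontal linear
#' polarizer, in that order along the beam. The four canonical retardance
#' pairs realize a horizontal (H), vertical (V), +45 deg (P45) and
#' right-circular (RC) analyzer, yielding the element images Ih, Iv, I45 and
#' Irc.
#'
#' @return A named list of `phsi_analyzer_state` objects `H`, `V`, `P45`, `RC`,
#'   each with fields `name`, `delta1`, `delta2` (radians).
#' @section Sign convention:
#' RC uses `delta2 = -pi/2` (see [mueller_retarder()]): this is the retardance
#' sign under which `2 * Irc - (Ih + Iv)` recovers `+S3` and the simulated
#' quarter-wave-plate calibration reproduces its theoretical curves.
#' @export
analyzer_states <- function() {
  list(
    H   = analyzer_state("H",   0,      0),
    V   = analyzer_state("V",   0,      pi),
    P45 = analyzer_state("P45", pi / 2, pi / 2),
    RC  = analyzer_state("RC",  0,      -pi / 2)
  )
}

#' Construct an analyzer state
#'
#' @param name Label for the state (for canonical states one of `"H"`, `"V"`,
#'   `"P45"`, `"RC"`; arbitrary labels are allowed for custom states).
#' @param delta1,delta2 Retardances of LCVR 1 and LCVR 2 in radians.
#' @return A `phsi_analyzer_state`.
#' @export
analyzer_state <- function(name, delta1, delta2) {
  stopifnot(is.character(name), length(name) == 1L,
            is.finite(delta1), is.finite(delta2))
  structure(list(name = name, delta1 = delta1, delta2 = delta2),
            class = "phsi_analyzer_state")
}

#' Detected intensity behind the analyzer for a given Stokes input
#'
#' Propagates an input Stokes vector through LCVR 1 (fast axis 0 deg,
#' retardance `delta1`), LCVR 2 (fast axis 45 deg, retardance `delta2`) and a
#' horizontal linear polarizer, and returns the first (intensity) element of
#' the result.
#'
#' @param state A `phsi_analyzer_state`.
#' @param s_in Numeric length-4 Stokes vector (S0, S1, S2, S3).
#' @return Scalar detected intensity.
#' @examples
#' st <- analyzer_states()
#' analyzer_intensity(st$H, c(1, 1, 0, 0))  # 1: horizontal light, H analyzer
#' analyzer_intensity(st$V, c(1, 1, 0, 0))  # 0
#' @export
analyzer_intensity <- function(state, s_in) {
  stopifnot(inherits(state, "phsi_analyzer_state"),
            is.numeric(s_in), length(s_in) == 4L)
  m <- mueller_linear_polarizer(0) %*%
    mueller_retarder(45, state$delta2) %*%
    mueller_retarder(0, state$delta1)
  drop(m %*% s_in)[1L]
}

# Precomputed first row of the analyzer Mueller chain: detected intensity is
# the dot product of this weight vector with the sample-exit Stokes vector.
# I = 0.5 * (S0 + cos(d2) S1 + sin(d1) sin(d2) S2 - cos(d1) sin(d2) S3)
analyzer_weights <- function(state) {
  0.5 * c(1,
          cos(state$delta2),
          sin(state$delta1) * sin(state$delta2),
          -cos(state$delta1) * sin(state$delta2))
}
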