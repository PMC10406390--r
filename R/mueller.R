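#' Mueller calculus primitives
#'
#' Building blocks for the polarization state generator (PSG) and analyzer
#' (PSA) optical trains: ideal linear polarizers and linear retarders, plus
#' the Mueller rotation that re-expresses an element whose fast axis /
#' transmission axis is rotated in the laboratory frame.
#'
#' Angles are in degrees throughout the package; Stokes convention is
#' (I, Q, U, V) with Q > 0 for horizontal linear polarization.
#'
#' @param angle axis orientation in degrees, counterclockwise from horizontal.
#' @param retardance retardance in degrees (90 for an ideal quarter-wave plate).
#' @return A 4 x 4 numeric Mueller matrix.
#' @name mueller
NULL

deg2rad <- function(x) x * pi / 180

#' @rdname mueller
#' @export
mueller_rotation <- function(angle) {
  a <- 2 * deg2rad(angle)
  matrix(c(1, 0, 0, 0,
           0, cos(a), sin(a), 0,
           0, -sin(a), cos(a), 0,
           0, 0, 0, 1), 4, 4, byrow = TRUE)
}

#' @rdname mueller
#' @export
mueller_polarizer <- function(angle = 0) {
  a <- 2 * deg2rad(angle)
  c2 <- cos(a); s2 <- sin(a)
  0.5 * matrix(c(1, c2, s2, 0,
                 c2, c2^2, c2 * s2, 0,
                 s2, c2 * s2, s2^2, 0,
                 0, 0, 0, 0), 4, 4, byrow = TRUE)
}

#' @rdname mueller
#' @export
mueller_retarder <- function(retardance, angle = 0) {
  d <- deg2rad(retardance)
  m <- matrix(c(1, 0, 0, 0,
                0, 1, 0, 0,
                0, 0, cos(d), sin(d),
                0, 0, -sin(d), cos(d)), 4, 4, byrow = TRUE)
  if (angle != 0) {
    m <- mueller_rotation(-angle) %*% m %*% mueller_rotation(angle)
  }
  m
}
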