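# Elementary Mueller matrices and Stokes helpers.
#
# Conventions used throughout the package:
#   * Stokes vector (I, Q, U, V): I total intensity, Q horizontal-minus-
#     vertical linear, U 45-minus-135 linear, V right-minus-left circular.
#   * Mueller elements are referred to by their 0-based physics labels
#     m00..m33 (row-first); in R code the same element is M[i+1, j+1].
#   * All optical-element angles are fast-axis / transmission-axis angles in
#     degrees, measured from horizontal; retardance is in radians.

deg2rad <- function(x) x * pi / 180

#' Mueller rotation matrix
#'
#' Rotation of the polarization reference frame by `angle_deg`. Conjugating a
#' sample matrix as `R(theta) %*% M %*% R(-theta)` expresses the same sample
#' with its axes rotated by `theta`; rotation-invariant polarimetric
#' parameters are unchanged under this operation.
#'
#' @param angle_deg Rotation angle in degrees.
#' @return A 4x4 Mueller matrix.
#' @export
mm_rotation <- function(angle_deg) {
  th <- deg2rad(angle_deg)
  c2 <- cos(2 * th); s2 <- sin(2 * th)
  matrix(c(1, 0, 0, 0,
           0, c2, -s2, 0,
           0, s2, c2, 0,
           0, 0, 0, 1), 4, 4, byrow = TRUE)
}

#' Ideal linear polarizer
#'
#' @param angle_deg Transmission-axis angle in degrees.
#' @return A 4x4 Mueller matrix (unit transmittance along the axis, so
#'   unpolarized light keeps half its intensity).
#' @export
mm_polarizer <- function(angle_deg) {
  p0 <- 0.5 * matrix(c(1, 1, 0, 0,
                       1, 1, 0, 0,
                       0, 0, 0, 0,
                       0, 0, 0, 0), 4, 4, byrow = TRUE)
  mm_rotation(angle_deg) %*% p0 %*% mm_rotation(-angle_deg)
}

#' Ideal linear retarder
#'
#' @param delta Retardance in radians.
#' @param angle_deg Fast-axis angle in degrees.
#' @return A 4x4 Mueller matrix.
#' @export
mm_retarder <- function(delta, angle_deg = 0) {
  cd <- cos(delta); sd_ <- sin(delta)
  r0 <- matrix(c(1, 0, 0, 0,
                 0, 1, 0, 0,
                 0, 0, cd, sd_,
                 0, 0, -sd_, cd), 4, 4, byrow = TRUE)
  mm_rotation(angle_deg) %*% r0 %*% mm_rotation(-angle_deg)
}

#' Linear diattenuator
#'
#' Partial polarizer with total diattenuation `d` along a linear axis,
#' normalized to unit `m00`.
#'
#' @param d Diattenuation in `[0, 1)`.
#' @param angle_deg Transmission-axis angle in degrees.
#' @return A 4x4 Mueller matrix with `m00 = 1`.
#' @export
mm_diattenuator <- function(d, angle_deg = 0) {
  stopifnot(d >= 0, d <= 1)
  d_vec <- d * c(cos(2 * deg2rad(angle_deg)), sin(2 * deg2rad(angle_deg)), 0)
  diattenuator_from_vector(d_vec)
}

# M_D from a diattenuation 3-vector (Lu-Chipman construction).
diattenuator_from_vector <- function(d_vec) {
  d <- sqrt(sum(d_vec^2))
  m_d <- sqrt(max(1 - d^2, 0)) * diag(3)
  if (d > 0) {
    dhat <- d_vec / d
    m_d <- m_d + (1 - sqrt(max(1 - d^2, 0))) * tcrossprod(dhat)
  }
  out <- rbind(c(1, d_vec), cbind(d_vec, m_d))
  dimnames(out) <- NULL
  out
}

#' Isotropic partial depolarizer
#'
#' @param depol Depolarization power in `[0, 1]`; `diag(1, 1-depol, 1-depol,
#'   1-depol)`.
#' @return A 4x4 Mueller matrix.
#' @export
mm_depolarizer <- function(depol) {
  stopifnot(depol >= 0, depol <= 1)
  diag(c(1, rep(1 - depol, 3)))
}

#' Test physical realizability of a Mueller matrix on a probe set
#'
#' Applies `m` to a set of fully polarized probe Stokes vectors spread over
#' the Poincare sphere and checks that every output is a physical Stokes
#' vector (`I >= 0`, degree of polarization `<= 1`) within `tol`.
#'
#' @param m A 4x4 Mueller matrix.
#' @param n_probes Number of probe states.
#' @param tol Numerical tolerance.
#' @return `TRUE`/`FALSE`.
#' @export
is_physical_mueller <- function(m, n_probes = 64, tol = 1e-9) {
  stopifnot(is.matrix(m), all(dim(m) == 4))
  if (!all(is.finite(m)) || m[1, 1] <= 0) return(FALSE)
  probes <- probe_stokes_set(n_probes)
  out <- m %*% probes
  i <- out[1, ]
  dop2 <- colSums(out[2:4, , drop = FALSE]^2)
  all(i >= -tol * m[1, 1]) && all(dop2 <= (i + tol * m[1, 1])^2 + tol)
}

# Deterministic quasi-uniform set of fully polarized Stokes probes (plus the
# unpolarized state), as columns.
probe_stokes_set <- function(n) {
  k <- seq_len(n)
  z <- (2 * k - 1) / n - 1
  phi <- k * pi * (3 - sqrt(5))
  r <- sqrt(pmax(1 - z^2, 0))
  rbind(1, r * cos(phi), r * sin(phi), z) |>
    cbind(c(1, 0, 0, 0))
}
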