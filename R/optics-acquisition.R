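# Forward model of the PSG / sample / PSA acquisition and the least-squares
# Mueller reconstruction. A polarization state is one row of a state table
# (tibble) with columns psg_pol, psg_qwp, psa_qwp, psa_pol -- all angles in
# degrees. Light traverses: polarizer(psg_pol) -> QWP(psg_qwp) -> sample ->
# QWP(psa_qwp) -> polarizer(psa_pol) -> camera.

#' Build a polarization-state table
#'
#' @param psg_pol,psg_qwp,psa_qwp,psa_pol Angles in degrees (recycled to a
#'   common length). Stored modulo 180.
#' @return A tibble with one row per acquisition state.
#' @export
pol_states <- function(psg_pol, psg_qwp, psa_qwp, psa_pol) {
  angles <- vctrs::vec_recycle_common(
    psg_pol = psg_pol, psg_qwp = psg_qwp,
    psa_qwp = psa_qwp, psa_pol = psa_pol
  )
  if (!all(vapply(angles, function(a) all(is.finite(a)), logical(1)))) {
    abort("All polarization-state angles must be finite.")
  }
  tibble::as_tibble(lapply(angles, function(a) a %% 180))
}

#' Default 24-state acquisition protocol
#'
#' Six generator states (polarizer fixed at 0 deg, quarter-wave plate at
#' 0, 30, ..., 150 deg) crossed with four analyzer settings (horizontal,
#' +45 deg, right-circular, vertical). The induced 24x16 design matrix has
#' rank 16 and condition number about 11.7.
#'
#' @return A 24-row polarization-state tibble.
#' @export
default_pol_sequence <- function() {
  psa <- data.frame(
    psa_qwp = c(0, 45, 0, 0),
    psa_pol = c(0, 45, 45, 90)
  )
  grid <- expand.grid(g = 1:6, a = 1:4)
  pol_states(
    psg_pol = 0,
    psg_qwp = (grid$g - 1) * 30,
    psa_qwp = psa$psa_qwp[grid$a],
    psa_pol = psa$psa_pol[grid$a]
  )
}

#' Stokes vector generated by the PSG
#'
#' Unpolarized unit-intensity light through an ideal linear polarizer then an
#' ideal quarter-wave plate. The result is fully polarized with intensity
#' 0.5 (the polarizer passes half of unpolarized light).
#'
#' @param state One-row polarization-state tibble (or any list with
#'   `psg_pol`, `psg_qwp`).
#' @return Numeric Stokes 4-vector.
#' @export
psg_stokes <- function(state) {
  s <- mm_retarder(pi / 2, state$psg_qwp[1]) %*%
    mm_polarizer(state$psg_pol[1]) %*% c(1, 0, 0, 0)
  drop(s)
}

#' Analyzer row of the PSA
#'
#' First row of `polarizer(psa_pol) %*% qwp(psa_qwp)`: the detected intensity
#' for a sample `M` in state `s` is `psa_row(s) %*% M %*% psg_stokes(s)`.
#'
#' @inheritParams psg_stokes
#' @return Numeric 4-vector.
#' @export
psa_row <- function(state) {
  (mm_polarizer(state$psa_pol[1]) %*% mm_retarder(pi / 2, state$psa_qwp[1]))[1, ]
}

#' Design matrix of an acquisition protocol
#'
#' Row k holds the coefficients of the linear map from the 16 Mueller
#' elements (row-first order m00..m33) to the detected intensity of state k.
#'
#' @param states Polarization-state tibble.
#' @return An `nrow(states)` x 16 matrix.
#' @export
design_matrix <- function(states) {
  t(vapply(seq_len(nrow(states)), function(k) {
    s <- psg_stokes(states[k, ])
    a <- psa_row(states[k, ])
    as.vector(t(outer(a, s)))
  }, numeric(16)))
}

#' Condition number of an acquisition protocol
#'
#' @param states Polarization-state tibble.
#' @return Ratio of the largest to the 16th singular value of the design
#'   matrix (`Inf` if rank-deficient).
#' @export
sequence_condition <- function(states) {
  sv <- svd(design_matrix(states))$d
  if (length(sv) < 16 || sv[16] <= 1e-12 * sv[1]) return(Inf)
  sv[1] / sv[16]
}

#' Simulate detected intensities for one Mueller matrix
#'
#' @param m A physical 4x4 Mueller matrix (`m00 > 0`).
#' @param states Polarization-state tibble.
#' @param noise_sd Standard deviation of additive Gaussian camera noise, in
#'   the same arbitrary units as the intensities (incident beam has `I = 1`,
#'   so noise-free frames lie in `[0, 0.25 * m00]` for passive samples).
#' @return Numeric vector of `nrow(states)` intensities.
#' @export
simulate_intensities <- function(m, states, noise_sd = 0) {
  stopifnot(is.matrix(m), all(dim(m) == 4), noise_sd >= 0)
  if (!is.finite(m[1, 1]) || m[1, 1] <= 0) {
    abort("Non-physical Mueller matrix: m00 must be positive.")
  }
  ideal <- drop(design_matrix(states) %*% as.vector(t(m)))
  ideal <- pmax(ideal, 0)  # clamp float underflow of mathematically zero signals
  if (noise_sd > 0) ideal <- ideal + rnorm(length(ideal), 0, noise_sd)
  ideal
}

#' Simulate an intensity stack for a Mueller-matrix image
#'
#' @param mm_image Array of shape (4, 4, H, W): one Mueller matrix per pixel.
#' @param states Polarization-state tibble.
#' @inheritParams simulate_intensities
#' @return An intensity stack: list with `frames` (array `n_states` x H x W)
#'   and `states` (the protocol), class `"intensity_stack"`.
#' @export
simulate_intensity_stack <- function(mm_image, states, noise_sd = 0) {
  stopifnot(length(dim(mm_image)) == 4, all(dim(mm_image)[1:2] == 4))
  h <- dim(mm_image)[3]; w <- dim(mm_image)[4]
  wmat <- design_matrix(states)
  # vec(t(m)) per pixel: row-first element order m00..m33
  pix <- matrix(aperm(mm_image, c(2, 1, 3, 4)), nrow = 16)
  frames <- pmax(wmat %*% pix, 0)
  if (noise_sd > 0) frames <- frames + rnorm(length(frames), 0, noise_sd)
  intensity_stack(array(frames, c(nrow(states), h, w)), states)
}

#' Construct an intensity stack object
#'
#' @param frames Array of shape (n_states, H, W), all values finite or NA.
#' @param states Polarization-state tibble with `n_states` rows.
#' @return An `"intensity_stack"` object.
#' @export
intensity_stack <- function(frames, states) {
  stopifnot(length(dim(frames)) == 3)
  if (dim(frames)[1] != nrow(states)) {
    abort(sprintf(
      "Stack has %d frames but the state manifest lists %d states.",
      dim(frames)[1], nrow(states)
    ))
  }
  structure(list(frames = frames, states = states), class = "intensity_stack")
}

#' @export
print.intensity_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<intensity_stack> %d states, %d x %d pixels\n", d[1], d[2], d[3]))
  invisible(x)
}

#' Reconstruct per-pixel Mueller matrices from an intensity stack
#'
#' Solves the overdetermined linear system `I_k = sum_ij W[k, ij] m_ij` by
#' least squares, with the pseudo-inverse of the design matrix computed once
#' and applied to every pixel. Pixels with any non-finite frame value are
#' propagated as fully masked (all-NA) matrices.
#'
#' @param stack An `"intensity_stack"`.
#' @return Array of shape (4, 4, H, W).
#' @export
reconstruct_mueller <- function(stack) {
  stopifnot(inherits(stack, "intensity_stack"))
  states <- stack$states
  if (nrow(states) < 16) {
    abort(sprintf(
      "Underdetermined protocol: %d states, at least 16 required.", nrow(states)
    ))
  }
  wmat <- design_matrix(states)
  sv <- svd(wmat)
  if (sum(sv$d > 1e-10 * sv$d[1]) < 16) {
    abort(paste0(
      "Rank-deficient acquisition protocol: the ", nrow(states),
      "-state manifest induces a design matrix of rank ",
      sum(sv$d > 1e-10 * sv$d[1]),
      " (< 16); Mueller elements are not identifiable."
    ))
  }
  pinv <- sv$v %*% (t(sv$u) / sv$d)
  d <- dim(stack$frames)
  frames <- matrix(stack$frames, nrow = d[1])
  masked <- colSums(!is.finite(frames)) > 0
  frames[, masked] <- 0
  elems <- pinv %*% frames            # 16 x Npix, row-first order
  elems[, masked] <- NA_real_
  out <- array(elems, c(4, 4, d[2], d[3]))
  aperm(out, c(2, 1, 3, 4))
}

#' Normalize a Mueller matrix by its m00 element
#'
#' @param m A 4x4 Mueller matrix with `m00 > 0`.
#' @return The matrix divided by `m[1, 1]`.
#' @export
normalize_mueller <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == 4))
  if (!is.finite(m[1, 1]) || m[1, 1] <= 0) {
    abort("Cannot normalize: m00 must be positive.")
  }
  m / m[1, 1]
}
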