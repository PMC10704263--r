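# Polarimetric parameter extraction from a 4x4 Mueller matrix:
# Lu-Chipman polar decomposition M = M_Delta %*% M_R %*% M_D, Mueller matrix
# transformation (MMT) parameters, and the assembled 25-feature vector.
#
# Element labels follow the 0-based physics convention m00..m33; in R code
# element mij is M[i+1, j+1].

clip01 <- function(x, tol = 1e-9) pmin(pmax(x, 0), 1 + tol) |> pmin(1)
clip_acos <- function(x) acos(pmin(pmax(x, -1), 1))

#' Diattenuation of a Mueller matrix
#'
#' Total and linear diattenuation from the first row:
#' `D = sqrt(m01^2 + m02^2 + m03^2) / m00`,
#' `D_L = sqrt(m01^2 + m02^2) / m00`.
#'
#' @param m A 4x4 Mueller matrix with `m00 > 0`.
#' @return List with `d_vec` (3-vector), `d`, `d_l` (both clipped to `[0, 1]`).
#' @export
diattenuation <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == 4), m[1, 1] > 0)
  d_vec <- m[1, 2:4] / m[1, 1]
  list(
    d_vec = d_vec,
    d = clip01(sqrt(sum(d_vec^2))),
    d_l = clip01(sqrt(sum(d_vec[1:2]^2)))
  )
}

#' Polarizance of a Mueller matrix
#'
#' Total and linear polarizance from the first column:
#' `P = sqrt(m10^2 + m20^2 + m30^2) / m00`,
#' `P_L = sqrt(m10^2 + m20^2) / m00`.
#'
#' @inheritParams diattenuation
#' @return List with `p_vec`, `p`, `p_l`.
#' @export
polarizance <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == 4), m[1, 1] > 0)
  p_vec <- m[2:4, 1] / m[1, 1]
  list(
    p_vec = p_vec,
    p = clip01(sqrt(sum(p_vec^2))),
    p_l = clip01(sqrt(sum(p_vec[1:2]^2)))
  )
}

#' Lu-Chipman polar decomposition
#'
#' Sequential factorization `M = M_Delta %*% M_R %*% M_D` into a depolarizer,
#' a retarder and a diattenuator, with the standard scalar parameters:
#' total retardance `R`, linear retardance `delta_l`, optical rotation `psi`,
#' depolarization power `Delta`, plus diattenuation and polarizance.
#'
#' The diattenuator factor is built from the first row; the depolarizer
#' 3x3 block is the symmetric square root of `m' m'^T` (eigendecomposition,
#' eigenvalues clipped at zero) with overall sign taken from `det(m')` so the
#' retarder block stays a proper rotation; the retarder factor is
#' `M_Delta^-1 %*% M'`.
#'
#' A diattenuation numerically at 1 (singular diattenuator) is clipped to
#' `1 - 1e-6` and flagged `"diattenuation_clipped"`; a fully depolarizing
#' sample (zero 3x3 block) takes `M_R = I` and is flagged
#' `"depolarizer_singular"`.
#'
#' @param m A 4x4 Mueller matrix with `m00 > 0` (normalized internally).
#' @return An object of class `"lu_chipman"`: a list with `m_d`, `m_r`,
#'   `m_delta` (the factors), `d_vec`, `d`, `d_l`, `p_vec`, `p`, `p_l`,
#'   `r` (total retardance, radians), `delta_l` (linear retardance, radians),
#'   `psi` (optical rotation, radians), `depol` (depolarization power) and
#'   `flags` (character vector, empty when no degeneracy was hit).
#' @export
lu_chipman <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == 4))
  if (!is.finite(m[1, 1]) || m[1, 1] <= 0) abort("lu_chipman() needs m00 > 0.")
  m <- m / m[1, 1]
  flags <- character()

  dia <- diattenuation(m)
  pol <- polarizance(m)
  d_vec <- dia$d_vec
  d <- sqrt(sum(d_vec^2))
  if (d >= 1 - 1e-6) {
    d_vec <- d_vec * (1 - 1e-6) / d
    d <- 1 - 1e-6
    flags <- c(flags, "diattenuation_clipped")
  }
  m_d <- diattenuator_from_vector(d_vec)
  m_prime <- m %*% solve(m_d)

  mp <- m_prime[2:4, 2:4]
  sym <- mp %*% t(mp)
  eig <- eigen((sym + t(sym)) / 2, symmetric = TRUE)
  root <- eig$vectors %*% (sqrt(pmax(eig$values, 0)) * t(eig$vectors))
  if (det(mp) < 0) root <- -root
  m_small_delta <- root

  if (max(abs(mp)) < 1e-9) {
    m_r_small <- diag(3)
    flags <- c(flags, "depolarizer_singular")
  } else {
    m_r_small <- tryCatch(
      solve(m_small_delta, mp),
      error = function(e) {
        flags <<- c(flags, "depolarizer_singular")
        MASS::ginv(m_small_delta) %*% mp
      }
    )
  }

  m_delta <- rbind(c(1, 0, 0, 0), cbind(m_prime[2:4, 1], m_small_delta))
  m_r <- diag(4); m_r[2:4, 2:4] <- m_r_small

  r_tot <- clip_acos(sum(diag(m_r)) / 2 - 1)
  delta_l <- clip_acos(
    sqrt((m_r[2, 2] + m_r[3, 3])^2 + (m_r[3, 2] - m_r[2, 3])^2) - 1
  )
  psi <- 0.5 * atan2(m_r[3, 2] - m_r[2, 3], m_r[2, 2] + m_r[3, 3])
  depol <- 1 - abs(sum(diag(m_small_delta))) / 3

  structure(list(
    m_d = m_d, m_r = m_r, m_delta = m_delta,
    d_vec = dia$d_vec, d = dia$d, d_l = dia$d_l,
    p_vec = pol$p_vec, p = pol$p, p_l = pol$p_l,
    r = r_tot, delta_l = delta_l, psi = psi,
    depol = clip01(depol),
    flags = flags
  ), class = "lu_chipman")
}

#' @export
print.lu_chipman <- function(x, ...) {
  cat("<lu_chipman decomposition>\n")
  cat(sprintf("  D = %.4f  P = %.4f  Delta = %.4f\n", x$d, x$p, x$depol))
  cat(sprintf("  R = %.4f rad  delta_L = %.4f rad  psi = %.4f rad\n",
              x$r, x$delta_l, x$psi))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn lu_chipman Tidy one-row tibble of the scalar parameters.
#' @param x A `"lu_chipman"` object.
#' @param ... Unused.
#' @method tidy lu_chipman
#' @export
tidy.lu_chipman <- function(x, ...) {
  tibble::tibble(
    D = x$d, D_L = x$d_l, P = x$p, P_L = x$p_l,
    Delta = x$depol, R = x$r, delta_L = x$delta_l, psi = x$psi,
    flags = paste(x$flags, collapse = ";")
  )
}

#' Mueller matrix transformation (MMT) parameters
#'
#' Orientation-insensitive scalar combinations of the central elements of the
#' normalized matrix: `b = (m11 + m22) / 2`,
#' `t1 = sqrt((m11 - m22)^2 + (m12 + m21)^2) / 2` and the normalized
#' anisotropy `A = 2 b t1 / (b^2 + t1^2)` (0 when the denominator vanishes).
#' All three are invariant under in-plane rotation of the sample.
#'
#' @param m A 4x4 Mueller matrix with `m00 > 0` (normalized internally).
#' @return List with `b`, `t1`, `a`.
#' @export
mmt_params <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == 4), m[1, 1] > 0)
  m <- m / m[1, 1]
  b <- (m[2, 2] + m[3, 3]) / 2
  t1 <- sqrt((m[2, 2] - m[3, 3])^2 + (m[2, 3] + m[3, 2])^2) / 2
  denom <- b^2 + t1^2
  a <- if (denom > 0) 2 * b * t1 / denom else 0
  list(b = b, t1 = t1, a = a)
}

#' Names of the 25 polarimetric features
#'
#' The 16 normalized Mueller elements (row-first, `m00`..`m33`) followed by
#' the 9 derived parameters: total diattenuation `D`, linear polarizance
#' `P_L`, depolarization power `Delta`, total retardance `R`, linear
#' retardance `delta_L`, optical rotation `psi`, and the MMT parameters `b`,
#' `t1`, `A`.
#'
#' @return Character vector of length 25.
#' @export
mm_feature_names <- function() {
  c(paste0("m", as.vector(t(outer(0:3, 0:3, paste0)))),
    "D", "P_L", "Delta", "R", "delta_L", "psi", "b", "t1", "A")
}

#' Extract the 25-feature polarimetric descriptor
#'
#' Normalizes the matrix by `m00`, then assembles the 16 element features
#' plus the 9 derived parameters (see [mm_feature_names()]). Any non-finite
#' value arising from a degenerate decomposition is replaced by 0 and
#' flagged, so the output is always finite.
#'
#' @param m A 4x4 Mueller matrix with `m00 > 0`.
#' @return A one-row tibble with 25 feature columns and a `flags` character
#'   column (`""` when clean).
#' @export
feature_vector <- function(m) {
  m <- normalize_mueller(m)
  lc <- lu_chipman(m)
  mt <- mmt_params(m)
  vals <- c(
    as.vector(t(m)),
    lc$d, lc$p_l, lc$depol, lc$r, lc$delta_l, lc$psi,
    mt$b, mt$t1, mt$a
  )
  flags <- lc$flags
  bad <- !is.finite(vals)
  if (any(bad)) {
    vals[bad] <- 0
    flags <- c(flags, "nonfinite_replaced")
  }
  out <- tibble::as_tibble(as.list(setNames(vals, mm_feature_names())))
  out$flags <- paste(flags, collapse = ";")
  out
}
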