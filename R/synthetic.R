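# Synthetic two-class polarimetric tissue cohorts.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: class-conditional distributions of linear retardance (collagen
# birefringence), diattenuation and depolarization; a patient -> ROI -> pixel
# hierarchy; the cohort imbalance of the motivating clinical setting
# (27 non-recurring vs 8 recurring patients, 3-14 ROIs each); and optional
# planted outlier patients with flipped labels.
#
# Each pixel's Mueller matrix is the forward composition
#   M = M_Delta(depol) %*% M_R(delta, theta) %*% M_D(d, phi)
# so the Lu-Chipman decomposition recovers the generating parameters exactly
# at zero within-pixel spread.

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(pmin(pmax(rep(mean, n), lo), hi))
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

#' Class-conditional tissue parameter distributions
#'
#' Gaussian hierarchies (truncated to physical ranges) for linear retardance
#' `delta` (radians), diattenuation `d` and depolarization power `depol`.
#' Each parameter has a class mean plus independent patient-, ROI- and
#' pixel-level standard deviations; fiber orientation `theta` is uniform on
#' `[0, 180)` degrees per ROI with a pixel-level jitter.
#'
#' @param delta_mean,d_mean,depol_mean Class means (`delta` in `[0, pi]`,
#'   `d` in `[0, 1)`, `depol` in `[0, 1]`).
#' @param delta_sd,d_sd,depol_sd Length-3 numeric vectors: patient, ROI and
#'   pixel standard deviations.
#' @param theta_pixel_sd Pixel-level fast-axis jitter, degrees.
#' @return A `"tissue_class_params"` list.
#' @export
tissue_class_params <- function(delta_mean, d_mean, depol_mean,
                                delta_sd = c(0.12, 0.10, 0.05),
                                d_sd = c(0.020, 0.015, 0.005),
                                depol_sd = c(0.05, 0.04, 0.02),
                                theta_pixel_sd = 5) {
  stopifnot(
    delta_mean >= 0, delta_mean <= pi,
    d_mean >= 0, d_mean < 1,
    depol_mean >= 0, depol_mean <= 1,
    length(delta_sd) == 3, length(d_sd) == 3, length(depol_sd) == 3,
    all(c(delta_sd, d_sd, depol_sd) >= 0), theta_pixel_sd >= 0
  )
  structure(list(
    delta_mean = delta_mean, delta_sd = delta_sd,
    d_mean = d_mean, d_sd = d_sd,
    depol_mean = depol_mean, depol_sd = depol_sd,
    theta_pixel_sd = theta_pixel_sd
  ), class = "tissue_class_params")
}

#' Default class parameters
#'
#' Non-recurring patients (`"noLR"`) model mature, densely aligned stroma:
#' higher birefringent retardance and diattenuation, lower depolarization.
#' Recurring patients (`"LR"`) model immature stroma with the opposite
#' contrast. Magnitudes are package defaults for simulation, not measured
#' tissue claims.
#'
#' @param class `"noLR"` or `"LR"`.
#' @return A `"tissue_class_params"` list.
#' @export
default_class_params <- function(class = c("noLR", "LR")) {
  class <- match.arg(class)
  if (class == "noLR") {
    tissue_class_params(delta_mean = 0.90, d_mean = 0.12, depol_mean = 0.25)
  } else {
    tissue_class_params(delta_mean = 0.55, d_mean = 0.06, depol_mean = 0.40)
  }
}

#' Compose a single-pixel Mueller matrix from tissue parameters
#'
#' `M = M_Delta(depol) %*% M_R(delta, theta) %*% M_D(d, phi)`.
#'
#' @param delta Linear retardance, radians.
#' @param theta Retarder fast-axis angle, degrees.
#' @param d Diattenuation.
#' @param phi Diattenuator axis angle, degrees (defaults to `theta`).
#' @param depol Depolarization power.
#' @return A 4x4 Mueller matrix with `m00 = 1`.
#' @export
compose_tissue_mueller <- function(delta, theta, d, depol, phi = theta) {
  mm_depolarizer(depol) %*% mm_retarder(delta, theta) %*% mm_diattenuator(d, phi)
}

#' Draw one pixel Mueller matrix from class distributions
#'
#' Draws `(delta, theta, d, depol)` from the class hierarchy (all three sd
#' levels collapsed into a single draw) and composes the matrix. Used for
#' quick property checks; [generate_cohort()] performs the full
#' patient/ROI/pixel hierarchy.
#'
#' @param params A `"tissue_class_params"` object.
#' @return A 4x4 Mueller matrix.
#' @export
sample_pixel_mueller <- function(params) {
  stopifnot(inherits(params, "tissue_class_params"))
  delta <- rtrunc_norm(1, params$delta_mean, sqrt(sum(params$delta_sd^2)), 0, pi)
  d <- rtrunc_norm(1, params$d_mean, sqrt(sum(params$d_sd^2)), 0, 0.99)
  depol <- rtrunc_norm(1, params$depol_mean, sqrt(sum(params$depol_sd^2)), 0, 1)
  theta <- runif(1, 0, 180)
  compose_tissue_mueller(delta, theta, d, depol)
}

#' Cohort configuration
#'
#' @param n_patients Named integer vector `c(noLR = ..., LR = ...)`.
#' @param roi_range Inclusive range of ROIs per patient (draws are uniform on
#'   this range unless `roi_counts` is given).
#' @param roi_counts Either `NULL` (uniform draws), the string `"cohort"`
#'   (deterministic per-patient counts reproducing the reference cohort
#'   totals of 263 non-recurring and 70 recurring ROIs), or a list with
#'   per-class integer vectors of per-patient ROI counts.
#' @param pixels_per_roi Number of pixels simulated per ROI (square image).
#' @param n_outliers Number of planted outlier patients (ordinary patients of
#'   either class whose labels are flipped).
#' @param seed Integer seed driving all randomness of the generator.
#' @return A `"cohort_config"` list.
#' @export
cohort_config <- function(n_patients = c(noLR = 27, LR = 8),
                          roi_range = c(3, 14),
                          roi_counts = NULL,
                          pixels_per_roi = 64,
                          n_outliers = 0,
                          seed = 1) {
  stopifnot(
    all(n_patients >= 1), all(c("noLR", "LR") %in% names(n_patients)),
    length(roi_range) == 2, roi_range[1] >= 1, roi_range[2] >= roi_range[1],
    pixels_per_roi >= 1, n_outliers >= 0,
    n_outliers <= sum(n_patients)
  )
  structure(list(
    n_patients = n_patients, roi_range = roi_range, roi_counts = roi_counts,
    pixels_per_roi = pixels_per_roi, n_outliers = n_outliers, seed = seed
  ), class = "cohort_config")
}

# Spread `total` ROIs over `n` patients as evenly as possible.
spread_roi_counts <- function(total, n) {
  base <- total %/% n
  counts <- rep(base, n)
  extra <- total - base * n
  if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1
  counts
}

resolve_roi_counts <- function(config) {
  np <- config$n_patients
  if (is.null(config$roi_counts)) {
    list(
      noLR = sample(config$roi_range[1]:config$roi_range[2], np[["noLR"]], TRUE),
      LR = sample(config$roi_range[1]:config$roi_range[2], np[["LR"]], TRUE)
    )
  } else if (identical(config$roi_counts, "cohort")) {
    list(
      noLR = spread_roi_counts(263, np[["noLR"]]),
      LR = spread_roi_counts(70, np[["LR"]])
    )
  } else {
    stopifnot(is.list(config$roi_counts),
              length(config$roi_counts$noLR) == np[["noLR"]],
              length(config$roi_counts$LR) == np[["LR"]])
    config$roi_counts
  }
}

draw_level <- function(mean, sd) rnorm(1, mean, sd)

#' Generate a synthetic polarimetric cohort
#'
#' Simulates the full patient -> ROI -> pixel hierarchy: per patient a random
#' effect on each tissue parameter, per ROI a further random effect plus a
#' uniform fiber orientation, per pixel a final jitter. Each ROI's pixel
#' Mueller matrices are reduced to the element-wise median matrix, from
#' which the 25-feature record is extracted (the same checkpoint order the
#' analysis pipeline uses). Planted outliers are ordinary patients whose
#' labels are flipped after simulation; their identities are recorded in the
#' ground-truth sidecar.
#'
#' T stages 1-4 are assigned per patient with probabilities `t_stage_probs`
#' so subgroup analyses can be exercised.
#'
#' @param config A [cohort_config()].
#' @param params_nolr,params_lr Class parameter sets
#'   (default [default_class_params()]).
#' @param t_stage_probs Probabilities of T stages 1:4.
#' @param keep_mm_images If `TRUE`, also return each ROI's pixel Mueller
#'   array (memory-heavy; off by default).
#' @return A `"mm_cohort"` list: `features` (one row per ROI: ids, `label`,
#'   `t_stage`, `n_pixels`, 25 features, `flags`), `patients` (one row per
#'   patient: `patient_id`, `label`, `t_stage`, `generating_class`,
#'   `outlier`), `truth` (per-ROI generating parameters), `outliers`
#'   (flipped patient ids), `config`, and optionally `mm_images`.
#' @export
generate_cohort <- function(config = cohort_config(),
                            params_nolr = default_class_params("noLR"),
                            params_lr = default_class_params("LR"),
                            t_stage_probs = c(0.06, 0.14, 0.68, 0.12),
                            keep_mm_images = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  roi_counts <- resolve_roi_counts(config)
  side <- ceiling(sqrt(config$pixels_per_roi))

  classes <- c(rep("noLR", config$n_patients[["noLR"]]),
               rep("LR", config$n_patients[["LR"]]))
  n_pat <- length(classes)
  patient_ids <- sprintf("P%02d", seq_len(n_pat))
  counts <- c(roi_counts$noLR, roi_counts$LR)
  t_stage <- sample(1:4, n_pat, replace = TRUE, prob = t_stage_probs)

  feat_rows <- list(); truth_rows <- list(); mm_images <- list()
  roi_counter <- 0L
  for (p in seq_len(n_pat)) {
    prm <- if (classes[p] == "noLR") params_nolr else params_lr
    pat_delta <- draw_level(prm$delta_mean, prm$delta_sd[1])
    pat_d <- draw_level(prm$d_mean, prm$d_sd[1])
    pat_depol <- draw_level(prm$depol_mean, prm$depol_sd[1])
    for (r in seq_len(counts[p])) {
      roi_counter <- roi_counter + 1L
      roi_id <- sprintf("R%03d", roi_counter)
      roi_delta <- draw_level(pat_delta, prm$delta_sd[2])
      roi_d <- draw_level(pat_d, prm$d_sd[2])
      roi_depol <- draw_level(pat_depol, prm$depol_sd[2])
      roi_theta <- runif(1, 0, 180)
      npix <- side * side
      px_delta <- rtrunc_norm(npix, roi_delta, prm$delta_sd[3], 0, pi)
      px_d <- rtrunc_norm(npix, roi_d, prm$d_sd[3], 0, 0.99)
      px_depol <- rtrunc_norm(npix, roi_depol, prm$depol_sd[3], 0, 1)
      px_theta <- roi_theta + rnorm(npix, 0, prm$theta_pixel_sd)
      mm_image <- array(NA_real_, c(4, 4, side, side))
      for (i in seq_len(npix)) {
        mm_image[, , ((i - 1) %% side) + 1, ((i - 1) %/% side) + 1] <-
          compose_tissue_mueller(px_delta[i], px_theta[i], px_d[i], px_depol[i])
      }
      roi_def <- tibble::tibble(
        roi_id = roi_id, patient_id = patient_ids[p],
        label = as.integer(classes[p] == "LR"),
        x0 = 0, y0 = 0, x1 = side, y1 = side
      )
      feat_rows[[roi_counter]] <- roi_feature_record(mm_image, roi_def)
      truth_rows[[roi_counter]] <- tibble::tibble(
        roi_id = roi_id, patient_id = patient_ids[p],
        generating_class = classes[p],
        delta = roi_delta, d = roi_d, depol = roi_depol, theta = roi_theta
      )
      if (keep_mm_images) mm_images[[roi_id]] <- mm_image
    }
  }

  features <- dplyr::bind_rows(feat_rows)
  truth <- dplyr::bind_rows(truth_rows)

  outlier_ids <- character()
  labels <- setNames(as.integer(classes == "LR"), patient_ids)
  if (config$n_outliers > 0) {
    outlier_ids <- sort(sample(patient_ids, config$n_outliers))
    labels[outlier_ids] <- 1L - labels[outlier_ids]
    features$label <- unname(labels[features$patient_id])
  }

  patients <- tibble::tibble(
    patient_id = patient_ids,
    label = as.integer(labels[patient_ids]),
    t_stage = t_stage,
    generating_class = classes,
    outlier = patient_ids %in% outlier_ids
  )
  features <- dplyr::left_join(
    features, patients[, c("patient_id", "t_stage")], by = "patient_id"
  )
  features <- dplyr::relocate(features, "t_stage", .after = "label")

  out <- list(
    features = features, patients = patients, truth = truth,
    outliers = outlier_ids, config = config
  )
  if (keep_mm_images) out$mm_images <- mm_images
  structure(out, class = "mm_cohort")
}

#' @export
print.mm_cohort <- function(x, ...) {
  cat(sprintf(
    "<mm_cohort> %d patients (%d LR), %d ROIs, %d planted outliers\n",
    nrow(x$patients), sum(x$patients$label), nrow(x$features),
    length(x$outliers)
  ))
  invisible(x)
}
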