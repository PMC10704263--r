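# ROI-level aggregation: per-pixel Mueller images + ROI rectangles -> one
# 25-feature record per ROI, through the median-Mueller-matrix checkpoint
# (element-wise median over pixels first, feature extraction second).
#
# ROI rectangles are axis-aligned, 0-based, half-open: pixel columns
# x0 <= x < x1, rows y0 <= y < y1, in Mueller-image coordinates.

validate_roi <- function(roi, h, w) {
  needed <- c("x0", "y0", "x1", "y1")
  if (!all(needed %in% names(roi))) {
    abort("ROI must have columns x0, y0, x1, y1.")
  }
  if (roi$x1 <= roi$x0 || roi$y1 <= roi$y0) {
    abort(sprintf("Empty ROI rectangle (%g, %g, %g, %g).",
                  roi$x0, roi$y0, roi$x1, roi$y1))
  }
  if (roi$x0 < 0 || roi$y0 < 0 || roi$x1 > w || roi$y1 > h) {
    abort(sprintf(
      "ROI (%g, %g, %g, %g) outside image bounds %d x %d.",
      roi$x0, roi$y0, roi$x1, roi$y1, h, w
    ))
  }
  invisible(roi)
}

#' Median Mueller matrix of an ROI
#'
#' Element-wise median across all unmasked ROI pixels. A pixel is masked if
#' any of its 16 elements is non-finite. With an even pixel count the median
#' is the mean of the two middle values.
#'
#' @param mm_image Array of shape (4, 4, H, W).
#' @param roi One-row data frame with `x0`, `y0`, `x1`, `y1` (0-based,
#'   half-open pixel rectangle).
#' @return A 4x4 matrix with attribute `n_pixels` (contributing pixels).
#' @export
median_mueller <- function(mm_image, roi) {
  stopifnot(length(dim(mm_image)) == 4, all(dim(mm_image)[1:2] == 4))
  h <- dim(mm_image)[3]; w <- dim(mm_image)[4]
  validate_roi(roi, h, w)
  sub <- mm_image[, , (roi$y0 + 1):roi$y1, (roi$x0 + 1):roi$x1, drop = FALSE]
  pix <- matrix(sub, nrow = 16)
  ok <- colSums(!is.finite(pix)) == 0
  if (!any(ok)) abort("All pixels in the ROI are masked.")
  med <- apply(pix[, ok, drop = FALSE], 1, median)
  structure(matrix(med, 4, 4), n_pixels = sum(ok))
}

#' Feature record of one ROI
#'
#' Computes the ROI's median Mueller matrix, then the 25-feature descriptor
#' of that median matrix (features of the median, not medians of per-pixel
#' features), and attaches the ROI metadata.
#'
#' @inheritParams median_mueller
#' @param roi One-row data frame with `roi_id`, `patient_id`, `label` and the
#'   rectangle columns.
#' @return A one-row tibble: `roi_id`, `patient_id`, `label`, `n_pixels`,
#'   the 25 features, and `flags`.
#' @export
roi_feature_record <- function(mm_image, roi) {
  med <- median_mueller(mm_image, roi)
  feats <- feature_vector(med)
  dplyr::bind_cols(
    tibble::tibble(
      roi_id = roi$roi_id, patient_id = roi$patient_id, label = roi$label,
      n_pixels = attr(med, "n_pixels")
    ),
    feats
  )
}

#' Feature records for a table of ROIs
#'
#' @inheritParams median_mueller
#' @param rois Data frame of ROI definitions (one row per ROI).
#' @return A tibble with one feature record per ROI.
#' @export
roi_features <- function(mm_image, rois) {
  purrr::map_dfr(seq_len(nrow(rois)), function(i) {
    roi_feature_record(mm_image, rois[i, ])
  })
}
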