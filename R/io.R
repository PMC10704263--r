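# File formats tying the stages together. One stated convention throughout:
# CSVs are UTF-8, comma-separated, header row, '.' decimal; pixel
# coordinates are 0-based half-open; angles are degrees; arrays travel as
# multi-page 32-bit TIFF with a JSON sidecar holding the affine intensity
# scaling and metadata.

FEATURE_CSV_META <- c("roi_id", "patient_id", "label")
ROI_CSV_COLS <- c("roi_id", "patient_id", "label", "x0", "y0", "x1", "y1")
PATIENT_CSV_COLS <- c("patient_id", "label", "t_stage")

require_cols <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("File '%s' is missing required column(s): %s.",
                  file, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' Read / write ROI feature tables
#'
#' The feature CSV carries `roi_id`, `patient_id`, `label`, optional
#' `t_stage`/`n_pixels`/`flags`, and the 25 feature columns of
#' [mm_feature_names()].
#'
#' @param features Feature tibble.
#' @param path File path.
#' @return `read_features_csv()` returns the validated tibble;
#'   `write_features_csv()` returns `path` invisibly.
#' @export
write_features_csv <- function(features, path) {
  require_cols(features, c(FEATURE_CSV_META, mm_feature_names()), path)
  readr::write_csv(features, path)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  require_cols(df, c(FEATURE_CSV_META, mm_feature_names()), path)
  df
}

#' Read / write ROI definition tables
#'
#' Columns: `roi_id`, `patient_id`, `label` (0/1), and the 0-based half-open
#' pixel rectangle `x0`, `y0`, `x1`, `y1`.
#'
#' @param rois ROI tibble.
#' @param path File path.
#' @return The tibble (read) or `path` invisibly (write).
#' @export
write_roi_csv <- function(rois, path) {
  require_cols(rois, ROI_CSV_COLS, path)
  readr::write_csv(rois, path)
  invisible(path)
}

#' @rdname write_roi_csv
#' @export
read_roi_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  require_cols(df, ROI_CSV_COLS, path)
  if (!all(df$label %in% c(0, 1))) {
    abort(sprintf("File '%s': label column must be 0/1.", path))
  }
  if (any(df$x1 <= df$x0 | df$y1 <= df$y0)) {
    abort(sprintf("File '%s': empty ROI rectangle(s).", path))
  }
  df
}

#' Read / write patient tables
#'
#' Columns: `patient_id`, `label` (0/1), `t_stage` (may be `NA`).
#'
#' @param patients Patient tibble.
#' @param path File path.
#' @return The tibble (read) or `path` invisibly (write).
#' @export
write_patients_csv <- function(patients, path) {
  require_cols(patients, PATIENT_CSV_COLS, path)
  readr::write_csv(patients, path)
  invisible(path)
}

#' @rdname write_patients_csv
#' @export
read_patients_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  require_cols(df, PATIENT_CSV_COLS, path)
  df
}

# ---- multi-page TIFF arrays -------------------------------------------------

# Store an (n, H, W) array as n TIFF pages, affinely rescaled to [0, 1];
# offset/scale go into the sidecar so the round trip is exact to float32
# resolution.
write_array_tiff <- function(arr, tiff_path, sidecar_path, extra_meta = list()) {
  rng <- range(arr, finite = TRUE)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  pages <- lapply(seq_len(dim(arr)[1]), function(k) {
    pmin(pmax((arr[k, , ] - rng[1]) / scale, 0), 1)
  })
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 32L)
  meta <- c(list(offset = rng[1], scale = scale, dim = dim(arr)), extra_meta)
  jsonlite::write_json(meta, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(tiff_path)
}

read_array_tiff <- function(tiff_path, sidecar_path) {
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  if (length(pages) != meta$dim[1]) {
    abort(sprintf(
      "File '%s' has %d pages but sidecar '%s' declares %d.",
      tiff_path, length(pages), sidecar_path, meta$dim[1]
    ))
  }
  arr <- array(NA_real_, meta$dim)
  for (k in seq_along(pages)) {
    arr[k, , ] <- pages[[k]] * meta$scale + meta$offset
  }
  list(array = arr, meta = meta)
}

#' Read / write polarization intensity stacks
#'
#' The stack travels as a multi-page 32-bit TIFF (one page per acquisition
#' state, page order = manifest order) plus a JSON sidecar holding the
#' intensity scaling and the state manifest (angles in degrees).
#'
#' @param stack An `"intensity_stack"`.
#' @param tiff_path TIFF file path.
#' @param sidecar_path JSON sidecar path (default: `tiff_path` with a
#'   `.json` extension appended).
#' @return The stack (read) or `tiff_path` invisibly (write).
#' @export
write_intensity_stack <- function(stack, tiff_path,
                                  sidecar_path = paste0(tiff_path, ".json")) {
  stopifnot(inherits(stack, "intensity_stack"))
  write_array_tiff(stack$frames, tiff_path, sidecar_path,
                   list(kind = "intensity_stack",
                        states = as.data.frame(stack$states)))
  invisible(tiff_path)
}

#' @rdname write_intensity_stack
#' @export
read_intensity_stack <- function(tiff_path,
                                 sidecar_path = paste0(tiff_path, ".json")) {
  res <- read_array_tiff(tiff_path, sidecar_path)
  states <- tibble::as_tibble(res$meta$states)
  require_cols(states, c("psg_pol", "psg_qwp", "psa_qwp", "psa_pol"),
               sidecar_path)
  intensity_stack(res$array, states)
}

#' Read / write per-pixel Mueller images
#'
#' The (4, 4, H, W) array travels as a 16-page TIFF (row-first element order
#' m00..m33) plus a JSON sidecar with the scaling and a `normalized` flag.
#'
#' @param mm_image Array of shape (4, 4, H, W).
#' @param tiff_path,sidecar_path File paths.
#' @param normalized Whether the elements are m00-normalized.
#' @return The array with attribute `normalized` (read) or `tiff_path`
#'   invisibly (write).
#' @export
write_mueller_image <- function(mm_image, tiff_path,
                                sidecar_path = paste0(tiff_path, ".json"),
                                normalized = FALSE) {
  stopifnot(length(dim(mm_image)) == 4, all(dim(mm_image)[1:2] == 4))
  d <- dim(mm_image)
  flat <- array(aperm(mm_image, c(2, 1, 3, 4)), c(16, d[3], d[4]))
  write_array_tiff(flat, tiff_path, sidecar_path,
                   list(kind = "mueller_image", normalized = normalized))
  invisible(tiff_path)
}

#' @rdname write_mueller_image
#' @export
read_mueller_image <- function(tiff_path,
                               sidecar_path = paste0(tiff_path, ".json")) {
  res <- read_array_tiff(tiff_path, sidecar_path)
  d <- dim(res$array)
  out <- aperm(array(res$array, c(4, 4, d[2], d[3])), c(2, 1, 3, 4))
  attr(out, "normalized") <- isTRUE(res$meta$normalized)
  out
}

#' Write a classification report to JSON
#'
#' Serializes the fold-averaged metrics, per-fold metrics, averaged
#' confusion matrices, mean ROC curves, importances and the removal log.
#'
#' @param report An `"lr_report"`.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "lr_report"))
  payload <- list(
    summary = tidy(report),
    glance = glance(report),
    fold_metrics = purrr::map(report$models, "fold_metrics"),
    confusion_roi_mean = purrr::map(report$models, function(m)
      as.data.frame(m$conf_roi_mean)),
    confusion_patient_mean = purrr::map(report$models, function(m)
      as.data.frame(m$conf_patient_mean)),
    mean_roc = purrr::map(report$models, "mean_roc"),
    importance = report_importances(report),
    removal_log = report$removal_log,
    config = report$config
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' Read a YAML run configuration
#'
#' Validates the schema before anything runs: unknown top-level keys are
#' rejected with the offending key and file named.
#'
#' @param path YAML file path.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("paths", "models", "k", "seed", "threshold", "features",
               "t_stage", "outlier_budget", "outlier_tol", "outlier_model",
               "cv_mode", "cohort")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    abort(sprintf("Unknown configuration key(s) in '%s': %s.",
                  path, paste(unknown, collapse = ", ")))
  }
  if (!is.null(cfg$models)) {
    bad <- setdiff(cfg$models, MODEL_NAMES)
    if (length(bad)) {
      abort(sprintf("Unknown model(s) in '%s': %s.", path,
                    paste(bad, collapse = ", ")))
    }
  }
  cfg
}
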