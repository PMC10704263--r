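# Patient-grouped, label-stratified k-fold assignment. All ROIs of a patient
# travel together, so no patient ever contributes to both the train and test
# side of a fold.

#' Patient-grouped stratified k-fold plan
#'
#' Patients (not ROIs) are assigned to folds: within each label group,
#' patients are shuffled and dealt one at a time to the currently smallest
#' fold, largest group first. Every patient lands in exactly one test fold,
#' fold sizes differ by at most one patient, and labels are spread as evenly
#' as the counts allow.
#'
#' @param patients Data frame with `patient_id` and `label` (one row per
#'   patient).
#' @param k Number of folds.
#' @param seed Integer seed for the shuffle.
#' @return A tibble `patient_id`, `label`, `fold` (1..k).
#' @export
grouped_kfold <- function(patients, k = 5, seed = 1) {
  stopifnot(all(c("patient_id", "label") %in% names(patients)))
  patients <- dplyr::distinct(
    tibble::as_tibble(patients)[, c("patient_id", "label")]
  )
  n <- nrow(patients)
  if (k > n) abort(sprintf("k = %d folds but only %d patients.", k, n))
  if (k < 2) abort("k must be at least 2.")
  set.seed(seed)
  sizes <- rep(0L, k)
  fold <- setNames(integer(n), patients$patient_id)
  groups <- split(patients$patient_id, patients$label)
  groups <- groups[order(-vapply(groups, length, integer(1)))]
  for (ids in groups) {
    for (id in sample(ids)) {
      f <- which.min(sizes)
      fold[id] <- f
      sizes[f] <- sizes[f] + 1L
    }
  }
  dplyr::arrange(
    tibble::tibble(
      patient_id = patients$patient_id,
      label = patients$label,
      fold = as.integer(fold[patients$patient_id])
    ),
    .data$fold, .data$patient_id
  )
}
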