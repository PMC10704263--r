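# Confusion matrices, sensitivity/specificity/accuracy, ROC curves and
# AUROC (rank-based Mann-Whitney form), vertical ROC averaging, and the
# majority-vote patient call.

#' 2x2 confusion matrix
#'
#' @param truth,pred Vectors of 0/1 labels.
#' @return A 2x2 matrix, rows = truth (1 then 0), columns = predicted
#'   (1 then 0): `[1,1]` TP, `[1,2]` FN, `[2,1]` FP, `[2,2]` TN.
#' @export
confusion_2x2 <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  truth <- as.integer(truth); pred <- as.integer(pred)
  m <- matrix(c(
    sum(truth == 1 & pred == 1), sum(truth == 1 & pred == 0),
    sum(truth == 0 & pred == 1), sum(truth == 0 & pred == 0)
  ), 2, 2, byrow = TRUE,
  dimnames = list(truth = c("1", "0"), pred = c("1", "0")))
  m
}

#' Sensitivity, specificity and accuracy from a 2x2 confusion matrix
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`,
#' `accuracy = (TP + TN) / total`. A zero denominator yields `NaN` and is
#' named in the `flags` column. Entries may be fractional (fold-averaged
#' matrices).
#'
#' @param cm Matrix as produced by [confusion_2x2()].
#' @return One-row tibble `sensitivity`, `specificity`, `accuracy`, `flags`.
#' @export
performance_metrics <- function(cm) {
  stopifnot(is.matrix(cm), all(dim(cm) == 2), all(cm >= 0))
  total <- sum(cm)
  if (total == 0) abort("All-zero confusion matrix.")
  tp <- cm[1, 1]; fn <- cm[1, 2]; fp <- cm[2, 1]; tn <- cm[2, 2]
  flags <- character()
  sens <- if (tp + fn > 0) tp / (tp + fn) else { flags <- c(flags, "sensitivity_undefined"); NaN }
  spec <- if (tn + fp > 0) tn / (tn + fp) else { flags <- c(flags, "specificity_undefined"); NaN }
  tibble::tibble(
    sensitivity = sens, specificity = spec,
    accuracy = (tp + tn) / total,
    flags = paste(flags, collapse = ";")
  )
}

#' Area under the ROC curve
#'
#' Tie-corrected Mann-Whitney form: the AUROC equals the U statistic of the
#' positive-class scores normalized by `n1 * n0` (midranks for ties).
#'
#' @param scores Numeric scores, larger = more recurrence-like.
#' @param labels 0/1 labels.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("AUROC needs both classes present.")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve
#'
#' One point per distinct score threshold (plus the (0,0) endpoint),
#' sweeping from the most to the least recurrence-like score.
#'
#' @inheritParams auroc
#' @return Tibble `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("ROC needs both classes present.")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  keep <- c(diff(s) != 0, TRUE)  # last duplicate of each distinct score
  tibble::tibble(
    threshold = c(Inf, s[keep]),
    fpr = c(0, cumsum(y == 0)[keep] / n0),
    tpr = c(0, cumsum(y == 1)[keep] / n1)
  )
}

#' Vertically averaged ROC curve across folds
#'
#' Each fold's curve is evaluated as a step function (largest TPR attained
#' at or below each grid FPR) on a fixed FPR grid, then averaged pointwise.
#'
#' @param curves List of tibbles from [roc_curve()].
#' @param grid FPR grid (default 101 points on `[0, 1]`).
#' @return Tibble `fpr`, `tpr_mean`, `tpr_sd`.
#' @export
mean_roc <- function(curves, grid = seq(0, 1, length.out = 101)) {
  stopifnot(length(curves) >= 1)
  tprs <- vapply(curves, function(cv) {
    approx(x = cv$fpr, y = cv$tpr, xout = grid, method = "constant",
           f = 0, ties = max, rule = 2)$y
  }, numeric(length(grid)))
  tprs <- matrix(tprs, nrow = length(grid))
  tibble::tibble(
    fpr = grid,
    tpr_mean = rowMeans(tprs),
    tpr_sd = apply(tprs, 1, sd)
  )
}

#' Majority-vote patient call
#'
#' A patient is called recurrent when at least `threshold` of their ROI
#' predictions are recurrent; at the default 0.5 threshold an exact tie
#' therefore resolves to the recurrent (clinically conservative) class.
#' Set `tie` to `"negative"` to resolve ties the other way.
#'
#' @param pred 0/1 ROI predictions for one patient.
#' @param threshold Fraction of recurrent ROI calls required.
#' @param tie `"positive"` (default, `>=` comparison) or `"negative"`
#'   (strict `>`).
#' @return Integer 0/1 patient label.
#' @export
majority_vote <- function(pred, threshold = 0.5, tie = c("positive", "negative")) {
  tie <- match.arg(tie)
  pred <- as.integer(pred)
  if (length(pred) == 0) abort("majority_vote() needs at least one ROI prediction.")
  frac <- mean(pred == 1)
  if (tie == "positive") as.integer(frac >= threshold) else as.integer(frac > threshold)
}

# Patient-level votes for a table of ROI predictions.
patient_votes <- function(pred_df, threshold = 0.5, tie = "positive") {
  pred_df |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      truth = .data$label[1],
      vote = majority_vote(.data$pred, threshold, tie),
      n_rois = dplyr::n(),
      .groups = "drop"
    )
}
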