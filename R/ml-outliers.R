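# Greedy leave-one-patient-out outlier elimination. The motivating idea --
# evaluating all possible sample subsets -- is combinatorially infeasible
# (2^n_patients), so the search is greedy: at each step the patient whose
# complete removal most improves mean cross-validated ROI-level AUROC is
# dropped, provided the improvement exceeds a tolerance, up to a removal
# budget.

patients_of <- function(features) {
  dplyr::distinct(features[, c("patient_id", "label")])
}

# Cross-validated ROI-level AUROC under a patient-grouped plan. `pooling`
# selects between the AUROC of all out-of-fold scores pooled together
# (lower-variance; default for the outlier search) and the mean of per-fold
# AUROCs (folds whose test set holds a single class are skipped). `plan` may
# be supplied so that alternative cohorts (e.g. candidate patient removals)
# are scored on the same fold layout, isolating the effect of the removal
# from fold-assignment noise; patients absent from `features` simply drop
# out of their folds.
cv_auroc <- function(features, model, feature_names, k, seed, plan = NULL,
                     pooling = c("pooled", "fold_mean")) {
  pooling <- match.arg(pooling)
  if (is.null(plan)) plan <- grouped_kfold(patients_of(features), k = k, seed = seed)
  scores <- vector("list", k); labels <- vector("list", k)
  aucs <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    test_ids <- plan$patient_id[plan$fold == f]
    train <- features[!features$patient_id %in% test_ids, ]
    test <- features[features$patient_id %in% test_ids, ]
    if (nrow(test) == 0 || nrow(train) == 0 ||
        length(unique(train$label)) < 2) next
    fit <- fit_classifier(train, model, feature_names, seed = seed)
    scores[[f]] <- predict(fit, test, type = "score")
    labels[[f]] <- test$label
    if (length(unique(test$label)) == 2) {
      aucs[f] <- auroc(scores[[f]], labels[[f]])
    }
  }
  if (pooling == "pooled") auroc(unlist(scores), unlist(labels))
  else mean(aucs, na.rm = TRUE)
}

#' Greedy outlier-patient elimination
#'
#' Starting from the full cohort, repeatedly evaluates the mean
#' cross-validated ROI-level AUROC with each remaining patient held out
#' entirely, removes the patient whose removal helps the most if the gain
#' exceeds `tol`, and stops at the removal `budget` or when no removal
#' helps. Deterministic given `seed`.
#'
#' @param features ROI feature tibble (`patient_id`, `label`, features).
#' @param model Learner used for the evaluations (default `"xgboost"`).
#' @param feature_names Features used in the evaluations.
#' @param k Folds of the inner cross-validation.
#' @param budget Maximum number of patients to remove.
#' @param tol Minimum AUROC improvement to accept a removal.
#' @param seed Integer seed.
#' @param pooling `"pooled"` (default): one AUROC over all out-of-fold
#'   scores -- the lower-variance estimate; `"fold_mean"`: mean of per-fold
#'   AUROCs.
#' @return List with `features` (reduced cohort), `removed` (patient ids in
#'   removal order) and `log` (tibble `step`, `patient_id`, `auroc_before`,
#'   `auroc_after`).
#' @export
eliminate_outliers <- function(features, model = "xgboost",
                               feature_names = mm_feature_names(),
                               k = 5, budget = 3, tol = 0.005, seed = 1,
                               pooling = c("pooled", "fold_mean")) {
  pooling <- match.arg(pooling)
  n_pat <- nrow(patients_of(features))
  if (n_pat - budget < 2 * k) {
    abort(sprintf(
      "Infeasible budget: %d patients minus budget %d leaves fewer than 2k = %d.",
      n_pat, budget, 2 * k
    ))
  }
  log <- list()
  removed <- character()
  current <- features
  for (step in seq_len(budget)) {
    pats <- patients_of(current)$patient_id
    plan <- grouped_kfold(patients_of(current), k = k, seed = seed)
    auc_now <- cv_auroc(current, model, feature_names, k, seed,
                        plan = plan, pooling = pooling)
    cand <- vapply(pats, function(p) {
      reduced <- current[current$patient_id != p, ]
      if (length(unique(reduced$label)) < 2) return(-Inf)
      cv_auroc(reduced, model, feature_names, k, seed,
               plan = plan, pooling = pooling)
    }, numeric(1))
    best <- which.max(cand)
    if (cand[best] - auc_now <= tol) break
    log[[step]] <- tibble::tibble(
      step = step, patient_id = pats[best],
      auroc_before = auc_now, auroc_after = cand[best]
    )
    removed <- c(removed, pats[best])
    current <- current[current$patient_id != pats[best], ]
  }
  list(
    features = current,
    removed = removed,
    log = if (length(log)) dplyr::bind_rows(log) else
      tibble::tibble(step = integer(), patient_id = character(),
                     auroc_before = numeric(), auroc_after = numeric())
  )
}
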