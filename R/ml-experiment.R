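# The full classification experiment: optional outlier elimination ->
# patient-grouped stratified CV -> per-fold training and evaluation ->
# ROI-level confusion -> majority-vote patient calls -> fold-averaged
# metrics, mean ROC and feature importances.

#' Run the cross-validated classification experiment
#'
#' Executes the complete workflow on an ROI feature table: (optionally)
#' greedy outlier elimination, a patient-grouped stratified k-fold plan,
#' per-fold model fitting and scoring, ROI-level and majority-vote
#' patient-level confusion matrices, and aggregation to fold means with
#' standard deviations. Fully reproducible given `seed`.
#'
#' @param cohort An `"mm_cohort"` from [generate_cohort()] or an ROI feature
#'   tibble with `patient_id`, `label` and feature columns (plus `t_stage`
#'   if subgroup filtering is requested).
#' @param models Character vector of learners (see [fit_classifier()]).
#' @param features Feature names to use (default all 25).
#' @param k Number of folds.
#' @param seed Integer seed controlling fold assignment and the stochastic
#'   learners.
#' @param threshold Majority-vote threshold (fraction of recurrent ROI calls).
#' @param t_stage Optional integer: restrict the cohort to patients of this
#'   T stage before the experiment.
#' @param outlier_budget Patients the greedy outlier elimination may remove
#'   (0 disables it).
#' @param outlier_tol,outlier_model Tolerance and learner of the outlier loop.
#' @param cv_mode `"partition"` (one stratified grouped partition; default)
#'   or `"draws"` (k independent stratified 80:20-style grouped draws, test
#'   fold = a freshly drawn 1/k of patients each repeat).
#' @return An `"lr_report"` object; see [tidy.lr_report()], [glance.lr_report()]
#'   and [autoplot.lr_report()].
#' @export
run_experiment <- function(cohort,
                           models = MODEL_NAMES,
                           features = mm_feature_names(),
                           k = 5, seed = 1, threshold = 0.5,
                           t_stage = NULL,
                           outlier_budget = 0, outlier_tol = 0.005,
                           outlier_model = "xgboost",
                           cv_mode = c("partition", "draws")) {
  cv_mode <- match.arg(cv_mode)
  feats <- if (inherits(cohort, "mm_cohort")) cohort$features else
    tibble::as_tibble(cohort)
  stopifnot(all(c("patient_id", "label") %in% names(feats)),
            all(features %in% names(feats)))
  models <- match.arg(models, MODEL_NAMES, several.ok = TRUE)

  if (!is.null(t_stage)) {
    if (!"t_stage" %in% names(feats)) {
      abort("Subgroup filtering requested but no t_stage column present.")
    }
    feats <- feats[feats$t_stage %in% t_stage, ]
  }
  pats <- patients_of(feats)
  if (nrow(pats) < k) {
    abort(sprintf("Only %d patients after filtering; k = %d folds impossible.",
                  nrow(pats), k))
  }
  if (length(unique(pats$label)) < 2) {
    abort("Cohort holds a single class after filtering.")
  }

  removal_log <- NULL
  if (outlier_budget > 0) {
    elim <- eliminate_outliers(feats, model = outlier_model,
                               feature_names = features, k = k,
                               budget = outlier_budget, tol = outlier_tol,
                               seed = seed)
    feats <- elim$features
    removal_log <- elim$log
  }

  plans <- if (cv_mode == "partition") {
    plan <- grouped_kfold(patients_of(feats), k = k, seed = seed)
    lapply(seq_len(k), function(f) plan$patient_id[plan$fold == f])
  } else {
    lapply(seq_len(k), function(f) {
      p <- grouped_kfold(patients_of(feats), k = k, seed = seed + f)
      p$patient_id[p$fold == 1]
    })
  }

  model_results <- lapply(models, function(mod) {
    folds <- lapply(seq_along(plans), function(f) {
      test_ids <- plans[[f]]
      train <- feats[!feats$patient_id %in% test_ids, ]
      test <- feats[feats$patient_id %in% test_ids, ]
      if (length(unique(train$label)) < 2) {
        abort(sprintf("Fold %d: training data holds a single class.", f))
      }
      fit <- fit_classifier(train, mod, features, seed = seed)
      preds <- tibble::tibble(
        fold = f,
        roi_id = if ("roi_id" %in% names(test)) test$roi_id else NA_character_,
        patient_id = test$patient_id,
        label = as.integer(test$label),
        score = predict(fit, test, type = "score"),
        pred = predict(fit, test, type = "class")
      )
      votes <- patient_votes(preds, threshold)
      both <- length(unique(preds$label)) == 2
      list(
        preds = preds,
        conf_roi = confusion_2x2(preds$label, preds$pred),
        conf_patient = confusion_2x2(votes$truth, votes$vote),
        votes = votes,
        roc = if (both) roc_curve(preds$score, preds$label) else NULL,
        auroc = if (both) auroc(preds$score, preds$label) else NA_real_,
        importance = feature_importance(fit)
      )
    })

    fold_metrics <- purrr::map_dfr(seq_along(folds), function(f) {
      fl <- folds[[f]]
      roi_m <- performance_metrics(fl$conf_roi)
      pat_m <- performance_metrics(fl$conf_patient)
      tibble::tibble(
        fold = f,
        sensitivity = roi_m$sensitivity,
        specificity = roi_m$specificity,
        accuracy_roi = roi_m$accuracy,
        accuracy_patient = pat_m$accuracy,
        auroc = fl$auroc
      )
    })
    curves <- purrr::compact(purrr::map(folds, "roc"))
    list(
      model = mod,
      folds = folds,
      fold_metrics = fold_metrics,
      mean_roc = if (length(curves)) mean_roc(curves) else NULL,
      conf_roi_mean = Reduce(`+`, purrr::map(folds, "conf_roi")) / length(folds),
      conf_patient_mean =
        Reduce(`+`, purrr::map(folds, "conf_patient")) / length(folds),
      importance = purrr::map_dfr(seq_along(folds), function(f) {
        dplyr::mutate(folds[[f]]$importance, fold = f)
      })
    )
  })
  names(model_results) <- models

  structure(list(
    models = model_results,
    config = list(models = models, features = features, k = k, seed = seed,
                  threshold = threshold, t_stage = t_stage,
                  outlier_budget = outlier_budget, cv_mode = cv_mode),
    n_patients = nrow(patients_of(feats)),
    n_rois = nrow(feats),
    removal_log = removal_log
  ), class = "lr_report")
}

#' @export
print.lr_report <- function(x, ...) {
  cat(sprintf("<lr_report> %d patients, %d ROIs, %d-fold grouped CV\n",
              x$n_patients, x$n_rois, x$config$k))
  print(as.data.frame(tidy(x)), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Tidy a classification report
#'
#' @param x An `"lr_report"`.
#' @param ... Unused.
#' @return A tibble with one row per model: fold means and standard
#'   deviations of ROI-level sensitivity, specificity and accuracy,
#'   majority-vote patient-level accuracy, and AUROC.
#' @method tidy lr_report
#' @export
tidy.lr_report <- function(x, ...) {
  purrr::map_dfr(x$models, function(mr) {
    fm <- mr$fold_metrics
    agg <- function(v) c(mean(v, na.rm = TRUE), sd(v, na.rm = TRUE))
    tibble::tibble(
      model = mr$model,
      sensitivity = agg(fm$sensitivity)[1], sensitivity_sd = agg(fm$sensitivity)[2],
      specificity = agg(fm$specificity)[1], specificity_sd = agg(fm$specificity)[2],
      accuracy_roi = agg(fm$accuracy_roi)[1], accuracy_roi_sd = agg(fm$accuracy_roi)[2],
      accuracy_patient = agg(fm$accuracy_patient)[1],
      accuracy_patient_sd = agg(fm$accuracy_patient)[2],
      auroc = agg(fm$auroc)[1], auroc_sd = agg(fm$auroc)[2]
    )
  })
}

#' Report-level summary
#'
#' @param x An `"lr_report"`.
#' @param ... Unused.
#' @return One-row tibble: cohort size, CV setup, best model by mean AUROC.
#' @method glance lr_report
#' @export
glance.lr_report <- function(x, ...) {
  td <- tidy(x)
  best <- td[which.max(td$auroc), ]
  tibble::tibble(
    n_patients = x$n_patients, n_rois = x$n_rois, k = x$config$k,
    n_models = length(x$models),
    n_features = length(x$config$features),
    n_removed = if (is.null(x$removal_log)) 0L else nrow(x$removal_log),
    best_model = best$model, best_auroc = best$auroc
  )
}

#' Combined importance table of a report
#'
#' @param report An `"lr_report"`.
#' @return Tibble `model`, `feature`, `importance` (fold means), ready for
#'   [rank_features()].
#' @export
report_importances <- function(report) {
  stopifnot(inherits(report, "lr_report"))
  purrr::map_dfr(report$models, function(mr) {
    mr$importance |>
      dplyr::group_by(.data$feature) |>
      dplyr::summarise(importance = mean(.data$importance), .groups = "drop") |>
      dplyr::mutate(model = mr$model, .before = 1)
  })
}

#' Plot mean ROC curves of a report
#'
#' Mean vertically-averaged ROC per model with the chance diagonal.
#'
#' @param object An `"lr_report"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lr_report
#' @export
autoplot.lr_report <- function(object, ...) {
  df <- purrr::map_dfr(object$models, function(mr) {
    if (is.null(mr$mean_roc)) return(NULL)
    dplyr::mutate(mr$mean_roc, model = mr$model)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$tpr_mean, colour = .data$model)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::labs(x = "False positive rate", y = "Mean true positive rate",
                  colour = NULL) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
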