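# Feature ranking, outlier elimination, and the end-to-end experiment.

test_that("min-max normalization and top-k selection behave as defined", {
  imp <- tibble::tibble(
    model = "m1", feature = c("a", "b", "c"), importance = c(2, 1, 0)
  )
  rk <- rank_features(imp, k = 2)
  norm <- attr(rk, "normalized")
  expect_equal(norm$normalized[match(c("a", "b", "c"), norm$feature)],
               c(1, 0.5, 0))
  expect_identical(selected_features(rk), c("a", "b"))
  # deterministic name-order tie-breaking
  imp_tie <- tibble::tibble(model = "m1", feature = c("z", "y", "x"),
                            importance = c(1, 1, 1))
  rk_tie <- rank_features(imp_tie, k = 2)
  expect_identical(selected_features(rk_tie), c("x", "y"))
  expect_match(paste(attr(rk_tie, "flags"), collapse = " "),
               "constant_importance")
  expect_true(all(attr(rk_tie, "normalized")$normalized == 0))
})

test_that("cross-model aggregation recovers planted informative features", {
  df <- make_feature_cohort(n_patients_per_class = 12, rois_per_patient = 6,
                            informative = c("delta_L", "D"), gap = 3, seed = 61)
  imp <- purrr::map_dfr(c("xgboost", "rf", "logistic"), function(mod) {
    fit <- suppressWarnings(fit_classifier(df, mod, seed = 1))
    dplyr::mutate(feature_importance(fit), model = mod)
  })
  rk <- rank_features(imp, k = 5)
  expect_length(selected_features(rk), 5)
  expect_true(all(c("delta_L", "D") %in% selected_features(rk)))
})

test_that("experiment report is reproducible, leakage-free and well-formed", {
  coh <- generate_cohort(
    cohort_config(n_patients = c(noLR = 12, LR = 6), pixels_per_roi = 16,
                  seed = 62)
  )
  rep1 <- run_experiment(coh, models = c("xgboost", "lda"), k = 3, seed = 5)
  rep2 <- run_experiment(coh, models = c("xgboost", "lda"), k = 3, seed = 5)
  expect_identical(rep1, rep2)  # bit-identical under the same seed

  td <- tidy(rep1)
  expect_identical(td$model, c("xgboost", "lda"))
  num <- unlist(td[, c("sensitivity", "specificity", "accuracy_roi",
                       "accuracy_patient", "auroc")])
  expect_true(all(num >= 0 & num <= 1))
  gl <- glance(rep1)
  expect_identical(gl$n_patients, 18L)
  expect_identical(gl$n_rois, nrow(coh$features))

  # fold confusion totals equal test-set sizes at both levels
  plan <- grouped_kfold(coh$patients, k = 3, seed = 5)
  for (f in 1:3) {
    ids <- plan$patient_id[plan$fold == f]
    fl <- rep1$models$xgboost$folds[[f]]
    expect_identical(sum(fl$conf_roi),
                     sum(coh$features$patient_id %in% ids))
    expect_identical(sum(fl$conf_patient), length(ids))
    # no leakage: every scored ROI belongs to a test patient of this fold
    expect_true(all(fl$preds$patient_id %in% ids))
  }
})

test_that("unanimous ROI predictions fix the patient call", {
  coh <- generate_cohort(
    cohort_config(n_patients = c(noLR = 10, LR = 5), pixels_per_roi = 16,
                  seed = 63)
  )
  rep <- run_experiment(coh, models = "xgboost", k = 3, seed = 2)
  for (fl in rep$models$xgboost$folds) {
    agg <- dplyr::group_by(fl$preds, patient_id)
    unanimous <- dplyr::summarise(agg, u = length(unique(pred)) == 1,
                                  p = pred[1], .groups = "drop")
    votes <- fl$votes
    for (i in which(unanimous$u)) {
      expect_identical(
        votes$vote[votes$patient_id == unanimous$patient_id[i]],
        as.integer(unanimous$p[i])
      )
    }
  }
})

test_that("strong class separation yields near-perfect patient accuracy", {
  sp <- separated_params()
  coh <- generate_cohort(
    cohort_config(n_patients = c(noLR = 14, LR = 7), pixels_per_roi = 16,
                  seed = 64),
    params_nolr = sp$nolr, params_lr = sp$lr
  )
  rep <- run_experiment(coh, models = "xgboost", k = 5, seed = 3)
  expect_gt(tidy(rep)$accuracy_patient, 0.95)
  expect_gt(tidy(rep)$auroc, 0.95)
})

test_that("null cohorts (same class params) stay near chance", {
  null_p <- default_class_params("noLR")
  coh <- generate_cohort(
    cohort_config(n_patients = c(noLR = 14, LR = 7), pixels_per_roi = 16,
                  seed = 65),
    params_nolr = null_p, params_lr = null_p
  )
  rep <- run_experiment(coh, models = "xgboost", k = 5, seed = 3)
  expect_gt(tidy(rep)$auroc, 0.35)
  expect_lt(tidy(rep)$auroc, 0.65)
})

test_that("subgroup filter and degenerate configurations error cleanly", {
  coh <- generate_cohort(
    cohort_config(n_patients = c(noLR = 10, LR = 5), pixels_per_roi = 16,
                  seed = 66)
  )
  feats <- coh$features
  feats$t_stage <- NULL
  expect_error(run_experiment(feats, models = "lda", t_stage = 3),
               "t_stage")
  one_class <- coh$features[coh$features$label == 0, ]
  expect_error(run_experiment(one_class, models = "lda", k = 3),
               "single class")
  expect_error(run_experiment(coh$features[1:12, ], models = "lda", k = 5),
               "k = 5")
})

test_that("greedy elimination removes exactly the planted flipped patients", {
  sp <- separated_params()
  coh <- generate_cohort(
    cohort_config(roi_counts = "cohort", pixels_per_roi = 16,
                  n_outliers = 3, seed = 2),
    params_nolr = sp$nolr, params_lr = sp$lr
  )
  el <- suppressWarnings(
    eliminate_outliers(coh$features, model = "lda", budget = 5, seed = 1)
  )
  expect_setequal(el$removed, coh$outliers)
  expect_identical(nrow(el$log), 3L)
  expect_true(all(el$log$auroc_after > el$log$auroc_before))
  expect_identical(
    sort(unique(el$features$patient_id)),
    sort(setdiff(coh$patients$patient_id, coh$outliers))
  )
})

test_that("clean separable cohorts trigger no removals and budgets are enforced", {
  sp <- separated_params()
  coh <- generate_cohort(
    cohort_config(roi_counts = "cohort", pixels_per_roi = 16, seed = 3),
    params_nolr = sp$nolr, params_lr = sp$lr
  )
  el <- suppressWarnings(
    eliminate_outliers(coh$features, model = "lda", budget = 3, seed = 1)
  )
  expect_identical(el$removed, character(0))
  expect_identical(nrow(el$log), 0L)
  expect_error(
    eliminate_outliers(coh$features, budget = 30),
    "Infeasible budget"
  )
})

test_that("repeated-draw CV mode runs and keeps folds leakage-free", {
  coh <- generate_cohort(
    cohort_config(n_patients = c(noLR = 10, LR = 5), pixels_per_roi = 16,
                  seed = 68)
  )
  rep <- run_experiment(coh, models = "lda", k = 3, seed = 1, cv_mode = "draws")
  expect_identical(rep$config$cv_mode, "draws")
  for (fl in rep$models$lda$folds) {
    expect_true(all(fl$preds$label %in% 0:1))
    # test patients of a draw never contribute training rows: scores exist
    # only for the held-out patients
    expect_lte(length(unique(fl$preds$patient_id)), 15)
  }
  expect_true(all(tidy(rep)$accuracy_roi >= 0 & tidy(rep)$accuracy_roi <= 1))
})

test_that("autoplot methods return ggplot objects", {
  coh <- generate_cohort(
    cohort_config(n_patients = c(noLR = 8, LR = 4), pixels_per_roi = 16,
                  seed = 67)
  )
  rep <- run_experiment(coh, models = "lda", k = 2, seed = 1)
  expect_s3_class(autoplot(rep), "ggplot")
  rk <- rank_features(report_importances(rep), k = 5)
  expect_s3_class(autoplot(rk), "ggplot")
})
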