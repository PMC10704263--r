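# Grouped folds, majority vote, confusion metrics, ROC/AUROC.

test_that("grouped folds partition patients with balanced sizes", {
  pats <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:35),
    label = rep(c(0L, 1L), c(27, 8))
  )
  plan <- grouped_kfold(pats, k = 5, seed = 7)
  expect_setequal(plan$patient_id, pats$patient_id)
  expect_identical(as.integer(table(plan$fold)), rep(7L, 5))
  # every fold holds at least one patient of the minority class
  lr_per_fold <- tapply(plan$label, plan$fold, sum)
  expect_true(all(lr_per_fold >= 1))

  plan10 <- grouped_kfold(
    tibble::tibble(patient_id = letters[1:10], label = rep(0:1, 5)), k = 5, seed = 1
  )
  expect_identical(as.integer(table(plan10$fold)), rep(2L, 5))
})

test_that("no patient straddles train and test in any generated plan", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    k <- sample(2:min(5, n), 1)
    pats <- tibble::tibble(
      patient_id = sprintf("Q%03d", 1:n),
      label = rbinom(n, 1, 0.3)
    )
    plan <- grouped_kfold(pats, k = k, seed = i)
    expect_identical(anyDuplicated(plan$patient_id), 0L)
    for (f in seq_len(k)) {
      test_ids <- plan$patient_id[plan$fold == f]
      train_ids <- plan$patient_id[plan$fold != f]
      expect_length(intersect(test_ids, train_ids), 0)
    }
    expect_setequal(unlist(lapply(seq_len(k), function(f)
      plan$patient_id[plan$fold == f])), pats$patient_id)
  }
})

test_that("k larger than the patient count is rejected", {
  pats <- tibble::tibble(patient_id = c("a", "b", "c"), label = c(0, 1, 0))
  expect_error(grouped_kfold(pats, k = 5), "3 patients")
})

test_that("majority vote applies the at-least-half rule with positive ties", {
  expect_identical(majority_vote(c(1, 1, 0, 0, 1, 0, 0, 1)), 1L)  # 4 of 8
  expect_identical(majority_vote(rep(0, 5)), 0L)
  expect_identical(majority_vote(c(1, 1, 1, 0, 0)), 1L)
  expect_identical(majority_vote(c(1, 1, 0, 0), tie = "negative"), 0L)
  expect_error(majority_vote(integer(0)), "at least one")
  # unanimity always carries over
  expect_identical(majority_vote(rep(1, 7)), 1L)
  expect_identical(majority_vote(rep(0, 7), tie = "negative"), 0L)
})

test_that("confusion metrics follow their defining ratios", {
  cm <- matrix(c(3, 1, 1, 5), 2, 2, byrow = TRUE)  # TP FN / FP TN
  pm <- performance_metrics(cm)
  expect_equal(pm$sensitivity, 0.75)
  expect_equal(pm$specificity, 5 / 6)
  expect_equal(pm$accuracy, 0.8)
  # metric identity: sens*(TP+FN) + spec*(TN+FP) = TP + TN
  expect_equal(pm$sensitivity * 4 + pm$specificity * 6, 3 + 5)

  perfect <- performance_metrics(matrix(c(4, 0, 0, 6), 2, 2, byrow = TRUE))
  expect_equal(unlist(perfect[c("sensitivity", "specificity", "accuracy")]),
               c(sensitivity = 1, specificity = 1, accuracy = 1))

  degen <- performance_metrics(matrix(c(0, 0, 2, 5), 2, 2, byrow = TRUE))
  expect_true(is.nan(degen$sensitivity))
  expect_match(degen$flags, "sensitivity_undefined")
  expect_error(performance_metrics(matrix(0, 2, 2)), "All-zero")
})

test_that("confusion_2x2 counts agree with predictions and sum to n", {
  set.seed(42)
  truth <- rbinom(50, 1, 0.4); pred <- rbinom(50, 1, 0.5)
  cm <- confusion_2x2(truth, pred)
  expect_identical(sum(cm), 50L)
  expect_identical(cm[1, 1], sum(truth == 1 & pred == 1))
  expect_identical(cm[2, 2], sum(truth == 0 & pred == 0))
})

test_that("AUROC equals the brute-force concordant-pair oracle", {
  set.seed(43)
  for (i in 1:25) {
    n <- sample(10:50, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.4))  # both classes guaranteed
    scores <- rnorm(n)
    if (i %% 3 == 0) scores <- round(scores)  # force ties
    expect_equal(auroc(scores, labels), auroc_pairs(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(44)
  labels <- rbinom(80, 1, 0.35)
  labels[1:2] <- 0:1
  scores <- rnorm(80) + labels
  expect_equal(
    auroc(scores, labels),
    as.numeric(suppressMessages(pROC::auc(labels, scores))),
    tolerance = 1e-12
  )
})

test_that("AUROC hits its reference points", {
  expect_equal(auroc(1:10, rep(0:1, each = 5)), 1)
  expect_equal(auroc(10:1, rep(0:1, each = 5)), 0)
  expect_error(auroc(1:4, rep(1, 4)), "both classes")
  # label-independent scores: near chance over a large draw
  set.seed(45)
  expect_equal(auroc(rnorm(4000), rbinom(4000, 1, 0.5)), 0.5, tolerance = 0.05)
})

test_that("ROC curve starts at (0,0), ends at (1,1), and integrates to the AUROC", {
  set.seed(46)
  labels <- rbinom(60, 1, 0.4); labels[1:2] <- 0:1
  scores <- rnorm(60) + 0.8 * labels
  rc <- roc_curve(scores, labels)
  expect_equal(c(rc$fpr[1], rc$tpr[1]), c(0, 0))
  expect_equal(c(rc$fpr[nrow(rc)], rc$tpr[nrow(rc)]), c(1, 1))
  expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
  # trapezoid integral of the step curve equals the rank AUROC (no ties here)
  step_auc <- sum(diff(rc$fpr) * (head(rc$tpr, -1) + rc$tpr[-1]) / 2)
  expect_equal(step_auc, auroc(scores, labels), tolerance = 1e-10)
})

test_that("mean ROC vertically averages fold curves on the FPR grid", {
  c1 <- tibble::tibble(threshold = c(Inf, 1, 0), fpr = c(0, 0, 1), tpr = c(0, 1, 1))
  c2 <- tibble::tibble(threshold = c(Inf, 1, 0), fpr = c(0, 1, 1), tpr = c(0, 0, 1))
  mr <- mean_roc(list(c1, c2), grid = c(0, 0.5, 1))
  expect_equal(mr$tpr_mean, c(0.5, 0.5, 1))  # perfect and null curve average
  expect_true(all(mr$tpr_sd >= 0))
})
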