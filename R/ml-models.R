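# Thin adapters giving the five supported learners a common contract:
# fit on a feature tibble, score new ROIs (probability-like score for the
# positive class where available, oriented decision values for the SVM),
# predict hard labels, and expose a raw feature-importance vector
# (absolute coefficients for the linear models, impurity/gain importances
# for the tree ensembles).

MODEL_NAMES <- c("xgboost", "rf", "svm", "lda", "logistic")

model_matrix <- function(data, features) {
  x <- as.matrix(data[, features, drop = FALSE])
  storage.mode(x) <- "double"
  x
}

#' Fit a classifier on ROI feature records
#'
#' @param data Tibble with a binary `label` column (0 = no recurrence,
#'   1 = recurrence) and the feature columns.
#' @param model One of `"xgboost"`, `"rf"` (random forest), `"svm"` (linear
#'   kernel), `"lda"`, `"logistic"`.
#' @param features Character vector of feature column names.
#' @param seed Integer seed for the stochastic learners.
#' @return An `"mm_classifier"` object.
#' @export
fit_classifier <- function(data, model = MODEL_NAMES, features = mm_feature_names(),
                           seed = 1) {
  model <- match.arg(model)
  stopifnot(all(features %in% names(data)), "label" %in% names(data))
  y <- as.integer(data$label)
  if (length(unique(y)) < 2) {
    abort(sprintf("Training data for '%s' contains a single class.", model))
  }
  x <- model_matrix(data, features)
  set.seed(seed)
  fit <- switch(model,
    logistic = suppressWarnings(
      glm(y ~ ., data = data.frame(y = y, x, check.names = FALSE),
          family = binomial())
    ),
    lda = {
      # MASS::lda rejects features constant within every group; drop them
      # (they carry no discriminant information) and keep the kept set so
      # prediction and importance can map back.
      group_means <- apply(x, 2, function(col) tapply(col, y, mean))
      resid_sd <- sqrt(diag(stats::var(x - group_means[as.character(y), ])))
      keep <- resid_sd >= 1.1e-4  # matches MASS::lda's constancy tolerance
      if (!any(keep)) abort("All features are constant within classes.")
      # collinearity among the 25 polarimetric features is expected (several
      # derived parameters are functions of the same elements)
      fit <- suppressWarnings(
        MASS::lda(x[, keep, drop = FALSE], grouping = factor(y, levels = 0:1))
      )
      attr(fit, "kept_features") <- colnames(x)[keep]
      fit
    },
    svm = e1071::svm(x, factor(y, levels = 0:1), kernel = "linear",
                     scale = apply(x, 2, sd) > 0),
    rf = ranger::ranger(
      y = factor(y, levels = 0:1), x = as.data.frame(x),
      probability = TRUE, num.trees = 500, seed = seed, num.threads = 1,
      importance = "impurity"
    ),
    xgboost = xgboost::xgb.train(
      params = list(objective = "binary:logistic", nthread = 1,
                    seed = seed, max_depth = 4, eta = 0.3),
      data = xgboost::xgb.DMatrix(x, label = y), nrounds = 50, verbose = 0
    )
  )
  structure(list(model = model, fit = fit, features = features),
            class = "mm_classifier")
}

#' @export
print.mm_classifier <- function(x, ...) {
  cat(sprintf("<mm_classifier> %s on %d features\n",
              x$model, length(x$features)))
  invisible(x)
}

#' Score and classify ROIs with a fitted classifier
#'
#' @param object An `"mm_classifier"`.
#' @param newdata Tibble containing the feature columns.
#' @param type `"score"` for a continuous score increasing with the
#'   probability of recurrence (a probability for all models except the SVM,
#'   which returns its oriented decision value), `"class"` for hard 0/1
#'   labels.
#' @param ... Unused.
#' @return Numeric (score) or integer (class) vector.
#' @export
predict.mm_classifier <- function(object, newdata, type = c("score", "class"), ...) {
  type <- match.arg(type)
  x <- model_matrix(newdata, object$features)
  score <- switch(object$model,
    logistic = {
      # manual linear predictor: robust to rank-deficient fits, where
      # aliased coefficients come back NA (treated as zero contribution)
      co <- coef(object$fit)
      co[!is.finite(co)] <- 0
      stats::plogis(drop(co[1] + x[, names(co)[-1], drop = FALSE] %*% co[-1]))
    },
    lda = {
      kept <- attr(object$fit, "kept_features")
      predict(object$fit, x[, kept, drop = FALSE])$posterior[, "1"]
    },
    svm = {
      pred <- predict(object$fit, x, decision.values = TRUE)
      dv <- drop(attr(pred, "decision.values"))
      # orient toward class "1": e1071 reports "a/b" meaning positive favours a
      if (startsWith(colnames(attr(pred, "decision.values"))[1], "1")) dv else -dv
    },
    rf = predict(object$fit, as.data.frame(x), num.threads = 1)$predictions[, "1"],
    xgboost = predict(object$fit, xgboost::xgb.DMatrix(x))
  )
  score <- unname(as.numeric(score))
  if (type == "score") return(score)
  if (object$model == "svm") as.integer(score > 0) else as.integer(score >= 0.5)
}

#' Raw feature importances of a fitted classifier
#'
#' Absolute coefficients for logistic/LDA/linear-SVM, impurity importance
#' for the random forest, gain for XGBoost. Every requested feature appears
#' (zero when the learner never used it).
#'
#' @param object An `"mm_classifier"`.
#' @return Tibble `feature`, `importance` in the fitted feature order.
#' @export
feature_importance <- function(object) {
  stopifnot(inherits(object, "mm_classifier"))
  feats <- object$features
  imp <- switch(object$model,
    logistic = abs(coef(object$fit)[-1]),
    lda = abs(object$fit$scaling[, 1]),
    svm = {
      w <- crossprod(object$fit$coefs, object$fit$SV)
      setNames(abs(drop(w)), colnames(object$fit$SV))
    },
    rf = ranger::importance(object$fit),
    xgboost = {
      tab <- xgboost::xgb.importance(model = object$fit)
      setNames(tab$Gain, tab$Feature)
    }
  )
  vals <- setNames(numeric(length(feats)), feats)
  common <- intersect(names(imp), feats)
  vals[common] <- imp[common]
  vals[!is.finite(vals)] <- 0
  tibble::tibble(feature = feats, importance = unname(vals))
}
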