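# Cross-model feature-importance ranking: min-max normalization per model,
# aggregation across models, top-k selection.

#' Rank features across models
#'
#' Each model's raw importances are min-max normalized to `[0, 1]` (a
#' constant importance vector normalizes to all zeros and is flagged), then
#' aggregated across models -- by mean normalized importance (default) or by
#' mean rank. The top `k` features by aggregate (ties broken by feature name)
#' are marked selected.
#'
#' @param importances Tibble with columns `model`, `feature`, `importance`
#'   (e.g. the `importance` component of [run_experiment()]'s report, or a
#'   row-bound set of [feature_importance()] results with a `model` column).
#' @param k Number of features to select.
#' @param method `"minmax_mean"` or `"rank_mean"`.
#' @return A `"feature_ranking"` object: tibble `feature`, `aggregate`,
#'   `rank`, `selected`, with attributes `normalized` (per-model table),
#'   `selected` (character vector) and `flags`.
#' @export
rank_features <- function(importances, k = 5, method = c("minmax_mean", "rank_mean")) {
  method <- match.arg(method)
  stopifnot(all(c("model", "feature", "importance") %in% names(importances)),
            k >= 1)
  flags <- character()
  norm <- importances |>
    dplyr::group_by(.data$model, .data$feature) |>
    dplyr::summarise(importance = mean(.data$importance), .groups = "drop") |>
    dplyr::group_by(.data$model) |>
    dplyr::mutate(
      normalized = {
        rng <- range(.data$importance)
        if (diff(rng) == 0) rep(0, dplyr::n())
        else (.data$importance - rng[1]) / diff(rng)
      },
      rank_in_model = rank(-.data$importance, ties.method = "average")
    ) |>
    dplyr::ungroup()
  constant <- norm |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(const = all(.data$normalized == 0), .groups = "drop")
  if (any(constant$const)) {
    flags <- c(flags, paste0("constant_importance:",
                             constant$model[constant$const]))
  }
  agg <- norm |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(
      aggregate = if (method == "minmax_mean") mean(.data$normalized)
                  else -mean(.data$rank_in_model),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$aggregate), .data$feature) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  selected = dplyr::row_number() <= k)
  if (k > nrow(agg)) abort("k exceeds the number of distinct features.")
  structure(agg,
            class = c("feature_ranking", class(agg)),
            normalized = norm,
            selected = agg$feature[agg$selected],
            flags = flags)
}

#' Selected feature names of a ranking
#'
#' @param ranking A `"feature_ranking"` object.
#' @return Character vector of the selected (top-k) feature names.
#' @export
selected_features <- function(ranking) {
  stopifnot(inherits(ranking, "feature_ranking"))
  attr(ranking, "selected")
}

#' Plot a feature-importance ranking
#'
#' Horizontal bar chart of aggregate normalized importance, selected
#' features highlighted.
#'
#' @param object A `"feature_ranking"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot feature_ranking
#' @export
autoplot.feature_ranking <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$aggregate,
    y = stats::reorder(.data$feature, .data$aggregate),
    fill = .data$selected
  )) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey60")) +
    ggplot2::labs(x = "Mean min-max normalized importance", y = NULL) +
    ggplot2::theme_minimal()
}
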