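#' Bar chart of the feature-ranking table
#'
#' Mirrors the standard presentation of resampling-based feature relevance:
#' one bar per feature, grouped by emotion domain, whose height is the
#' percentage of resamplings in which the feature ranked in the top-k of a
#' sufficiently accurate classifier.
#'
#' @param ranking A [rank_features()] table, or a named list of them (e.g.
#'   `list(female = ..., male = ...)`) to facet by model.
#' @return A ggplot object.
#' @export
plot_feature_ranking <- function(ranking) {
  if (!inherits(ranking, "ranking_table") && is.list(ranking)) {
    ranking <- dplyr::bind_rows(lapply(ranking, tibble::as_tibble),
                                .id = "model")
  } else {
    ranking <- tibble::as_tibble(ranking)
  }
  ranking$feature_id <- factor(ranking$feature_id, levels = schema_ids())
  p <- ggplot2::ggplot(ranking,
                       ggplot2::aes(x = .data$feature_id,
                                    y = .data$percentage,
                                    fill = .data$domain)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of resamplings in top-5 at wACC ≥ 0.6",
                  fill = "Domain") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
  if ("model" %in% names(ranking)) {
    p <- p + ggplot2::facet_wrap(~model, ncol = 1)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @rdname plot_feature_ranking
#' @param object,... An object to plot; passed on.
#' @method autoplot ranking_table
#' @export
autoplot.ranking_table <- function(object, ...) plot_feature_ranking(object)

#' Relevance profile of a single fitted model
#' @param object An `angle_gmlvq` model.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot angle_gmlvq
#' @export
autoplot.angle_gmlvq <- function(object, ...) {
  td <- tidy(object)
  td$feature_id <- factor(td$feature_id, levels = td$feature_id)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$feature_id,
                                   y = .data$relevance,
                                   fill = .data$domain)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Normalized relevance", fill = "Domain") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Distribution of test metrics across resamplings
#'
#' @param ... Named [holdout_resample()] tibbles, e.g.
#'   `female = res_f, male = res_m`.
#' @param metrics Metric columns to show.
#' @return A ggplot object (boxplots per metric and model).
#' @export
plot_metric_distributions <- function(...,
                                      metrics = c("wacc", "ppv", "npv",
                                                  "tpr", "tnr")) {
  inputs <- list(...)
  if (is.null(names(inputs)) || any(names(inputs) == "")) {
    names(inputs) <- paste0("model_", seq_along(inputs))
  }
  long <- dplyr::bind_rows(
    lapply(inputs, function(r) {
      tidyr::pivot_longer(tibble::as_tibble(r)[metrics],
                          dplyr::all_of(metrics),
                          names_to = "metric", values_to = "value")
    }), .id = "model")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value,
                                     fill = .data$model)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, position = "dodge") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Test-set value", fill = NULL) +
    ggplot2::theme_minimal()
}
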