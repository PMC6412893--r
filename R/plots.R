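#' Plot an evaluation report as a confusion heatmap
#'
#' @param object A `har_eval` from [macro_prf()].
#' @param normalize Show row-normalised proportions instead of counts.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot har_eval
#' @export
autoplot.har_eval <- function(object, normalize = TRUE, ...) {
  cm <- object$confusion
  if (normalize) {
    rs <- rowSums(cm)
    rs[rs == 0] <- 1
    cm <- cm / rs
  }
  df <- tibble::as_tibble(as.table(cm), .name_repair = ~ c("truth", "prediction", "value"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$prediction, y = .data$truth,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$value >= 0.01 | !normalize,
                     sprintf(if (normalize) "%.2f" else "%.0f", .data$value), "")),
      colour = "white", size = 3) +
    ggplot2::scale_y_discrete(limits = rev(rownames(object$confusion))) +
    ggplot2::labs(x = "Predicted activity", y = "True activity",
                  fill = if (normalize) "Proportion" else "Count") +
    ggplot2::theme_minimal()
}

#' Plot SDAE training loss curves
#'
#' @param object An `sdae` from [build_stack()] / [fine_tune_stack()].
#' @param ... Unused.
#' @return A ggplot object of reconstruction loss per epoch, one panel
#'   per pretraining layer plus the fine-tuning stage.
#' @method autoplot sdae
#' @export
autoplot.sdae <- function(object, ...) {
  df <- tidy.sdae(object)
  df$panel <- ifelse(df$stage == "pretrain", paste0("layer ", df$layer),
                     "fine-tune")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "Epoch", y = "Reconstruction MSE") +
    ggplot2::theme_minimal()
}

#' Distribution of one learned feature across activity classes
#'
#' A diagnostic of single-feature class separability: the per-class
#' empirical distribution of one column of the feature matrix.
#'
#' @param features A `har_features` tibble.
#' @param feature Column index (or name) of the feature to plot.
#' @param bins Histogram bin count.
#' @return A ggplot object.
#' @export
plot_feature_distribution <- function(features, feature = 1, bins = 40) {
  vals <- features$features[, feature]
  df <- tibble::tibble(value = vals, activity = features$activity)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, fill = .data$activity)) +
    ggplot2::geom_histogram(bins = bins, position = "identity", alpha = 0.5) +
    ggplot2::labs(x = sprintf("Feature %s", as.character(feature)),
                  y = "Window count", fill = "Activity") +
    ggplot2::theme_minimal()
}

#' Plot the separability report
#'
#' @param object A `har_divergence` from [divergence_report()].
#' @param ... Unused.
#' @return A ggplot bar chart of inner/outer scatter traces per space.
#' @method autoplot har_divergence
#' @export
autoplot.har_divergence <- function(object, ...) {
  df <- tidyr::pivot_longer(object$totals, c("inner_trace", "outer_trace"),
                            names_to = "kind", values_to = "trace")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$space, y = .data$trace,
                                   fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Scatter-matrix trace", fill = NULL) +
    ggplot2::theme_minimal()
}
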