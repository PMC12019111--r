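#' Plot an explained-variance curve with its elbow
#'
#' @param object Tibble from [explained_variance_curve()].
#' @param gain_threshold Threshold handed to [select_k_elbow()] for the
#'   marked elbow.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot statedyn_ev
#' @export
autoplot.statedyn_ev <- function(object, gain_threshold = 0.01, ...) {
  k_star <- suppressWarnings(select_k_elbow(object, gain_threshold))
  ggplot2::ggplot(object, ggplot2::aes(.data$k, .data$explained_variance)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = as.numeric(k_star), linetype = 2,
                        color = "firebrick") +
    ggplot2::labs(x = "number of states (k)", y = "explained variance",
                  title = sprintf("Elbow at k = %d", k_star)) +
    ggplot2::theme_minimal()
}

#' Heatmap of state centroids
#'
#' @param object A `state_kmeans` fit.
#' @param templates Optional templates to order ROIs by network.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot state_kmeans
#' @export
autoplot.state_kmeans <- function(object, templates = NULL, ...) {
  td <- tidy(object, templates = templates)
  td$roi <- factor(td$roi, levels = unique(td$roi))
  ggplot2::ggplot(td, ggplot2::aes(.data$roi, .data$state_name,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", high = "firebrick",
                                  mid = "white") +
    ggplot2::labs(x = "ROI", y = "state", fill = "amplitude") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Histogram of the bootstrap indirect-effect distribution
#'
#' @param object A `mediation_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mediation_result
#' @export
autoplot.mediation_result <- function(object, ...) {
  df <- tibble::tibble(ab = object$boot_indirect)
  ggplot2::ggplot(df, ggplot2::aes(.data$ab)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", color = "grey30") +
    ggplot2::geom_vline(xintercept = c(object$ci_low, object$ci_high),
                        linetype = 2) +
    ggplot2::geom_vline(xintercept = object$indirect, color = "firebrick") +
    ggplot2::labs(x = "bootstrap indirect effect (a x b)", y = "count") +
    ggplot2::theme_minimal()
}

#' Condition comparison of one dynamic metric across states
#'
#' @param metrics Tidy tibble from [dynamic_metrics()].
#' @param metric Which metric to plot.
#' @return A ggplot (boxplots of per-scan values by state and condition).
#' @export
plot_metric_contrast <- function(metrics, metric = "dwell_time") {
  df <- dplyr::filter(metrics, .data$metric == !!metric)
  ggplot2::ggplot(df, ggplot2::aes(.data$state_name, .data$value,
                                   fill = .data$condition)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = "state", y = metric, fill = "condition") +
    ggplot2::theme_minimal()
}
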