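# ggplot2 displays of prints, t-fields, clusters and ROC curves.

#' @importFrom ggplot2 ggplot aes geom_raster geom_tile geom_line geom_abline
#'   scale_fill_viridis_c scale_fill_gradient2 coord_fixed labs theme_minimal
#'   autoplot
NULL

#' @export
ggplot2::autoplot

#' Plot a peak-pressure print
#'
#' @param object A `peak_print`.
#' @param ... Unused.
#' @return A ggplot raster of the pressure image (kPa).
#' @method autoplot peak_print
#' @export
autoplot.peak_print <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$col, y = .data$row,
                 fill = .data$pressure_kpa)) +
    geom_raster() +
    scale_fill_viridis_c(name = "kPa") +
    coord_fixed() +
    ggplot2::scale_y_reverse() +
    labs(title = sprintf("Peak pressure, foot %s (%s)", object$foot_id,
                         object$condition),
         x = "sensel column", y = "sensel row") +
    theme_minimal()
}

#' Plot a t-field
#'
#' @param object A `t_field`.
#' @param threshold Optional |t| threshold; values below are blanked, which
#'   turns the raw map into a thresholded cluster map.
#' @param ... Unused.
#' @return A ggplot: blue = lower pressure after trimming, red = higher.
#' @method autoplot t_field
#' @export
autoplot.t_field <- function(object, threshold = NULL, ...) {
  df <- tidy(object)
  if (!is.null(threshold)) df <- filter(df, abs(.data$t) > threshold)
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$t)) +
    geom_tile() +
    scale_fill_gradient2(low = "blue3", mid = "grey92", high = "red3",
                         name = "t") +
    coord_fixed() +
    ggplot2::scale_y_reverse() +
    labs(title = if (is.null(threshold)) "Pixel-level t statistics"
         else sprintf("Supra-threshold pixels (|t| > %.2f)", threshold),
         x = "sensel column", y = "sensel row") +
    theme_minimal()
}

#' Figure panels for one foot's topographic comparison
#'
#' Builds the four standard panels: mean before-trimming map, mean
#' after-trimming map (kPa), the raw t-map and the thresholded cluster map.
#'
#' @param t_field A `t_field`.
#' @param cluster_result The matching `cluster_result`.
#' @param alpha Cluster-level significance threshold used in the title.
#' @return Named list of ggplots: `mean_before`, `mean_after`, `t_map`,
#'   `cluster_map`.
#' @export
plot_foot_panels <- function(t_field, cluster_result, alpha = 0.05) {
  df <- tidy(t_field)
  mean_panel <- function(col, ttl) {
    ggplot(df, aes(x = .data$col, y = .data$row, fill = .data[[col]])) +
      geom_raster() +
      scale_fill_viridis_c(name = "kPa") +
      coord_fixed() + ggplot2::scale_y_reverse() +
      labs(title = ttl, x = "sensel column", y = "sensel row") +
      theme_minimal()
  }
  list(
    mean_before = mean_panel("mean_before_kpa", "Mean peak pressure, before"),
    mean_after = mean_panel("mean_after_kpa", "Mean peak pressure, after"),
    t_map = autoplot(t_field),
    cluster_map = autoplot(t_field, threshold = cluster_result$threshold) +
      labs(subtitle = sprintf("%d cluster(s); %d with p < %g",
                              nrow(cluster_result$clusters),
                              sum(cluster_result$clusters$p_value < alpha),
                              alpha))
  )
}

#' ROC curve of a model evaluation
#'
#' @param object A `model_eval` (from [evaluate_model()]); scores and
#'   labels stored with the evaluation supply the curve.
#' @param ... Unused.
#' @return A ggplot ROC curve annotated with the AUROC and its CI.
#' @method autoplot model_eval
#' @export
autoplot.model_eval <- function(object, ...) {
  roc <- pROC::roc(response = object$labels, predictor = object$scores,
                   levels = c(0, 1), direction = "<", quiet = TRUE)
  df <- tibble(sensitivity = 100 * roc$sensitivities,
               specificity = 100 * roc$specificities)
  ggplot(df, aes(x = 100 - .data$specificity, y = .data$sensitivity)) +
    geom_line(colour = "steelblue", linewidth = 0.8) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    labs(title = sprintf("ROC: AUROC %.2f (95%% CI %.2f; %.2f)",
                         object$auroc$auroc, object$auroc$lower,
                         object$auroc$upper),
         x = "100 - specificity (%)", y = "sensitivity (%)") +
    theme_minimal()
}
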