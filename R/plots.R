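#' Plot a swarm convergence trace
#'
#' Best and mean fitness per iteration on a log fitness scale.
#'
#' @param object A `"pso_result"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pso_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history,
                              c("best_fitness", "mean_fitness"),
                              names_to = "series", values_to = "fitness")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$fitness,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Iteration", y = "Fitness (MSE)", colour = NULL,
                  title = "Swarm convergence") +
    ggplot2::theme_minimal()
}

#' Plot one-vs-rest ROC and precision-recall curves
#'
#' @param object A `"curve_set"` from [roc_pr_curves()].
#' @param ... Unused.
#' @return A ggplot object, one facet per curve type.
#' @export
autoplot.curve_set <- function(object, ...) {
  pts <- object$points
  pts$curve <- factor(pts$curve, c("roc", "pr"),
                      c("ROC (FPR vs TPR)", "Precision-Recall"))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y,
                                    colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$curve)) +
    ggplot2::labs(x = NULL, y = NULL, colour = "Class",
                  title = "One-vs-rest curves") +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix heatmap
#'
#' @param object A `"confusion_matrix"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object)))
  names(df) <- c("true", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(title = "Confusion matrix") +
    ggplot2::theme_minimal()
}

#' Plot the training trace of a fitted hybrid model
#'
#' @param object An `"ann_pso"` model.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ann_pso <- function(object, ...) {
  autoplot.pso_result(list(history = object$history))
}

#' Plot permutation feature importances
#'
#' @param importance Tibble from [permutation_importance()].
#' @param top_n Show the `top_n` most important features (default all).
#' @return A ggplot object.
#' @export
plot_importance <- function(importance, top_n = nrow(importance)) {
  df <- head(importance, top_n)
  df$feature <- factor(df$feature, rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$importance, y = .data$feature)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$importance - .data$sd,
                                         xmax = .data$importance + .data$sd),
                            height = 0.25, na.rm = TRUE) +
    ggplot2::labs(x = "Metric drop when shuffled", y = NULL,
                  title = "Permutation feature importance") +
    ggplot2::theme_minimal()
}
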