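#' Tidy a fitted hybrid model
#'
#' Per-class test-set metrics in long-friendly form, one row per class.
#'
#' @param x An `"ann_pso"` model.
#' @param which `"test"` (default) or `"validation"`.
#' @param ... Unused.
#' @return A tibble with `class`, `precision`, `recall`, `f1`, `support`.
#' @export
tidy.ann_pso <- function(x, which = c("test", "validation"), ...) {
  which <- match.arg(which)
  rep <- if (which == "test") x$test else x$validation
  dplyr::select(rep$per_class, "class", "precision", "recall", "f1", "support")
}

#' Glance at a fitted hybrid model
#'
#' @param x An `"ann_pso"` model.
#' @param ... Unused.
#' @return A one-row tibble: test/validation accuracy, macro F1, final
#'   training fitness, parameter count and iterations.
#' @export
glance.ann_pso <- function(x, ...) {
  tibble::tibble(
    accuracy = x$test$accuracy,
    macro_f1 = x$test$macro$f1,
    validation_accuracy = x$validation$accuracy,
    train_fitness = x$best_fitness,
    n_parameters = param_count(x$spec),
    iterations = x$config$pso$k_max
  )
}

#' Tidy a swarm optimization trace
#'
#' @param x A `"pso_result"`.
#' @param ... Unused.
#' @return The history tibble (`iteration`, `best_fitness`,
#'   `mean_fitness`).
#' @export
tidy.pso_result <- function(x, ...) x$history

#' @rdname tidy.pso_result
#' @export
glance.pso_result <- function(x, ...) {
  tibble::tibble(best_fitness = x$best_fitness,
                 iterations = x$config$k_max,
                 n_particles = x$config$n_particles,
                 dim = length(x$best_position))
}

#' Tidy a classification report
#'
#' @param x A `"classification_report"`.
#' @param ... Unused.
#' @return The per-class metric tibble.
#' @export
tidy.classification_report <- function(x, ...) x$per_class

#' @rdname tidy.classification_report
#' @export
glance.classification_report <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy,
                 macro_precision = x$macro$precision,
                 macro_recall = x$macro$recall,
                 macro_f1 = x$macro$f1, n = x$n)
}

#' Tidy a curve set
#'
#' @param x A `"curve_set"`.
#' @param ... Unused.
#' @return The curve points tibble.
#' @export
tidy.curve_set <- function(x, ...) x$points

#' @rdname tidy.curve_set
#' @export
glance.curve_set <- function(x, ...) {
  tibble::tibble(macro_roc_auc = x$macro_roc_auc,
                 macro_pr_auc = x$macro_pr_auc)
}
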