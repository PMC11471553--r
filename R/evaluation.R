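#' Confusion matrix
#'
#' Rows are true classes, columns predicted classes; entry (i, j) counts
#' records with true class i predicted as class j.
#'
#' @param y_true,y_pred Integer labels in `1..n_classes`, equal length.
#' @param n_classes Number of classes, default 7.
#' @param class_names Optional class names for dimnames.
#' @return An integer matrix of class `"confusion_matrix"`.
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes = 7,
                             class_names = NULL) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) abort("`y_true` and `y_pred` must have equal length.")
  if (any(c(y_true, y_pred) < 1 | c(y_true, y_pred) > n_classes)) {
    abort("Labels out of 1..n_classes range.")
  }
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(y_true)) {
    cm[y_true[i], y_pred[i]] <- cm[y_true[i], y_pred[i]] + 1L
  }
  if (is.null(class_names)) class_names <- paste0("class_", seq_len(n_classes))
  dimnames(cm) <- list(true = class_names, predicted = class_names)
  class(cm) <- c("confusion_matrix", "matrix")
  cm
}

#' Classification report
#'
#' Per-class precision `tp / (tp + fp)`, recall `tp / (tp + fn)` and F1
#' `2PR / (P + R)`, plus overall accuracy (`trace / total`) and macro
#' (unweighted mean) aggregates. A zero denominator yields a metric of 0
#' with `undefined = TRUE` for that class. For single-label multiclass
#' data, micro-averaged precision and recall both equal the accuracy.
#'
#' @param cm A [confusion_matrix()].
#' @return An object of class `"classification_report"`: list with
#'   `per_class` tibble (`class`, `precision`, `recall`, `f1`,
#'   `support`, `undefined`), `accuracy`, `macro` (named list), `n`.
#' @export
classification_report <- function(cm) {
  if (!inherits(cm, "confusion_matrix")) {
    cm0 <- as.matrix(cm)
    if (nrow(cm0) != ncol(cm0)) abort("Confusion matrix must be square.")
    class(cm0) <- c("confusion_matrix", "matrix")
    cm <- cm0
  }
  m <- unclass(cm)
  total <- sum(m)
  if (total == 0) abort("Empty confusion matrix.")
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  undefined <- (tp + fp == 0) | (tp + fn == 0)
  per_class <- tibble::tibble(
    class = rownames(m) %||% paste0("class_", seq_len(nrow(m))),
    precision = unname(precision), recall = unname(recall),
    f1 = unname(f1), support = unname(rowSums(m)),
    undefined = unname(undefined)
  )
  structure(list(
    per_class = per_class,
    accuracy = sum(tp) / total,
    macro = list(precision = mean(precision), recall = mean(recall),
                 f1 = mean(f1)),
    n = total, cm = cm
  ), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> n=%d accuracy=%.4f macro-F1=%.4f\n",
              x$n, x$accuracy, x$macro$f1))
  print(x$per_class)
  invisible(x)
}

# One-vs-rest ROC points at every distinct score threshold, plus the
# (0,0) and (1,1) anchors; trapezoidal AUC.
binary_roc <- function(truth, score) {
  ord <- order(score, decreasing = TRUE)
  truth <- truth[ord]; score <- score[ord]
  n_pos <- sum(truth); n_neg <- sum(!truth)
  tp <- cumsum(truth); fp <- cumsum(!truth)
  last <- !duplicated(score, fromLast = TRUE)  # one point per distinct score
  pts <- tibble::tibble(threshold = score[last],
                        x = fp[last] / n_neg, y = tp[last] / n_pos)
  pts <- dplyr::bind_rows(tibble::tibble(threshold = Inf, x = 0, y = 0), pts)
  if (pts$x[nrow(pts)] < 1 || pts$y[nrow(pts)] < 1) {
    pts <- dplyr::bind_rows(pts, tibble::tibble(threshold = -Inf, x = 1, y = 1))
  }
  auc <- sum(diff(pts$x) * (head(pts$y, -1) + tail(pts$y, -1)) / 2)
  list(points = pts, auc = auc)
}

binary_pr <- function(truth, score) {
  ord <- order(score, decreasing = TRUE)
  truth <- truth[ord]; score <- score[ord]
  n_pos <- sum(truth)
  tp <- cumsum(truth); pred_pos <- seq_along(truth)
  last <- !duplicated(score, fromLast = TRUE)
  pts <- tibble::tibble(threshold = score[last],
                        x = tp[last] / n_pos,          # recall
                        y = tp[last] / pred_pos[last]) # precision
  # anchor at recall 0 with the first observed precision
  pts <- dplyr::bind_rows(tibble::tibble(threshold = Inf, x = 0, y = pts$y[1]), pts)
  auc <- sum(diff(pts$x) * (head(pts$y, -1) + tail(pts$y, -1)) / 2)
  list(points = pts, auc = auc)
}

#' One-vs-rest ROC and precision-recall curves
#'
#' For each class, the class-probability column is scored against the
#' binary indicator "true class == this class" at every distinct
#' threshold; AUCs are trapezoidal. The macro AUC is the unweighted mean
#' over classes present in `y_true`; a class absent from `y_true` is
#' skipped with a warning.
#'
#' @param y_true Integer labels in `1..ncol(probs)`.
#' @param probs Matrix of class probabilities (rows sum to 1).
#' @param class_names Optional class names.
#' @return An object of class `"curve_set"`: list with `points` (tibble
#'   `class`, `curve` ("roc"/"pr"), `threshold`, `x`, `y`), `auc`
#'   (tibble `class`, `roc_auc`, `pr_auc`), `macro_roc_auc`,
#'   `macro_pr_auc`.
#' @export
roc_pr_curves <- function(y_true, probs, class_names = NULL) {
  probs <- as.matrix(probs)
  y_true <- as.integer(y_true)
  k <- ncol(probs)
  if (is.null(class_names)) class_names <- paste0("class_", seq_len(k))
  present <- sort(unique(y_true))
  skipped <- setdiff(seq_len(k), present)
  if (length(skipped) > 0) {
    warn(paste0("Class(es) absent from y_true, skipped: ",
                paste(class_names[skipped], collapse = ", ")))
  }
  res <- purrr::map(present, function(cls) {
    truth <- y_true == cls
    roc <- binary_roc(truth, probs[, cls])
    pr <- binary_pr(truth, probs[, cls])
    list(points = dplyr::bind_rows(
      dplyr::mutate(roc$points, class = class_names[cls], curve = "roc"),
      dplyr::mutate(pr$points, class = class_names[cls], curve = "pr")),
      auc = tibble::tibble(class = class_names[cls],
                           roc_auc = roc$auc, pr_auc = pr$auc))
  })
  auc <- purrr::map_dfr(res, "auc")
  structure(list(
    points = purrr::map_dfr(res, "points")[, c("class", "curve", "threshold", "x", "y")],
    auc = auc,
    macro_roc_auc = mean(auc$roc_auc),
    macro_pr_auc = mean(auc$pr_auc)
  ), class = "curve_set")
}

#' @export
print.curve_set <- function(x, ...) {
  cat(sprintf("<curve_set> macro ROC-AUC=%.4f macro PR-AUC=%.4f\n",
              x$macro_roc_auc, x$macro_pr_auc))
  print(x$auc)
  invisible(x)
}

#' Permutation feature importance
#'
#' Model-agnostic attribution: the drop in a performance metric when one
#' feature column is shuffled, averaged over `n_repeats` shuffles, with
#' the shuffle standard deviation. Used here as the interpretability
#' stand-in for game-theoretic attribution.
#'
#' @param model A fitted `"ann_pso"` model, or any function mapping a
#'   feature matrix to predicted integer labels.
#' @param X Feature matrix (already engineered/scaled when `model` is a
#'   bare function; raw schema records when it is an `"ann_pso"`).
#' @param y True integer labels.
#' @param metric `"accuracy"` (default) or `"macro_f1"`.
#' @param n_repeats Shuffles per feature, default 10.
#' @param seed Optional integer seed.
#' @return A tibble `feature`, `importance`, `sd`, sorted by decreasing
#'   importance, with the baseline metric as attribute `"baseline"`.
#' @export
permutation_importance <- function(model, X, y,
                                   metric = c("accuracy", "macro_f1"),
                                   n_repeats = 10, seed = NULL) {
  metric <- match.arg(metric)
  if (inherits(model, "ann_pso")) {
    X <- prepare_features(model, X)
    obj <- model
    predict_fun <- function(M) {
      predict_class(forward_pass(obj$spec, obj$weights, M))
    }
  } else {
    predict_fun <- model
    X <- as.matrix(X)
  }
  y <- as.integer(y)
  n_classes <- max(y)
  score <- function(pred) {
    cm <- confusion_matrix(y, pred, n_classes = max(n_classes, max(pred)))
    rep <- classification_report(cm)
    if (metric == "accuracy") rep$accuracy else rep$macro$f1
  }
  baseline <- score(predict_fun(X))
  res <- with_seed_if(seed, {
    purrr::map_dfr(colnames(X) %||% as.character(seq_len(ncol(X))), function(f) {
      j <- if (is.null(colnames(X))) as.integer(f) else which(colnames(X) == f)
      drops <- purrr::map_dbl(seq_len(n_repeats), function(r) {
        Xp <- X
        Xp[, j] <- X[sample.int(nrow(X)), j]
        baseline - score(predict_fun(Xp))
      })
      tibble::tibble(feature = as.character(f),
                     importance = mean(drops), sd = stats::sd(drops))
    })
  })
  res <- dplyr::arrange(res, dplyr::desc(.data$importance))
  attr(res, "baseline") <- baseline
  res
}
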