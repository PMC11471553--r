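# Independent oracle implementations, deliberately written with naive
# per-record loops so they share no code path with the package.

oracle_report <- function(y_true, y_pred, n_classes) {
  res <- data.frame(class = seq_len(n_classes), precision = 0, recall = 0, f1 = 0)
  for (c0 in seq_len(n_classes)) {
    tp <- fp <- fn <- 0
    for (i in seq_along(y_true)) {
      if (y_pred[i] == c0 && y_true[i] == c0) tp <- tp + 1
      if (y_pred[i] == c0 && y_true[i] != c0) fp <- fp + 1
      if (y_pred[i] != c0 && y_true[i] == c0) fn <- fn + 1
    }
    res$precision[c0] <- if (tp + fp > 0) tp / (tp + fp) else 0
    res$recall[c0] <- if (tp + fn > 0) tp / (tp + fn) else 0
    pr <- res$precision[c0]; rc <- res$recall[c0]
    res$f1[c0] <- if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
  }
  res$accuracy <- mean(y_true == y_pred)
  res
}

# Exhaustive threshold sweep for a one-vs-rest ROC curve; trapezoidal AUC.
oracle_roc_auc <- function(truth, score) {
  ths <- sort(unique(score), decreasing = TRUE)
  xs <- 0; ys <- 0
  for (t in ths) {
    pred_pos <- score >= t
    xs <- c(xs, sum(pred_pos & !truth) / sum(!truth))
    ys <- c(ys, sum(pred_pos & truth) / sum(truth))
  }
  if (xs[length(xs)] < 1 || ys[length(ys)] < 1) { xs <- c(xs, 1); ys <- c(ys, 1) }
  sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)
}

oracle_pr_auc <- function(truth, score) {
  ths <- sort(unique(score), decreasing = TRUE)
  rec <- 0; prec <- NULL
  for (t in ths) {
    pred_pos <- score >= t
    rec <- c(rec, sum(pred_pos & truth) / sum(truth))
    prec <- c(prec, sum(pred_pos & truth) / sum(pred_pos))
  }
  prec <- c(prec[1], prec)
  sum(diff(rec) * (head(prec, -1) + tail(prec, -1)) / 2)
}

# Small schema-conformant tibble built in code (no fixture files).
toy_records <- function(n = 12, seed = 99) {
  generate_obesity_data(n_records = n, seed = seed)
}

# Cheap trainer settings for structural tests (not the benchmark).
fast_pso <- function(seed = 1, k_max = 15) {
  pso_config(k_max = k_max, n_particles = 10, bounds = c(-0.25, 0.25),
             r_mode = "dimension", seed = seed)
}
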