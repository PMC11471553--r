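#' SMOTE minority-class oversampling
#'
#' Balances every class up to the majority count by synthesizing new
#' minority records along segments between same-class nearest neighbors:
#' each synthetic row is `x + u * (x_nn - x)` with `u ~ Uniform(0, 1)`
#' and `x_nn` drawn among the `k` nearest same-class neighbors of `x`
#' (Euclidean distance on the feature columns, which should already be
#' scaled). Original rows are preserved verbatim; only the training
#' split should ever be passed here.
#'
#' A class with a single member cannot be interpolated; it falls back to
#' duplication with a small Gaussian jitter and a warning.
#'
#' @param data Data frame of numeric features plus a label column.
#' @param label_col Name of the label column, default `"Obesity_level"`.
#' @param k Number of nearest neighbors, default 5 (capped at class
#'   size minus 1).
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble in which every class count equals the majority
#'   count; original rows first, synthetic rows appended.
#' @export
smote_oversample <- function(data, label_col = "Obesity_level", k = 5,
                             seed = NULL) {
  data <- tibble::as_tibble(data)
  if (!label_col %in% names(data)) {
    abort(paste0("Label column `", label_col, "` not found."))
  }
  if (k < 1) abort("`k` must be at least 1.")
  y <- data[[label_col]]
  feat_cols <- setdiff(names(data), label_col)
  if (!all(vapply(data[feat_cols], is.numeric, logical(1)))) {
    abort("All feature columns must be numeric for SMOTE.")
  }
  counts <- table(y)
  n_target <- max(counts)
  if (all(counts == n_target)) return(data)

  with_seed_if(seed, {
    synth <- purrr::map(names(counts)[counts < n_target], function(cls) {
      idx <- which(y == cls)
      X <- as.matrix(data[idx, feat_cols, drop = FALSE])
      n_new <- n_target - length(idx)
      if (length(idx) == 1) {
        warn(paste0("Class ", cls, " has a single member; duplicating with jitter."))
        base <- X[rep(1, n_new), , drop = FALSE]
        out <- base + matrix(rnorm(n_new * ncol(X), sd = 1e-3), nrow = n_new)
      } else {
        kk <- min(k, nrow(X) - 1)
        d <- as.matrix(stats::dist(X))
        diag(d) <- Inf
        # k same-class nearest neighbors of every class member
        nn_raw <- apply(d, 1, function(row) order(row)[seq_len(kk)])
        nn <- if (kk == 1) matrix(nn_raw, ncol = 1) else t(nn_raw)
        src <- sample.int(nrow(X), n_new, replace = TRUE)
        pick <- nn[cbind(src, sample.int(kk, n_new, replace = TRUE))]
        u <- runif(n_new)
        out <- X[src, , drop = FALSE] + u * (X[pick, , drop = FALSE] - X[src, , drop = FALSE])
      }
      res <- tibble::as_tibble(as.data.frame(out))
      names(res) <- feat_cols
      res[[label_col]] <- rep(data[[label_col]][idx[1]], n_new)
      res
    })
    dplyr::bind_rows(data, dplyr::bind_rows(synth))
  })
}
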