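#' Data split specification
#'
#' 70/15/15 train/validation/test split, stratified by class, with a
#' 10-fold cross-validation default for reporting metric variance.
#'
#' @param train,validation,test Fractions summing to 1.
#' @param stratified Preserve class proportions in each part? Default TRUE.
#' @param cv_folds Folds for [kfold()], default 10.
#' @param seed Optional integer seed.
#' @return An object of class `"split_spec"`.
#' @export
split_spec <- function(train = 0.70, validation = 0.15, test = 0.15,
                       stratified = TRUE, cv_folds = 10, seed = NULL) {
  if (abs(train + validation + test - 1) > 1e-8) {
    abort("Split fractions must sum to 1.")
  }
  if (cv_folds < 2) abort("`cv_folds` must be >= 2.")
  structure(list(train = train, validation = validation, test = test,
                 stratified = stratified, cv_folds = as.integer(cv_folds),
                 seed = seed),
            class = "split_spec")
}

# Allocate n_c items of one class to the three parts: floors first, then
# remainders by largest fractional part (ties favor train > val > test).
allocate_split <- function(n_c, fracs) {
  target <- fracs * n_c
  base <- floor(target)
  rem <- n_c - sum(base)
  if (rem > 0) {
    order_idx <- order(target - base, 3:1, decreasing = TRUE)
    base[order_idx[seq_len(rem)]] <- base[order_idx[seq_len(rem)]] + 1
  }
  base
}

#' Split a dataset into train/validation/test
#'
#' Disjoint and exhaustive; when stratified, each class's proportions
#' are within one record of the global fractions. Stratification needs
#' enough records per class (>= 10); otherwise it falls back to an
#' unstratified split with a warning.
#'
#' @param data A data frame with a label column.
#' @param spec A [split_spec()].
#' @param label_col Label column name, default `"Obesity_level"`.
#' @return A named list of tibbles `train`, `validation`, `test`.
#' @export
split_dataset <- function(data, spec = split_spec(),
                          label_col = "Obesity_level") {
  data <- tibble::as_tibble(data)
  n <- nrow(data)
  fracs <- c(spec$train, spec$validation, spec$test)
  stratified <- isTRUE(spec$stratified)
  if (stratified) {
    if (!label_col %in% names(data)) abort("Label column not found for stratified split.")
    if (min(table(data[[label_col]])) < 10) {
      warn("A class has fewer than 10 records; falling back to unstratified split.")
      stratified <- FALSE
    }
  }
  assignment <- integer(n)
  with_seed_if(spec$seed, {
    if (stratified) {
      for (cls in unique(data[[label_col]])) {
        idx <- sample(which(data[[label_col]] == cls))
        sizes <- allocate_split(length(idx), fracs)
        assignment[idx] <- rep(1:3, times = sizes)
      }
    } else {
      idx <- sample.int(n)
      sizes <- allocate_split(n, fracs)
      assignment[idx] <- rep(1:3, times = sizes)
    }
  })
  list(train = data[assignment == 1, , drop = FALSE],
       validation = data[assignment == 2, , drop = FALSE],
       test = data[assignment == 3, , drop = FALSE])
}

#' Stratified k-fold partition
#'
#' Partitions row indices into `folds` holdout sets of near-equal size
#' (differing by at most one record overall) while preserving class
#' proportions. Fold ids are assigned cyclically within each shuffled
#' class, continuing the cycle across classes so global fold sizes stay
#' balanced.
#'
#' @param data Data frame (or an integer row count).
#' @param folds Number of folds, default 10.
#' @param seed Optional integer seed.
#' @param label_col Label column for stratification; `NULL` for plain
#'   k-fold.
#' @return A list of `folds` elements, each `list(fit = , holdout = )`
#'   integer index vectors.
#' @export
kfold <- function(data, folds = 10, seed = NULL,
                  label_col = "Obesity_level") {
  n <- if (is.numeric(data) && length(data) == 1) as.integer(data) else nrow(data)
  if (n < folds) abort("Fewer records than folds.")
  y <- if (!is.numeric(data) && !is.null(label_col) &&
           label_col %in% names(data)) data[[label_col]] else rep(1L, n)
  fold_id <- integer(n)
  with_seed_if(seed, {
    offset <- 0L
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold_id[idx] <- ((offset + seq_along(idx) - 1L) %% folds) + 1L
      offset <- offset + length(idx)
    }
  })
  purrr::map(seq_len(folds), function(f) {
    list(fit = which(fold_id != f), holdout = which(fold_id == f))
  })
}

#' Build the swarm fitness from a network and training data
#'
#' Returns the pure function `vector -> mse_loss(forward(spec, vector,
#' X), one_hot(y))`: the mean squared error of the network's softmax
#' outputs against one-hot targets on the training split, which the
#' swarm minimizes.
#'
#' @param spec A [network_spec()].
#' @param X Numeric training feature matrix.
#' @param y Integer training labels in `1..n_out`.
#' @return A function of one numeric vector.
#' @export
make_fitness <- function(spec, X, y) {
  X <- as.matrix(X)
  targets <- one_hot(y, spec$sizes[length(spec$sizes)])
  function(vector) mse_loss(forward_pass(spec, vector, X), targets)
}

# Feature matrix + label vector from an engineered data frame.
as_feature_matrix <- function(data, label_col = "Obesity_level") {
  feat <- setdiff(names(data), label_col)
  list(X = as.matrix(data[feat]), y = as.integer(data[[label_col]]),
       features = feat)
}

evaluate_weights <- function(spec, weights, data, label_col = "Obesity_level") {
  fm <- as_feature_matrix(data, label_col)
  probs <- forward_pass(spec, weights, fm$X)
  pred <- predict_class(probs)
  cm <- confusion_matrix(fm$y, pred, n_classes = spec$sizes[length(spec$sizes)])
  list(report = classification_report(cm), probs = probs, pred = pred,
       y = fm$y)
}

#' Train the hybrid network-swarm classifier
#'
#' The full training procedure: clean the records, engineer features,
#' drop height, split 70/15/15 (stratified), fit the min-max scaler on
#' the training split only, balance the training split with SMOTE,
#' then run particle swarm optimization over the flattened network
#' weights with the training MSE as fitness. The global best at the
#' final iteration is the model; validation and test metrics are
#' reported. Reproducible end-to-end given the seeds in the configs.
#'
#' @param data Schema-conformant data frame (e.g. from
#'   [generate_obesity_data()] or [read_obesity_csv()]).
#' @param hidden Hidden layer widths, default `c(128, 64, 32)`.
#' @param pso A [pso_config()]. The trainer's default differs from the
#'   optimizer's generic default in two documented ways suited to
#'   network-weight search: stochastic factors are drawn per dimension
#'   (`r_mode = "dimension"`), and the position box is `[-0.25, 0.25]`
#'   -- a weight scale matched to min-max scaled inputs that keeps the
#'   softmax away from saturation, where the MSE landscape is flat.
#' @param split A [split_spec()].
#' @param features A [feature_config()].
#' @param clean Run [clean_records()] first? Default TRUE.
#' @param cv Also run per-fold swarm refits on the training split to
#'   report cross-validated metric variance? Default FALSE (each fold
#'   repeats the full optimization).
#' @param restarts Independent swarm runs; the one with the best final
#'   training fitness is kept (standard multi-start practice for
#'   stochastic optimizers). Default 2. Restart seeds are derived
#'   deterministically from the swarm seed.
#' @param loss `"mse"` (default, the swarm fitness) or `"cross_entropy"`.
#' @param label_col Label column name.
#' @return An object of class `"ann_pso"`: trained weights, network
#'   spec, swarm history, validation/test reports, scalers and config
#'   snapshot. Methods: [predict.ann_pso()], [tidy()], [glance()],
#'   [autoplot.ann_pso()].
#' @export
train_ann_pso <- function(data,
                          hidden = c(128, 64, 32),
                          pso = pso_config(r_mode = "dimension",
                                           bounds = c(-0.25, 0.25)),
                          split = split_spec(),
                          features = feature_config(),
                          clean = TRUE,
                          cv = FALSE,
                          restarts = 2,
                          loss = c("mse", "cross_entropy"),
                          label_col = "Obesity_level") {
  loss <- match.arg(loss)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("[", name, "] ", conditionMessage(e)))
    })
  }
  data <- stage("clean", {
    if (clean) clean_records(data, quiet = TRUE) else tibble::as_tibble(data)
  })
  parts <- stage("split", split_dataset(data, split, label_col))
  eng_train <- stage("features", engineer_features(parts$train, features))
  tue_scaler <- attr(eng_train, "tue_scaler")
  eng_val <- stage("features", engineer_features(parts$validation, features, tue_scaler))
  eng_test <- stage("features", engineer_features(parts$test, features, tue_scaler))
  if (isTRUE(features$drop_height)) {
    eng_train <- drop_height(eng_train)
    eng_val <- drop_height(eng_val)
    eng_test <- drop_height(eng_test)
  }
  scaler <- stage("scale", fit_scaler(eng_train,
                                      columns = setdiff(names(eng_train), label_col),
                                      mode = features$scaling))
  eng_train <- scale_features(eng_train, scaler)
  eng_val <- scale_features(eng_val, scaler)
  eng_test <- scale_features(eng_test, scaler)
  if (isTRUE(features$smote$enabled)) {
    eng_train <- stage("smote", smote_oversample(
      eng_train, label_col = label_col, k = features$smote$k,
      seed = pso$seed %||% split$seed))
  }
  fm <- as_feature_matrix(eng_train, label_col)
  spec <- network_spec(ncol(fm$X), hidden = hidden,
                       n_out = length(bmi_class_table("seven")$class))
  objective <- if (loss == "mse") {
    make_fitness(spec, fm$X, fm$y)
  } else {
    targets <- one_hot(fm$y, spec$sizes[length(spec$sizes)])
    function(v) cross_entropy_loss(forward_pass(spec, v, fm$X), targets)
  }
  opt <- stage("optimize", {
    runs <- purrr::map(seq_len(max(1, restarts)), function(r) {
      cfg_r <- pso
      if (!is.null(pso$seed) && r > 1) cfg_r$seed <- pso$seed + 1000L * (r - 1L)
      pso_optimize(objective, param_count(spec), cfg_r)
    })
    runs[[which.min(purrr::map_dbl(runs, "best_fitness"))]]
  })

  val_eval <- stage("evaluate", evaluate_weights(spec, opt$best_position, eng_val, label_col))
  test_eval <- stage("evaluate", evaluate_weights(spec, opt$best_position, eng_test, label_col))

  cv_metrics <- NULL
  if (isTRUE(cv)) {
    folds <- kfold(eng_train, folds = split$cv_folds,
                   seed = split$seed, label_col = label_col)
    cv_metrics <- purrr::imap_dfr(folds, function(f, i) {
      sub <- as_feature_matrix(eng_train[f$fit, , drop = FALSE], label_col)
      obj <- make_fitness(spec, sub$X, sub$y)
      o <- pso_optimize(obj, param_count(spec), pso)
      ev <- evaluate_weights(spec, o$best_position,
                             eng_train[f$holdout, , drop = FALSE], label_col)
      tibble::tibble(fold = i, accuracy = ev$report$accuracy,
                     macro_f1 = ev$report$macro$f1)
    })
  }

  structure(list(
    spec = spec, weights = opt$best_position,
    history = opt$history, best_fitness = opt$best_fitness,
    features = fm$features, feature_config = features,
    scaler = scaler, tue_scaler = tue_scaler,
    validation = val_eval$report, test = test_eval$report,
    test_probs = test_eval$probs, test_y = test_eval$y,
    test_X = as_feature_matrix(eng_test, label_col)$X,
    cv_metrics = cv_metrics,
    config = list(hidden = hidden, pso = pso, split = split, loss = loss,
                  label_col = label_col)
  ), class = "ann_pso")
}

#' Predict obesity classes for new records
#'
#' Applies the stored feature engineering and scalers (fitted on the
#' training split) and the trained network to raw schema records.
#'
#' @param object A fitted `"ann_pso"` model.
#' @param newdata Schema-conformant data frame (label optional).
#' @param type `"class"` (default) for integer labels or `"prob"` for
#'   the class-probability matrix.
#' @param ... Unused.
#' @return Integer labels or a probability matrix.
#' @export
predict.ann_pso <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- prepare_features(object, newdata)
  probs <- forward_pass(object$spec, object$weights, X)
  if (type == "prob") probs else predict_class(probs)
}

# Raw records -> scaled engineered feature matrix in training column order.
prepare_features <- function(object, newdata) {
  eng <- engineer_features(tibble::as_tibble(newdata),
                           object$feature_config, object$tue_scaler)
  if (isTRUE(object$feature_config$drop_height) && "Height" %in% names(eng)) {
    eng <- drop_height(eng)
  }
  eng <- scale_features(eng, object$scaler)
  missing_cols <- setdiff(object$features, names(eng))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing feature columns: ", paste(missing_cols, collapse = ", ")))
  }
  as.matrix(eng[object$features])
}

#' @export
print.ann_pso <- function(x, ...) {
  cat(sprintf("<ann_pso> layers [%s], %d parameters\n",
              paste(x$spec$sizes, collapse = "-"), param_count(x$spec)))
  if (!is.null(x$best_fitness)) {
    cat(sprintf("  final training fitness (MSE): %.5f\n", x$best_fitness))
  }
  if (!is.null(x$test)) {
    cat(sprintf("  validation accuracy: %.4f | test accuracy: %.4f\n",
                x$validation$accuracy, x$test$accuracy))
  }
  invisible(x)
}
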