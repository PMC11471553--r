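test_that("confusion matrices count true-by-predicted pairs", {
  y <- c(1, 1, 2, 3, 3, 3)
  cm <- confusion_matrix(y, y, n_classes = 3)
  expect_equal(unname(diag(unclass(cm))), c(2L, 1L, 3L))
  expect_equal(sum(cm), length(y))

  cm2 <- confusion_matrix(c(1, 1, 2), c(1, 2, 2), n_classes = 2)
  expect_equal(unclass(cm2), matrix(c(1L, 0L, 1L, 1L), 2, 2),
               ignore_attr = TRUE)
  set.seed(1)
  for (i in 1:10) {
    yt <- sample(1:7, 40, replace = TRUE); yp <- sample(1:7, 40, replace = TRUE)
    expect_equal(sum(confusion_matrix(yt, yp)), 40)
  }
  expect_error(confusion_matrix(1:3, 1:2), "equal length")
  expect_error(confusion_matrix(c(1, 8), c(1, 1), n_classes = 7), "range")
})

test_that("classification reports match hand arithmetic and conventions", {
  cm <- confusion_matrix(c(rep(1, 10), rep(2, 10)),
                         c(rep(1, 8), 2, 2, 1, 1, 1, rep(2, 7)), n_classes = 2)
  rep <- classification_report(cm)  # [[8,2],[3,7]]
  expect_equal(rep$per_class$precision[1], 8 / 11)
  expect_equal(rep$per_class$recall[1], 0.8)
  expect_equal(rep$per_class$f1[1], 2 * (8 / 11) * 0.8 / ((8 / 11) + 0.8))
  expect_equal(rep$accuracy, 15 / 20)

  perfect <- classification_report(confusion_matrix(1:7, 1:7))
  expect_equal(perfect$accuracy, 1)
  expect_true(all(perfect$per_class$f1 == 1))

  # class never predicted and never true: flagged zeros
  cm0 <- confusion_matrix(c(1, 1, 2), c(1, 1, 2), n_classes = 3)
  rep0 <- classification_report(cm0)
  expect_true(rep0$per_class$undefined[3])
  expect_equal(rep0$per_class$f1[3], 0)
  expect_error(classification_report(confusion_matrix(integer(0), integer(0))),
               "Empty")
})

test_that("report(confusion(y, y)) is perfect for any labeling", {
  set.seed(2)
  for (i in 1:10) {
    y <- sample(1:7, 30, replace = TRUE)
    rep <- classification_report(confusion_matrix(y, y))
    expect_equal(rep$accuracy, 1)
    present <- rep$per_class$support > 0
    expect_true(all(rep$per_class$f1[present] == 1))
  }
})

test_that("micro-averaged precision and recall equal accuracy", {
  set.seed(3)
  for (i in 1:20) {
    yt <- sample(1:7, 60, replace = TRUE)
    yp <- sample(1:7, 60, replace = TRUE)
    cm <- unclass(confusion_matrix(yt, yp))
    tp <- diag(cm)
    micro_p <- sum(tp) / sum(colSums(cm))
    micro_r <- sum(tp) / sum(rowSums(cm))
    acc <- classification_report(confusion_matrix(yt, yp))$accuracy
    expect_equal(micro_p, acc)
    expect_equal(micro_r, acc)
  }
})

test_that("ROC and PR curves behave at the extremes", {
  y <- c(1, 1, 2, 2)
  sep <- rbind(c(0.9, 0.1), c(0.8, 0.2), c(0.1, 0.9), c(0.2, 0.8))
  cs <- roc_pr_curves(y, sep)
  expect_equal(cs$auc$roc_auc, c(1, 1))
  expect_equal(cs$macro_roc_auc, 1)
  flat <- matrix(0.5, 4, 2)
  expect_equal(roc_pr_curves(y, flat)$auc$roc_auc, c(0.5, 0.5)) # chance line
  roc_pts <- cs$points[cs$points$curve == "roc" & cs$points$class == "class_1", ]
  expect_equal(roc_pts$x[1], 0); expect_equal(roc_pts$y[1], 0)
  expect_equal(roc_pts$x[nrow(roc_pts)], 1)
  expect_equal(roc_pts$y[nrow(roc_pts)], 1)
  expect_warning(roc_pr_curves(c(1, 1, 2, 2), matrix(1 / 3, 4, 3)), "absent")
})

test_that("curves match exhaustive threshold enumeration on a hand example", {
  y <- c(1, 2, 1, 2)
  probs <- rbind(c(0.7, 0.3), c(0.6, 0.4), c(0.55, 0.45), c(0.2, 0.8))
  cs <- roc_pr_curves(y, probs)
  truth <- y == 1
  expect_equal(cs$auc$roc_auc[1], oracle_roc_auc(truth, probs[, 1]))
  expect_equal(cs$auc$pr_auc[1], oracle_pr_auc(truth, probs[, 1]))
})

test_that("ROC AUC is invariant under strictly monotone score transforms", {
  set.seed(4)
  y <- sample(1:3, 30, replace = TRUE)
  probs <- matrix(runif(90), 30, 3); probs <- probs / rowSums(probs)
  base <- roc_pr_curves(y, probs)$auc$roc_auc
  trans <- roc_pr_curves(y, qlogis(probs / 2 + 0.25))$auc$roc_auc
  expect_equal(trans, base, tolerance = 1e-12)
})

test_that("all metrics agree with independent references on random fixtures", {
  set.seed(5)
  skip_if_not_installed("pROC")
  for (i in 1:100) {
    n <- sample(15:40, 1)
    k <- sample(2:5, 1)
    yt <- sample(seq_len(k), n, replace = TRUE)
    while (length(unique(yt)) < k) yt <- sample(seq_len(k), n, replace = TRUE)
    yp <- sample(seq_len(k), n, replace = TRUE)
    probs <- matrix(runif(n * k), n, k); probs <- probs / rowSums(probs)

    rep <- classification_report(confusion_matrix(yt, yp, n_classes = k))
    ref <- oracle_report(yt, yp, k)
    expect_equal(rep$per_class$precision, ref$precision, tolerance = 1e-12)
    expect_equal(rep$per_class$recall, ref$recall, tolerance = 1e-12)
    expect_equal(rep$per_class$f1, ref$f1, tolerance = 1e-12)
    expect_equal(rep$accuracy, ref$accuracy[1], tolerance = 1e-12)

    cs <- roc_pr_curves(yt, probs)
    for (cls in seq_len(k)) {
      expect_equal(cs$auc$roc_auc[cls], oracle_roc_auc(yt == cls, probs[, cls]),
                   tolerance = 1e-12)
      expect_equal(cs$auc$pr_auc[cls], oracle_pr_auc(yt == cls, probs[, cls]),
                   tolerance = 1e-12)
      proc_auc <- as.numeric(pROC::auc(pROC::roc(
        response = as.integer(yt == cls), predictor = probs[, cls],
        quiet = TRUE, direction = "<")))
      expect_equal(cs$auc$roc_auc[cls], proc_auc, tolerance = 1e-12)
    }
  }
})

test_that("permutation importance ranks the label-defining features first", {
  # model: the BMI rule itself, so weight and height must dominate
  bmi_model <- function(M) {
    classify_bmi(pmax(M[, "Weight"], 1) / pmax(M[, "Height"], 0.1)^2, as = "code")
  }
  ranks <- sapply(1:10, function(s) {
    d <- generate_obesity_data(n_records = 150, seed = 100 + s)
    X <- as.matrix(d[, c("Weight", "Height", "Age", "FAF", "CAEC")])
    imp <- permutation_importance(bmi_model, X, d$Obesity_level,
                                  n_repeats = 3, seed = s)
    match(c("Weight", "Height"), imp$feature)
  })
  expect_true(all(ranks %in% 1:2))

  # a constant column has (near) zero importance
  d <- generate_obesity_data(n_records = 120, seed = 200)
  X <- cbind(as.matrix(d[, c("Weight", "Height")]), Const = 1)
  imp <- permutation_importance(bmi_model, X, d$Obesity_level,
                                n_repeats = 3, seed = 1)
  expect_equal(imp$importance[imp$feature == "Const"], 0)

  # n_repeats = 1 equals a single fixed-permutation evaluation
  imp1 <- permutation_importance(bmi_model, X, d$Obesity_level,
                                 n_repeats = 1, seed = 9)
  base <- attr(imp1, "baseline")
  w_drop <- imp1$importance[imp1$feature == "Weight"]
  pred <- withr::with_seed(9, {
    Xp <- X; Xp[, 1] <- X[sample.int(nrow(X)), 1]
    bmi_model(Xp)
  })
  expect_equal(w_drop, base - mean(pred == d$Obesity_level))
})
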