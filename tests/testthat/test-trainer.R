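test_that("splits are disjoint, exhaustive and stratified within one record", {
  d <- generate_obesity_data(n_records = 1000, seed = 20)
  parts <- split_dataset(d, split_spec(seed = 1, stratified = FALSE))
  expect_equal(vapply(parts, nrow, integer(1)),
               c(train = 700L, validation = 150L, test = 150L))
  parts_s <- split_dataset(d, split_spec(seed = 1))
  expect_equal(sum(vapply(parts_s, nrow, integer(1))), 1000)
  all_rows <- dplyr::bind_rows(parts_s)
  expect_equal(dplyr::arrange_all(all_rows), dplyr::arrange_all(d)) # exhaustive
  for (cls in 1:7) {
    n_c <- sum(d$Obesity_level == cls)
    expect_lte(abs(sum(parts_s$train$Obesity_level == cls) - 0.7 * n_c), 1)
    expect_lte(abs(sum(parts_s$test$Obesity_level == cls) - 0.15 * n_c), 1)
  }
  expect_identical(split_dataset(d, split_spec(seed = 1)), parts_s) # same seed
  expect_error(split_spec(train = 0.8, validation = 0.15, test = 0.15), "sum to 1")

  tiny <- generate_obesity_data(n_records = 40, seed = 21)
  expect_warning(split_dataset(tiny, split_spec(seed = 2)), "unstratified")
})

test_that("k-fold partitions are balanced and exhaustive", {
  d <- generate_obesity_data(n_records = 100, seed = 22)
  folds <- kfold(d, folds = 10, seed = 1)
  expect_length(folds, 10)
  holdouts <- purrr::map(folds, "holdout")
  expect_equal(sort(unlist(holdouts)), 1:100)
  expect_true(all(vapply(holdouts, length, integer(1)) == 10))
  for (f in folds) {
    expect_equal(sort(c(f$fit, f$holdout)), 1:100)
  }
  # pigeonhole at n = 103: seven folds of 10 and three of 11
  d2 <- generate_obesity_data(n_records = 103, seed = 23)
  sizes <- sort(vapply(kfold(d2, folds = 10, seed = 1), function(f)
    length(f$holdout), integer(1)))
  expect_equal(sizes, c(rep(10L, 7), rep(11L, 3)))
  expect_error(kfold(5, folds = 10), "Fewer records")
})

test_that("the swarm fitness closure is pure and matches closed forms", {
  spec <- network_spec(2, hidden = 4, n_out = 4)
  X <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4, 2)
  y <- 1:4
  fitness <- make_fitness(spec, X, y)
  zero <- rep(0, param_count(spec))
  uniform_loss <- ((1 - 1 / 4)^2 + 3 * (1 / 4)^2) / 4
  expect_equal(fitness(zero), uniform_loss)
  expect_identical(fitness(zero), fitness(zero)) # purity

  # hand-built corner-detector net separates the 4 records perfectly
  W1 <- cbind(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  b1 <- c(1, 0, 0, -1)
  W2 <- diag(4) * 50
  b2 <- rep(0, 4)
  v <- flatten_weights(list(list(W = W1, b = b1), list(W = W2, b = b2)))
  expect_lt(fitness(v), 1e-6)
})

test_that("training is leakage-free: test records never touch the weights", {
  base <- generate_obesity_data(n_records = 420, seed = 30)
  spl <- split_spec(seed = 3)
  assignment <- split_dataset(base, spl)
  # perturb only features of rows that land in the test partition; the
  # stratified assignment depends only on labels, so it is unchanged
  modified <- base
  idx <- do.call(paste, base) %in% do.call(paste, assignment$test)
  modified$CH2O[idx] <- (modified$CH2O[idx] %% 3) + 1

  fit_a <- train_ann_pso(base, hidden = c(8), pso = fast_pso(seed = 5),
                         split = spl, restarts = 1, clean = FALSE)
  fit_b <- train_ann_pso(modified, hidden = c(8), pso = fast_pso(seed = 5),
                         split = spl, restarts = 1, clean = FALSE)
  expect_identical(fit_a$weights, fit_b$weights)
  expect_identical(fit_a$history, fit_b$history)
})

test_that("training is deterministic and the optimizer never hurts", {
  d <- generate_obesity_data(n_records = 400, seed = 31)
  fit1 <- train_ann_pso(d, hidden = c(8), pso = fast_pso(seed = 6),
                        split = split_spec(seed = 6), restarts = 1)
  fit2 <- train_ann_pso(d, hidden = c(8), pso = fast_pso(seed = 6),
                        split = split_spec(seed = 6), restarts = 1)
  expect_identical(fit1$weights, fit2$weights)
  expect_identical(glance(fit1), glance(fit2))
  # final best fitness no worse than the initial random swarm's best
  expect_lte(fit1$best_fitness, fit1$history$best_fitness[1])
  expect_true(all(diff(fit1$history$best_fitness) <= 0))
})

test_that("per-fold cross-validated metrics are reported on request", {
  d <- generate_obesity_data(n_records = 300, seed = 32)
  fit <- train_ann_pso(d, hidden = c(6), pso = fast_pso(seed = 7, k_max = 5),
                       split = split_spec(seed = 7, cv_folds = 3),
                       restarts = 1, cv = TRUE)
  expect_equal(nrow(fit$cv_metrics), 3)
  expect_true(all(fit$cv_metrics$accuracy >= 0 & fit$cv_metrics$accuracy <= 1))
})

test_that("prediction applies the stored pipeline to raw records", {
  d <- generate_obesity_data(n_records = 400, seed = 33)
  fit <- train_ann_pso(d, hidden = c(8), pso = fast_pso(seed = 8),
                       split = split_spec(seed = 8), restarts = 1)
  newd <- generate_obesity_data(n_records = 50, seed = 34)
  pred <- predict(fit, newd)
  expect_length(pred, 50)
  expect_true(all(pred %in% 1:7))
  probs <- predict(fit, newd, type = "prob")
  expect_equal(dim(probs), c(50, 7))
  expect_equal(rowSums(probs), rep(1, 50), tolerance = 1e-12)
  expect_equal(predict_class(probs), pred)
})
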