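test_that("parameter counting matches hand tallies", {
  expect_equal(param_count(network_spec(2, hidden = 3, n_out = 2)), 17)
  expect_equal(param_count(network_spec(16)), 12743) # 16-128-64-32-7
  # single-layer closed form n*m + m
  for (n in c(1, 4, 9)) for (m in c(2, 5)) {
    sp <- structure(list(sizes = c(n, m), activation = "relu"),
                    class = "network_spec")
    expect_equal(param_count(sp), n * m + m)
  }
})

test_that("flatten/unflatten is an exact round trip with shape checking", {
  spec <- network_spec(4, hidden = c(5, 3), n_out = 2)
  set.seed(1)
  w <- unflatten_weights(rnorm(param_count(spec)), spec)
  expect_identical(unflatten_weights(flatten_weights(w), spec), w)
  z <- unflatten_weights(rep(0, param_count(spec)), spec)
  expect_true(all(vapply(z, function(l) all(l$W == 0) && all(l$b == 0), logical(1))))
  expect_error(unflatten_weights(rep(0, param_count(spec) + 1), spec), "length")
  expect_error(unflatten_weights(rep(0, 12744), network_spec(16)), "12743")
})

test_that("forward pass produces softmax rows and matches hand arithmetic", {
  spec <- network_spec(3, hidden = 4, n_out = 7)
  v <- rep(0, param_count(spec))
  X <- matrix(rnorm(15), 5, 3)
  probs <- forward_pass(spec, v, X)
  expect_equal(probs, matrix(1 / 7, 5, 7)) # zeros: uniform rows
  set.seed(2)
  v2 <- runif(param_count(spec), -1, 1)
  probs2 <- forward_pass(spec, v2, X)
  expect_equal(rowSums(probs2), rep(1, 5), tolerance = 1e-12)
  expect_error(forward_pass(spec, v2, X[, 1:2]), "inputs")

  # single ReLU unit, pencil-and-paper: W1=(1,-2), b1=0.5; W2=(2,-1), b2=(0,1)
  sp <- network_spec(2, hidden = 1, n_out = 2)
  vec <- c(1, -2, 0.5, 2, -1, 0, 1)
  x <- matrix(c(1, 0.25), 1, 2)
  h <- max(0, 1 * 1 + (-2) * 0.25 + 0.5)        # 1
  logits <- c(2 * h + 0, -1 * h + 1)            # (2, 0)
  expect_equal(forward_pass(sp, vec, x),
               matrix(exp(logits) / sum(exp(logits)), 1, 2))
})

test_that("forward pass is permutation-equivariant over records", {
  spec <- network_spec(6, hidden = c(8, 5), n_out = 7)
  set.seed(3)
  v <- runif(param_count(spec), -0.5, 0.5)
  X <- matrix(rnorm(60), 10, 6)
  perm <- sample(10)
  expect_equal(forward_pass(spec, v, X[perm, ]), forward_pass(spec, v, X)[perm, ])
})

test_that("MSE loss is bounded, zero only at the target", {
  y <- c(2, 5, 1)
  target <- one_hot(y, 7)
  expect_equal(mse_loss(target, target), 0)
  uniform <- matrix(1 / 7, 3, 7)
  expect_equal(mse_loss(uniform, target), ((1 - 1 / 7)^2 + 6 * (1 / 7)^2) / 7)
  set.seed(4)
  for (i in 1:20) {
    p <- matrix(runif(21), 3, 7); p <- p / rowSums(p)
    l <- mse_loss(p, target)
    expect_true(l >= 0 && l <= 1)
    if (l == 0) expect_equal(p, target)
  }
  expect_error(mse_loss(uniform, target[1:2, ]), "Shape")
})

test_that("argmax prediction breaks ties toward the lowest class", {
  expect_equal(predict_class(matrix(c(0.9, 0.05, 0.05), 1)), 1L)
  tie <- matrix(c(0.1, 0.3, 0.1, 0.1, 0.3, 0.1, 0), 1)
  expect_equal(predict_class(tie), 2L) # tie between classes 2 and 5
  spec <- network_spec(3, hidden = 4, n_out = 7)
  probs <- forward_pass(spec, rep(0, param_count(spec)), matrix(rnorm(9), 3, 3))
  expect_equal(predict_class(probs), rep(1L, 3)) # uniform rows, tie rule
})

test_that("model serialization round-trips weights bit-exactly", {
  spec <- network_spec(5, hidden = c(6, 4), n_out = 7)
  set.seed(5)
  m <- list(spec = spec, weights = runif(param_count(spec), -1, 1),
            seed = 5, note = "fixture")
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  back <- load_model(path)
  expect_identical(back$weights, m$weights)
  expect_equal(back$spec$sizes, spec$sizes)
  expect_equal(back$spec$activation, spec$activation)
  expect_equal(back$note, "fixture")
})
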