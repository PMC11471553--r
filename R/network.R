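#' Feedforward network architecture
#'
#' Defines a fully connected multiclass network. The default hidden
#' stack 128-64-32 with ReLU activations mirrors the tuned multilayer
#' perceptron used by the hybrid classifier; the output layer is softmax
#' over the seven obesity classes so that class probabilities are
#' available for ROC/PR analysis.
#'
#' @param n_in Number of input features.
#' @param hidden Integer vector of hidden layer widths (at least one).
#' @param n_out Number of classes, default 7.
#' @param activation Hidden activation, `"relu"` (default) or `"tanh"`.
#' @return An object of class `"network_spec"`.
#' @examples
#' network_spec(16)
#' param_count(network_spec(16)) # 12743
#' @export
network_spec <- function(n_in, hidden = c(128, 64, 32), n_out = 7,
                         activation = c("relu", "tanh")) {
  activation <- match.arg(activation)
  if (length(hidden) < 1) abort("At least one hidden layer is required.")
  sizes <- as.integer(c(n_in, hidden, n_out))
  if (any(sizes < 1)) abort("All layer sizes must be positive.")
  structure(list(sizes = sizes, activation = activation), class = "network_spec")
}

#' @rdname network_spec
#' @param spec A `"network_spec"`.
#' @export
param_count <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  s <- spec$sizes
  sum(s[-length(s)] * s[-1] + s[-1])
}

#' Flatten and restore network weights
#'
#' The swarm optimizer treats all network parameters as one flat real
#' vector. Layout: layer by layer, the weight matrix in row-major order
#' (rows = inputs of the layer) followed by the bias vector.
#' `unflatten_weights(flatten_weights(w), spec)` is the exact identity.
#'
#' @param weights A list of layers, each `list(W = matrix, b = vector)`.
#' @return `flatten_weights()` a numeric vector; `unflatten_weights()`
#'   the layer list.
#' @export
flatten_weights <- function(weights) {
  unlist(purrr::map(weights, function(l) c(t(l$W), l$b)), use.names = FALSE)
}

#' @rdname flatten_weights
#' @param vector Flat numeric vector of length `param_count(spec)`.
#' @param spec A `"network_spec"`.
#' @export
unflatten_weights <- function(vector, spec) {
  stopifnot(inherits(spec, "network_spec"))
  if (length(vector) != param_count(spec)) {
    abort(sprintf("Weight vector has length %d; spec requires %d.",
                  length(vector), param_count(spec)))
  }
  s <- spec$sizes
  pos <- 0L
  purrr::map(seq_len(length(s) - 1), function(l) {
    n_in <- s[l]; n_out <- s[l + 1]
    W <- matrix(vector[pos + seq_len(n_in * n_out)], nrow = n_in,
                ncol = n_out, byrow = TRUE)
    pos <<- pos + n_in * n_out
    b <- vector[pos + seq_len(n_out)]
    pos <<- pos + n_out
    list(W = W, b = b)
  })
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Forward pass
#'
#' Deterministic forward propagation of a feature matrix through the
#' network defined by a spec and a flat weight vector. Hidden layers use
#' the spec's activation; the output layer is row-wise softmax, so every
#' output row is a probability distribution over the classes.
#'
#' @param spec A `"network_spec"`.
#' @param vector Flat weight vector.
#' @param X Numeric matrix (or data frame) with `n_in` columns.
#' @return An `nrow(X) x n_out` matrix of class probabilities.
#' @export
forward_pass <- function(spec, vector, X) {
  stopifnot(inherits(spec, "network_spec"))
  X <- as.matrix(X)
  if (ncol(X) != spec$sizes[1]) {
    abort(sprintf("X has %d columns; spec requires %d inputs.",
                  ncol(X), spec$sizes[1]))
  }
  layers <- unflatten_weights(vector, spec)
  A <- X
  n_layers <- length(layers)
  for (l in seq_len(n_layers)) {
    Z <- A %*% layers[[l]]$W + matrix(layers[[l]]$b, nrow(A),
                                      length(layers[[l]]$b), byrow = TRUE)
    A <- if (l < n_layers) {
      if (spec$activation == "relu") pmax(Z, 0) else tanh(Z)
    } else {
      softmax_rows(Z)
    }
  }
  A
}

#' One-hot encode class labels
#'
#' @param y Integer labels in `1..n_classes`.
#' @param n_classes Number of classes, default 7.
#' @return An `length(y) x n_classes` 0/1 matrix.
#' @export
one_hot <- function(y, n_classes = 7) {
  y <- as.integer(y)
  if (any(y < 1 | y > n_classes)) abort("Labels out of 1..n_classes range.")
  M <- matrix(0, length(y), n_classes)
  M[cbind(seq_along(y), y)] <- 1
  M
}

#' Mean squared error loss
#'
#' The swarm fitness: the mean over records and classes of the squared
#' difference between predicted class probabilities and one-hot targets.
#' Bounded in [0, 1]; zero iff predictions equal the targets exactly.
#'
#' @param probs Probability matrix from [forward_pass()].
#' @param targets One-hot target matrix of the same shape.
#' @return A single non-negative number.
#' @export
mse_loss <- function(probs, targets) {
  if (!all(dim(probs) == dim(targets))) abort("Shape mismatch in mse_loss.")
  mean((probs - targets)^2)
}

#' Cross-entropy loss (alternative fitness)
#'
#' @param probs,targets As in [mse_loss()].
#' @param eps Probability floor for numerical stability.
#' @return Mean negative log-likelihood.
#' @export
cross_entropy_loss <- function(probs, targets, eps = 1e-12) {
  if (!all(dim(probs) == dim(targets))) abort("Shape mismatch in cross_entropy_loss.")
  -mean(rowSums(targets * log(pmax(probs, eps))))
}

#' Hard class predictions from probabilities
#'
#' Row-wise argmax; exact ties break toward the lowest class index so
#' predictions are deterministic.
#'
#' @param probs Probability matrix, one row per record.
#' @return Integer vector of predicted class indices.
#' @export
predict_class <- function(probs) {
  max.col(as.matrix(probs), ties.method = "first")
}

#' Save and load a trained model as JSON
#'
#' The model file is a JSON object holding the architecture, the flat
#' weight vector at full double precision, and free-form metadata;
#' `load_model(save_model(m))` round-trips weights bit-exactly.
#'
#' @param model A list with elements `spec` (a `"network_spec"`) and
#'   `weights` (flat vector); extra elements are stored as metadata.
#' @param path Output path.
#' @return `save_model()` returns `path` invisibly; `load_model()` the
#'   model list.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model$spec, "network_spec"))
  payload <- list(
    sizes = model$spec$sizes,
    activation = model$spec$activation,
    weights = model$weights,
    metadata = model[setdiff(names(model), c("spec", "weights"))]
  )
  write_json_atomic(payload, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- network_spec(p$sizes[1], p$sizes[-c(1, length(p$sizes))],
                       p$sizes[length(p$sizes)], p$activation)
  c(list(spec = spec, weights = as.numeric(p$weights)), p$metadata)
}

# Atomic JSON writer: write to a temp file in the same directory, then
# rename, so a failed run never leaves a partial artifact. 17 significant
# digits make double round trips bit-exact.
write_json_atomic <- function(x, path, ...) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = I(17), ...)
  file.rename(tmp, path)
  invisible(path)
}
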