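#' Exponential linear unit
#'
#' Activation used on the hidden layers: identity on positives, smooth
#' saturation to -1 on negatives (`exp(z) - 1`), unit scale.
#'
#' @param z Numeric vector/matrix.
#' @return Same shape as `z`.
#' @export
elu <- function(z) ifelse(z > 0, z, exp(z) - 1)

# derivative of elu: 1 for z > 0, exp(z) otherwise
elu_grad <- function(z) ifelse(z > 0, 1, exp(z))

#' Row-wise softmax
#'
#' Numerically stable (max-shifted) softmax mapping logits to a probability
#' distribution over classes; invariant to adding a constant to all logits.
#'
#' @param logits Numeric matrix (samples x classes) or vector.
#' @return Matrix/vector of the same shape with rows summing to 1.
#' @export
softmax <- function(logits) {
  if (is.vector(logits)) return(drop(softmax(matrix(logits, nrow = 1))))
  shifted <- logits - apply(logits, 1, max)
  e <- exp(shifted)
  e / rowSums(e)
}

#' Initialise classifier parameters
#'
#' The classifier is a stack of affine maps: `n_features` to the hidden
#' sizes (ELU-activated, default 1000 then 500) and a final un-activated
#' affine map to `n_classes` logits fed to [softmax()]. Weights use Glorot
#' (variance-scaled) uniform initialisation, biases start at zero;
#' reproducible from `seed`.
#'
#' @param n_features Number of input CpG features (k).
#' @param hidden_sizes Integer vector of hidden-layer widths; may be empty
#'   for a single affine map (multinomial-logistic degenerate form).
#' @param n_classes Number of subtypes C (>= 2).
#' @param seed Integer seed.
#' @return An object of class `model_params`: `weights`, `biases` (lists),
#'   `hidden_sizes`, `n_features`, `n_classes`.
#' @export
init_params <- function(n_features, hidden_sizes = c(1000, 500), n_classes,
                        seed = 0) {
  stopifnot(n_features >= 1, n_classes >= 2, all(hidden_sizes >= 1))
  dims <- c(n_features, hidden_sizes, n_classes)
  params <- with_seed(seed, {
    weights <- biases <- vector("list", length(dims) - 1)
    for (l in seq_along(weights)) {
      fan_in <- dims[l]; fan_out <- dims[l + 1]
      lim <- sqrt(6 / (fan_in + fan_out))
      weights[[l]] <- matrix(stats::runif(fan_in * fan_out, -lim, lim),
                             nrow = fan_in, ncol = fan_out)
      biases[[l]] <- numeric(fan_out)
    }
    list(weights = weights, biases = biases)
  })
  structure(list(weights = params$weights, biases = params$biases,
                 hidden_sizes = as.integer(hidden_sizes),
                 n_features = as.integer(n_features),
                 n_classes = as.integer(n_classes)),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params> %d -> %s-> %d (%d weight matrices, %d parameters)\n",
              x$n_features,
              if (length(x$hidden_sizes))
                paste0(paste(x$hidden_sizes, collapse = " -> "), " ") else "",
              x$n_classes, length(x$weights),
              sum(vapply(x$weights, length, 1L)) +
                sum(vapply(x$biases, length, 1L))))
  invisible(x)
}

# Forward pass with caches for backprop. X is samples x features. Dropout
# (inverted scaling) is applied to hidden activations only in training mode
# and consumes RNG; inference mode is a pure function of (params, X).
nn_forward <- function(params, X, dropout_rate = 0, training = FALSE) {
  stopifnot(ncol(X) == params$n_features,
            dropout_rate >= 0, dropout_rate < 1)
  L <- length(params$weights)
  caches <- vector("list", L - 1)
  A <- X
  for (l in seq_len(L - 1)) {
    Z <- A %*% params$weights[[l]]
    Z <- Z + rep(params$biases[[l]], each = nrow(Z))
    H <- elu(Z)
    mask <- NULL
    if (training && dropout_rate > 0) {
      keep <- 1 - dropout_rate
      mask <- matrix(stats::rbinom(length(H), 1, keep) / keep,
                     nrow = nrow(H))
      H <- H * mask
    }
    caches[[l]] <- list(A_prev = A, Z = Z, mask = mask)
    A <- H
  }
  logits <- A %*% params$weights[[L]]
  logits <- logits + rep(params$biases[[L]], each = nrow(logits))
  list(logits = logits, caches = caches, A_last = A)
}

#' Compute classifier logits
#'
#' Applies each hidden affine map with ELU activation (dropout on hidden
#' activations only when `training_mode = TRUE`), then the final affine map
#' to one logit per class. With `training_mode = FALSE` the output is a
#' deterministic function of the inputs.
#'
#' @param params A `model_params` object.
#' @param X Numeric matrix, samples x features.
#' @param dropout_rate Hidden-unit dropout probability in \[0, 1).
#' @param training_mode Logical; dropout is active only when `TRUE`.
#' @return Numeric matrix of logits, samples x classes.
#' @export
forward <- function(params, X, dropout_rate = 0, training_mode = FALSE) {
  nn_forward(params, X, dropout_rate, training_mode)$logits
}

# Backprop from d(loss)/d(logits); returns gradients matching params.
# l2_coefficient adds d/dW of l2 * sum(W^2) = 2 * l2 * W (weights only).
nn_backward <- function(params, fw, d_logits, l2_coefficient = 0) {
  L <- length(params$weights)
  gw <- gb <- vector("list", L)
  gw[[L]] <- crossprod(fw$A_last, d_logits)
  gb[[L]] <- colSums(d_logits)
  dA <- tcrossprod(d_logits, params$weights[[L]])
  for (l in rev(seq_len(L - 1))) {
    cache <- fw$caches[[l]]
    if (!is.null(cache$mask)) dA <- dA * cache$mask
    dZ <- dA * elu_grad(cache$Z)
    gw[[l]] <- crossprod(cache$A_prev, dZ)
    gb[[l]] <- colSums(dZ)
    if (l > 1) dA <- tcrossprod(dZ, params$weights[[l]])
  }
  if (l2_coefficient > 0) {
    for (l in seq_len(L)) {
      gw[[l]] <- gw[[l]] + 2 * l2_coefficient * params$weights[[l]]
    }
  }
  list(weights = gw, biases = gb)
}

#' Posterior subtype probabilities and hard predictions
#'
#' Runs the network in inference mode (no dropout) and converts logits to
#' posteriors with [softmax()]. Predictions are the per-sample argmax, ties
#' broken to the lowest class index, so repeated calls are identical.
#'
#' @param params A `model_params` object.
#' @param X Numeric matrix, samples x features.
#' @return A list of class `prediction_result`: `posteriors` (samples x
#'   classes), `predicted` (1-based class index), `max_prob`.
#' @export
predict_proba <- function(params, X) {
  post <- softmax(forward(params, X))
  if (is.vector(post)) post <- matrix(post, nrow = 1)
  pred <- apply(post, 1, which.max)  # which.max: first maximum -> lowest index
  structure(list(posteriors = post,
                 predicted = as.integer(pred),
                 max_prob = post[cbind(seq_len(nrow(post)), pred)]),
            class = "prediction_result")
}

#' L2 weight penalty
#'
#' `coefficient` times the sum of squared weight entries, biases excluded.
#'
#' @param params A `model_params` object.
#' @param coefficient Non-negative penalty strength.
#' @return Scalar penalty value.
#' @export
l2_penalty <- function(params, coefficient) {
  if (coefficient < 0) stop("L2 coefficient must be >= 0", call. = FALSE)
  coefficient * sum(vapply(params$weights, function(w) sum(w^2), numeric(1)))
}

# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
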