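# Small feed-forward neural network (two ReLU hidden layers, sigmoid
# output) trained by full-batch gradient descent with momentum on weighted
# cross-entropy. Written in plain R + matrix algebra: deliberately modest —
# it is the "deep learning" base of the ensemble at desk scale, not a GPU
# model. Supports per-example weights so it can sit under AdaBoost.

.mlp_init <- function(n_in, hidden, seed) {
  withr::with_seed(seed, {
    sizes <- c(n_in, hidden, 1L)
    lapply(seq_len(length(sizes) - 1L), function(i) {
      list(
        W = matrix(stats::rnorm(sizes[i] * sizes[i + 1L],
                                sd = sqrt(2 / sizes[i])),
                   nrow = sizes[i]),
        b = rep(0, sizes[i + 1L])
      )
    })
  })
}

.mlp_forward <- function(layers, X) {
  acts <- list(X)
  n_layers <- length(layers)
  for (i in seq_len(n_layers)) {
    Z <- acts[[i]] %*% layers[[i]]$W
    Z <- sweep(Z, 2L, layers[[i]]$b, "+")
    A <- if (i < n_layers) pmax(Z, 0) else 1 / (1 + exp(-Z))
    acts[[i + 1L]] <- A
  }
  acts
}

#' Train a two-hidden-layer perceptron
#'
#' @param X Numeric matrix (dense or sparse; coerced to dense).
#' @param y 0/1 numeric vector (1 = positive class).
#' @param hidden Integer vector of hidden layer sizes.
#' @param epochs Number of full-batch epochs.
#' @param lr Learning rate.
#' @param momentum Momentum coefficient.
#' @param l2 L2 penalty on weights.
#' @param weights Optional non-negative case weights (normalized internally).
#' @param seed Integer seed for weight initialization.
#' @return An `ebm_mlp` object with a [predict()] method returning
#'   probabilities.
#' @export
mlp_fit <- function(X, y, hidden = c(32L, 16L), epochs = 80L, lr = 0.5,
                    momentum = 0.9, l2 = 1e-4, weights = NULL, seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) == 0L) {
    abort("cannot train an MLP on 0 rows", class = "ebm_validation_error")
  }
  stopifnot(length(y) == nrow(X), all(y %in% c(0, 1)))
  w <- weights %||% rep(1, nrow(X))
  w <- w / sum(w)

  layers <- .mlp_init(ncol(X), hidden, seed)
  vel <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
  n_layers <- length(layers)

  for (ep in seq_len(epochs)) {
    acts <- .mlp_forward(layers, X)
    p <- acts[[n_layers + 1L]][, 1L]
    delta <- matrix((p - y) * w, ncol = 1L)  # d(loss)/d(z_out)
    for (i in rev(seq_len(n_layers))) {
      gW <- crossprod(acts[[i]], delta) + l2 * layers[[i]]$W
      gb <- colSums(delta)
      vel[[i]]$W <- momentum * vel[[i]]$W - lr * gW
      vel[[i]]$b <- momentum * vel[[i]]$b - lr * gb
      layers[[i]]$W <- layers[[i]]$W + vel[[i]]$W
      layers[[i]]$b <- layers[[i]]$b + vel[[i]]$b
      if (i > 1L) {
        delta <- (delta %*% t(layers[[i]]$W)) * (acts[[i]] > 0)
      }
    }
  }
  structure(list(layers = layers, hidden = hidden, seed = seed),
            class = "ebm_mlp")
}

#' @export
predict.ebm_mlp <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  acts <- .mlp_forward(object$layers, X)
  acts[[length(acts)]][, 1L]
}
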