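# Conventional fully connected ReLU network trained by SGD. Serves as the
# accuracy baseline and as the weight source for the off-chip
# ANN-to-SNN conversion; bias-free so its weights map directly onto
# differential conductance pairs.

#' Forward pass of a bias-free ReLU network
#'
#' Hidden layers apply ReLU; the output layer is linear.
#'
#' @param weights list of weight matrices (`n_in x n_out` per layer).
#' @param x input matrix, samples in rows.
#' @return list of activations per layer (element 1 is the input).
#' @export
ann_forward <- function(weights, x) {
  acts <- vector("list", length(weights) + 1)
  acts[[1]] <- x
  for (l in seq_along(weights)) {
    z <- acts[[l]] %*% weights[[l]]
    acts[[l + 1]] <- if (l < length(weights)) pmax(z, 0) else z
  }
  acts
}

#' Mean squared loss and analytic gradients of the ReLU network
#'
#' Loss is `0.5 * mean over samples of ||out - y||^2` against one-hot
#' targets, matching the spiking system's supervision (rate 1 for the
#' correct class, 0 otherwise).
#'
#' @param weights list of weight matrices.
#' @param x input matrix, samples in rows.
#' @param y one-hot target matrix.
#' @return list with `loss` and `grads` (same shapes as `weights`).
#' @export
ann_loss_grad <- function(weights, x, y) {
  n <- nrow(x)
  acts <- ann_forward(weights, x)
  out <- acts[[length(acts)]]
  err <- out - y
  loss <- 0.5 * sum(err^2) / n
  grads <- vector("list", length(weights))
  d <- err / n
  for (l in rev(seq_along(weights))) {
    grads[[l]] <- crossprod(acts[[l]], d)
    if (l > 1) {
      d <- (d %*% t(weights[[l]])) * (acts[[l]] > 0)
    }
  }
  list(loss = loss, grads = grads)
}

#' Train the reference ReLU network by minibatch SGD
#'
#' @param dataset dataset list with `images` and 0-based `labels`.
#' @param layer_sizes layer widths, input first.
#' @param epochs SGD epochs.
#' @param lr learning rate.
#' @param batch_size minibatch size.
#' @param seed RNG seed (initialization and shuffling).
#' @return list with `weights`, per-epoch `loss`, and `layer_sizes`.
#' @export
reference_ann <- function(dataset, layer_sizes, epochs = 30, lr = 0.5,
                          batch_size = 10, seed = 1L) {
  x <- dataset$images
  num_classes <- layer_sizes[length(layer_sizes)]
  y <- diag(num_classes)[dataset$labels + 1L, , drop = FALSE]
  set.seed(seed)
  weights <- lapply(seq_len(length(layer_sizes) - 1), function(l) {
    matrix(stats::rnorm(layer_sizes[l] * layer_sizes[l + 1],
                        sd = sqrt(1 / layer_sizes[l])),
           layer_sizes[l], layer_sizes[l + 1])
  })
  n <- nrow(x)
  loss <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (b in split(ord, ceiling(seq_along(ord) / batch_size))) {
      lg <- ann_loss_grad(weights, x[b, , drop = FALSE],
                          y[b, , drop = FALSE])
      weights <- Map(function(w, g) w - lr * g, weights, lg$grads)
    }
    loss[ep] <- ann_loss_grad(weights, x, y)$loss
  }
  list(weights = weights, loss = loss, layer_sizes = layer_sizes)
}

#' Predicted labels of the reference network
#'
#' @param model a [reference_ann()] fit.
#' @param x input matrix, samples in rows.
#' @return 0-based predicted labels.
#' @export
ann_predict <- function(model, x) {
  out <- ann_forward(model$weights, x)
  max.col(out[[length(out)]], ties.method = "first") - 1L
}
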