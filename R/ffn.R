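# Single-hidden-layer feed-forward network mapping one 20-ms bin of firing
# rates to four velocity outputs. Written directly on BLAS matrix ops with an
# Adam optimizer; gradients are exercised by finite-difference checks in the
# test suite.

#' Train a feed-forward network velocity decoder
#'
#' A densely connected single hidden layer (default 512 rectified-linear
#' units) with a linear readout to the four velocity outputs, trained with
#' minibatch Adam on mean squared error plus an optional L2 weight penalty.
#' Deterministic given `seed`.
#'
#' @param features bins x channels matrix.
#' @param targets bins x 4 velocity targets.
#' @param hidden Hidden-layer width.
#' @param activation `"relu"` (default) or `"tanh"`.
#' @param epochs Passes over the data.
#' @param batch Minibatch size.
#' @param lr Adam learning rate.
#' @param l2 L2 penalty on weights.
#' @param seed RNG seed (initialization and batch order).
#' @param verbose Print the loss every few epochs.
#' @return A `bci_ffn` model.
#' @export
train_ffn <- function(features, targets, hidden = 512, activation = c("relu", "tanh"),
                      epochs = 60, batch = 256, lr = 1e-3, l2 = 5e-3,
                      seed = 1L, verbose = FALSE) {
  activation <- match.arg(activation)
  X <- as.matrix(features); Y <- as.matrix(targets)
  stopifnot(nrow(X) == nrow(Y))
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  with_seed(child_seed(seed, "ffn"), {
    W1 <- matrix(stats::rnorm(p * hidden, sd = sqrt(2 / p)), p, hidden)
    b1 <- numeric(hidden)
    W2 <- matrix(stats::rnorm(hidden * q, sd = sqrt(1 / hidden)), hidden, q)
    b2 <- numeric(q)
    params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
    opt <- adam_init(params)
    act <- if (activation == "relu") function(z) pmax(z, 0) else tanh
    act_grad <- if (activation == "relu") function(z, a) (z > 0) + 0 else
      function(z, a) 1 - a^2

    step <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample(n)
      for (start in seq(1, n, by = batch)) {
        idx <- ord[start:min(start + batch - 1, n)]
        xb <- X[idx, , drop = FALSE]; yb <- Y[idx, , drop = FALSE]
        m <- length(idx)
        z1 <- sweep(xb %*% params$W1, 2, params$b1, `+`)
        a1 <- act(z1)
        pred <- sweep(a1 %*% params$W2, 2, params$b2, `+`)
        err <- pred - yb
        if (!all(is.finite(err))) {
          stop("FFN training diverged (non-finite loss at epoch ", ep, ")")
        }
        g_pred <- 2 * err / (m * q)
        grads <- list(
          W1 = NULL, b1 = NULL,
          W2 = crossprod(a1, g_pred) + 2 * l2 * params$W2,
          b2 = colSums(g_pred))
        g_a1 <- g_pred %*% t(params$W2)
        g_z1 <- g_a1 * act_grad(z1, a1)
        grads$W1 <- crossprod(xb, g_z1) + 2 * l2 * params$W1
        grads$b1 <- colSums(g_z1)
        step <- step + 1L
        params <- adam_update(params, grads, opt, lr, step)
      }
      if (verbose && ep %% 5 == 0) {
        tr_loss <- mean((ffn_forward(params, X, act) - Y)^2)
        message(sprintf("epoch %d  mse %.5f", ep, tr_loss))
      }
    }
    structure(list(params = params, activation = activation, hidden = hidden,
                   config = list(epochs = epochs, batch = batch, lr = lr,
                                 l2 = l2, seed = seed)),
              class = "bci_ffn")
  })
}

ffn_forward <- function(params, X, act) {
  a1 <- act(sweep(X %*% params$W1, 2, params$b1, `+`))
  sweep(a1 %*% params$W2, 2, params$b2, `+`)
}

#' @export
predict.bci_ffn <- function(object, newdata, ...) {
  act <- if (object$activation == "relu") function(z) pmax(z, 0) else tanh
  ffn_forward(object$params, as.matrix(newdata), act)
}

# ---- Adam optimizer shared by the FFN and GRU trainers ----

adam_init <- function(params) {
  e <- new.env(parent = emptyenv())
  e$m <- lapply(params, function(p) p * 0)
  e$v <- lapply(params, function(p) p * 0)
  e
}

adam_update <- function(params, grads, opt, lr, step,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    mhat <- opt$m[[nm]] / (1 - beta1^step)
    vhat <- opt$v[[nm]] / (1 - beta2^step)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  params
}
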