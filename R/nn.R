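# Dense feed-forward network primitives: tanh hidden layers, linear
# output, analytic backpropagation, Adam with optional decoupled weight
# decay. Everything operates on row-major batches (n x d matrices).
# These primitives back the emulator, the Real-NVP coupling nets and the
# variational encoder/decoder; their gradients are verified against
# finite differences in the test suite.

#' Initialize a dense feed-forward network
#'
#' @param sizes integer vector of layer widths, input first, output last
#'   (e.g. `c(23, 64, 64, 16)`)
#' @param seed optional seed for the Glorot-uniform initialization
#' @return list of class `mlp` with weight matrices `W` and bias vectors `b`
#' @export
mlp_init <- function(sizes, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- length(sizes) - 1
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    r <- sqrt(6 / (sizes[l] + sizes[l + 1]))
    W[[l]] <- matrix(runif(sizes[l] * sizes[l + 1], -r, r), sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  structure(list(W = W, b = b, sizes = sizes), class = "mlp")
}

#' Forward pass through a dense network
#'
#' @param net an [mlp_init] network
#' @param X n x d_in batch
#' @return list with `out` (n x d_out) and `h` (per-layer activations,
#'   kept for backpropagation)
#' @export
mlp_forward <- function(net, X) {
  if (is.null(dim(X))) X <- matrix(X, 1)
  L <- length(net$W)
  h <- vector("list", L + 1)
  h[[1]] <- X
  for (l in seq_len(L)) {
    z <- sweep(h[[l]] %*% net$W[[l]], 2, net$b[[l]], "+")
    h[[l + 1]] <- if (l < L) tanh(z) else z
  }
  list(out = h[[L + 1]], h = h)
}

#' Backward pass: gradients of a scalar loss through a dense network
#'
#' @param net an [mlp_init] network
#' @param fwd the cache returned by [mlp_forward]
#' @param dOut gradient of the loss w.r.t. the network output (n x d_out)
#' @return list with `dW`, `db` (matching `net$W`, `net$b`) and `dX`
#'   (gradient w.r.t. the input batch)
#' @export
mlp_backward <- function(net, fwd, dOut) {
  L <- length(net$W)
  dW <- vector("list", L); db <- vector("list", L)
  delta <- dOut
  for (l in L:1) {
    dW[[l]] <- crossprod(fwd$h[[l]], delta)
    db[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(net$W[[l]])) * (1 - fwd$h[[l]]^2)
    } else {
      delta <- delta %*% t(net$W[[l]])
    }
  }
  list(dW = dW, db = db, dX = delta)
}

#' @rdname adam_step
#' @export
adam_init <- function(net) {
  zero_like <- function(x) lapply(x, function(m) m * 0)
  list(mW = zero_like(net$W), vW = zero_like(net$W),
       mb = zero_like(net$b), vb = zero_like(net$b), t = 0L)
}

#' Adam optimizer step (decoupled weight decay)
#'
#' @param net an [mlp_init] network
#' @param grads gradients (`dW`, `db`) from [mlp_backward]
#' @param state optimizer state from [adam_init]
#' @param lr learning rate
#' @param beta1,beta2,eps Adam moment parameters
#' @param weight_decay decoupled L2 decay on weights (not biases)
#' @return list with updated `net` and `state`
#' @export
adam_step <- function(net, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  for (l in seq_along(net$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$dW[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$dW[[l]]^2
    step <- (state$mW[[l]] / c1) / (sqrt(state$vW[[l]] / c2) + eps)
    net$W[[l]] <- net$W[[l]] - lr * (step + weight_decay * net$W[[l]])
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$db[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$db[[l]]^2
    net$b[[l]] <- net$b[[l]] - lr * (state$mb[[l]] / c1) / (sqrt(state$vb[[l]] / c2) + eps)
  }
  list(net = net, state = state)
}

# elementwise accumulate two gradient lists
add_grads <- function(g1, g2, w2 = 1) {
  list(dW = Map(function(a, b) a + w2 * b, g1$dW, g2$dW),
       db = Map(function(a, b) a + w2 * b, g1$db, g2$db))
}

scale_grads <- function(g, w) {
  list(dW = lapply(g$dW, function(a) w * a),
       db = lapply(g$db, function(a) w * a))
}
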