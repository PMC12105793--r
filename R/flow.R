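# Real-NVP normalizing flow: a stack of affine coupling layers mapping a
# standard-normal base z to the (normalized) clinical-output
# distribution. Each layer freezes the masked half of its input and
# applies an elementwise affine map to the other half, with scale and
# shift produced by small dense nets of the masked half; the scale is
# bounded by a saturating tanh for stability. Both directions are exact,
# and the log-determinant of the Jacobian is the sum of the active scale
# outputs, giving exact densities for ranking and maximum-likelihood
# training.

#' Initialize a Real-NVP flow
#'
#' @param dim data dimension (16 for the clinical-output vector)
#' @param n_layers number of affine coupling layers (masks alternate
#'   between the two halves of the vector)
#' @param hidden hidden width of the per-layer scale/shift nets
#' @param s_cap saturation bound on the log-scale outputs
#' @param seed optional initialization seed
#' @return object of class `rnvp_flow`
#' @export
flow_init <- function(dim = 16, n_layers = 4, hidden = 64, s_cap = 2,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base_mask <- as.numeric(seq_len(dim) <= ceiling(dim / 2))
  layers <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    m <- if (l %% 2 == 1) base_mask else 1 - base_mask
    layers[[l]] <- list(mask = m,
                        s_net = mlp_init(c(dim, hidden, dim)),
                        t_net = mlp_init(c(dim, hidden, dim)))
  }
  structure(list(dim = dim, layers = layers, s_cap = s_cap), class = "rnvp_flow")
}

# one coupling layer in the data->base (inverse) direction, with cache
coupling_inverse <- function(layer, U, s_cap) {
  m <- layer$mask; um <- 1 - m
  U1 <- sweep(U, 2, m, "*")
  fs <- mlp_forward(layer$s_net, U1)
  ft <- mlp_forward(layer$t_net, U1)
  s <- s_cap * tanh(fs$out)
  E <- exp(-s)
  V <- U1 + sweep((U - ft$out) * E, 2, um, "*")
  ld <- -as.numeric((s %*% um))
  list(V = V, ld = ld,
       cache = list(U = U, U1 = U1, fs = fs, ft = ft, s = s, E = E))
}

# backward pass of coupling_inverse; dV: grad wrt output, dld: grad wrt
# the per-sample logdet contribution
coupling_inverse_backward <- function(layer, cache, dV, dld, s_cap) {
  m <- layer$mask; um <- 1 - m
  W <- (cache$U - cache$ft$out) * cache$E          # (U - t) exp(-s)
  dV_um <- sweep(dV, 2, um, "*")
  dS <- -dV_um * W + outer(dld, -um)
  dT <- -dV_um * cache$E
  dS_raw <- dS * s_cap * (1 - (cache$s / s_cap)^2)
  gs <- mlp_backward(layer$s_net, cache$fs, dS_raw)
  gt <- mlp_backward(layer$t_net, cache$ft, dT)
  dU <- sweep(dV, 2, m, "*") + dV_um * cache$E +
    sweep(gs$dX + gt$dX, 2, m, "*")
  list(dU = dU, gs = gs, gt = gt)
}

#' Map data to the base space (inverse direction) with log-determinant
#'
#' @param flow an `rnvp_flow`
#' @param Y n x dim matrix of normalized outputs
#' @param keep_cache retain per-layer caches for backpropagation
#' @return list with `Z` (base-space batch), `logdet` (per-sample sum of
#'   inverse-direction log-Jacobian determinants), optionally `caches`
#' @export
flow_inverse <- function(flow, Y, keep_cache = FALSE) {
  if (is.null(dim(Y))) Y <- matrix(Y, 1)
  U <- Y
  ld <- numeric(nrow(Y))
  caches <- if (keep_cache) vector("list", length(flow$layers))
  for (l in rev(seq_along(flow$layers))) {
    r <- coupling_inverse(flow$layers[[l]], U, flow$s_cap)
    U <- r$V; ld <- ld + r$ld
    if (keep_cache) caches[[l]] <- r$cache
  }
  out <- list(Z = U, logdet = ld)
  if (keep_cache) out$caches <- caches
  out
}

#' Map base-space samples to data space (sampling direction)
#'
#' @param flow an `rnvp_flow`
#' @param Z n x dim matrix of base-space points
#' @return n x dim matrix in (normalized) data space
#' @export
flow_forward <- function(flow, Z) {
  if (is.null(dim(Z))) Z <- matrix(Z, 1)
  X <- Z
  for (l in seq_along(flow$layers)) {
    layer <- flow$layers[[l]]
    m <- layer$mask; um <- 1 - m
    X1 <- sweep(X, 2, m, "*")
    s <- flow$s_cap * tanh(mlp_forward(layer$s_net, X1)$out)
    t_out <- mlp_forward(layer$t_net, X1)$out
    X <- X1 + sweep(X * exp(s) + t_out, 2, um, "*")
  }
  X
}

#' Exact log-density of normalized outputs under the flow
#'
#' Change of variables: `log p(y) = log N(z(y); 0, I) + sum of
#' inverse-direction log-Jacobian determinants`.
#'
#' @param flow an `rnvp_flow`
#' @param Y n x dim matrix (normalized units)
#' @return numeric vector of per-sample log-densities
#' @export
flow_log_density <- function(flow, Y) {
  r <- flow_inverse(flow, Y)
  if (any(!is.finite(r$logdet))) stop("non-finite flow log-determinant")
  -0.5 * rowSums(r$Z^2) - 0.5 * flow$dim * log(2 * pi) + r$logdet
}

#' Negative log-likelihood and its gradients for a batch
#'
#' @param flow an `rnvp_flow`
#' @param Y n x dim batch (normalized units)
#' @return list with `loss` (mean NLL) and `grads` (per layer: `gs`,
#'   `gt` gradient lists for the scale and shift nets)
#' @export
flow_nll_grad <- function(flow, Y) {
  n <- nrow(Y)
  r <- flow_inverse(flow, Y, keep_cache = TRUE)
  loss <- mean(0.5 * rowSums(r$Z^2) + 0.5 * flow$dim * log(2 * pi) - r$logdet)
  dU <- r$Z / n           # d loss / d z
  dld <- rep(-1 / n, n)   # d loss / d logdet
  grads <- vector("list", length(flow$layers))
  for (l in seq_along(flow$layers)) {
    bk <- coupling_inverse_backward(flow$layers[[l]], r$caches[[l]], dU, dld,
                                    flow$s_cap)
    grads[[l]] <- list(gs = bk$gs, gt = bk$gt)
    dU <- bk$dU
  }
  list(loss = loss, grads = grads)
}

#' Draw synthetic outputs from the flow
#'
#' @param flow an `rnvp_flow`
#' @param n number of draws
#' @param seed optional seed
#' @return n x dim matrix in normalized units
#' @export
flow_sample <- function(flow, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Z <- matrix(rnorm(n * flow$dim), n, flow$dim)
  flow_forward(flow, Z)
}
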