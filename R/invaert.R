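#' Training configuration for an inVAErt model
#'
#' The latent dimension defaults to 7 = dim(v) - dim(y): the latent
#' space must carry exactly the information the 16 outputs cannot, for
#' the 23 inputs to be recoverable. Loss penalties follow the joint
#' objective: `beta_d` on the input-reconstruction MSE, `beta_v` on the
#' KL divergence of the variational latent space, `beta_r` on the
#' re-evaluation loss through the frozen emulator; each term is a
#' per-sample sum over components, averaged over the batch.
#'
#' Profiles: `"desk"` is a reduced-size profile (smaller flow, fewer
#' epochs) for continuous testing; `"synthetic"` mirrors the noiseless
#' full-scale study; `"ehr"` adds measurement-noise injection
#' (delta = 0.5), L2 weight decay, and a lower input-reconstruction
#' penalty against overfitting.
#'
#' @param profile `"desk"`, `"synthetic"` or `"ehr"`
#' @param ... named overrides of any configuration field
#' @return list of class `invaert_config`
#' @export
training_config <- function(profile = c("desk", "synthetic", "ehr"), ...) {
  profile <- match.arg(profile)
  cfg <- list(profile = profile,
              dim_v = 23L, dim_y = 16L, dim_w = 7L,
              hidden_emulator = c(64, 64),
              hidden_encoder = c(64),
              hidden_decoder = c(96, 96),
              flow_layers = 6L, flow_hidden = 96L, s_cap = 2,
              epochs_emulator = 800L, epochs_flow = 800L, epochs_vae = 2500L,
              batch_size = 128L, lr = 2e-3, weight_decay = 0,
              beta_d = 0.2, beta_v = 0.02, beta_r = 3,
              reeval_prior_w = TRUE,
              delta = 0, seed = 1L)
  if (profile == "synthetic") {
    cfg$flow_layers <- 8L
    cfg$hidden_emulator <- c(128, 128); cfg$hidden_decoder <- c(128, 128)
    cfg$epochs_emulator <- 3000L; cfg$epochs_flow <- 1500L; cfg$epochs_vae <- 3000L
  } else if (profile == "ehr") {
    cfg$flow_layers <- 8L
    cfg$delta <- 0.5; cfg$weight_decay <- 1e-4; cfg$beta_d <- 0.1
    cfg$epochs_emulator <- 2000L; cfg$epochs_flow <- 1000L; cfg$epochs_vae <- 1500L
  }
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  if (cfg$dim_w < 1) stop("dim_w must be >= 1")
  if (any(c(cfg$beta_d, cfg$beta_v, cfg$beta_r) < 0)) stop("beta penalties must be >= 0")
  if (cfg$delta < 0) stop("delta must be >= 0")
  structure(cfg, class = "invaert_config")
}

# stepwise learning-rate decay: halve at 50% and 75% of the schedule
lr_at <- function(lr, epoch, epochs) {
  lr * 0.5^((epoch > 0.5 * epochs) + (epoch > 0.75 * epochs))
}

minibatches <- function(n, batch_size) {
  idx <- sample.int(n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}

#' Train the neural emulator
#'
#' Fits a dense feed-forward surrogate of the simulator input-to-output
#' map by minimizing the mean squared error on normalized data. No
#' measurement noise is ever injected here: the forward map is
#' deterministic.
#'
#' @param Vn_train,Yn_train normalized training inputs/outputs
#' @param Vn_test,Yn_test normalized online-test split (monitoring)
#' @param cfg a [training_config]
#' @return list with `net` (the emulator [mlp_init] network) and
#'   `history` (per-epoch train/test MSE)
#' @export
train_emulator <- function(Vn_train, Yn_train, Vn_test, Yn_test, cfg) {
  set.seed(cfg$seed + 101)
  net <- mlp_init(c(cfg$dim_v, cfg$hidden_emulator, cfg$dim_y))
  st <- adam_init(net)
  hist <- data.frame(epoch = integer(), train = numeric(), test = numeric())
  for (ep in seq_len(cfg$epochs_emulator)) {
    lr <- lr_at(cfg$lr, ep, cfg$epochs_emulator)
    for (bi in minibatches(nrow(Vn_train), cfg$batch_size)) {
      fwd <- mlp_forward(net, Vn_train[bi, , drop = FALSE])
      resid <- fwd$out - Yn_train[bi, , drop = FALSE]
      if (any(!is.finite(resid)))
        stop("NaN loss while training the emulator at epoch ", ep)
      g <- mlp_backward(net, fwd, 2 * resid / length(bi))
      up <- adam_step(net, g, st, lr, weight_decay = cfg$weight_decay)
      net <- up$net; st <- up$state
    }
    if (ep %% 10 == 0 || ep == cfg$epochs_emulator) {
      tr <- mean((mlp_forward(net, Vn_train)$out - Yn_train)^2)
      te <- mean((mlp_forward(net, Vn_test)$out - Yn_test)^2)
      hist <- rbind(hist, data.frame(epoch = ep, train = tr, test = te))
    }
  }
  list(net = net, history = hist)
}

#' Train the Real-NVP density estimator
#'
#' Maximum-likelihood training of the flow on (optionally
#' noise-corrupted) normalized outputs. When `cfg$delta > 0` a fresh
#' Gaussian corruption of the physical outputs is drawn at every epoch.
#'
#' @param Y_train,Y_test physical-unit output matrices
#' @param norm_y output normalization statistics
#' @param cfg a [training_config]
#' @param noise a [noise_model] (scaled by `cfg$delta`)
#' @return list with `flow`, `history`, and `noise_trace` (a per-epoch
#'   fingerprint of the injected corruption, for the fresh-draw contract)
#' @export
train_flow_density <- function(Y_train, Y_test, norm_y, cfg,
                               noise = noise_model(cfg$delta)) {
  set.seed(cfg$seed + 202)
  flow <- flow_init(cfg$dim_y, cfg$flow_layers, cfg$flow_hidden, cfg$s_cap)
  states <- lapply(flow$layers, function(l)
    list(s = adam_init(l$s_net), t = adam_init(l$t_net)))
  Yn_test <- apply_norm(Y_test, norm_y)
  hist <- data.frame(epoch = integer(), train = numeric(), test = numeric())
  noise_trace <- numeric(cfg$epochs_flow)
  for (ep in seq_len(cfg$epochs_flow)) {
    lr <- lr_at(cfg$lr, ep, cfg$epochs_flow)
    Yp <- if (noise$delta > 0) inject_noise(Y_train, noise) else Y_train
    noise_trace[ep] <- sum(Yp[1, ])
    Yn <- apply_norm(Yp, norm_y)
    last <- NA_real_
    for (bi in minibatches(nrow(Yn), cfg$batch_size)) {
      r <- flow_nll_grad(flow, Yn[bi, , drop = FALSE])
      if (!is.finite(r$loss)) stop("NaN loss while training the flow at epoch ", ep)
      last <- r$loss
      for (l in seq_along(flow$layers)) {
        up_s <- adam_step(flow$layers[[l]]$s_net, r$grads[[l]]$gs,
                          states[[l]]$s, lr, weight_decay = cfg$weight_decay)
        up_t <- adam_step(flow$layers[[l]]$t_net, r$grads[[l]]$gt,
                          states[[l]]$t, lr, weight_decay = cfg$weight_decay)
        flow$layers[[l]]$s_net <- up_s$net; states[[l]]$s <- up_s$state
        flow$layers[[l]]$t_net <- up_t$net; states[[l]]$t <- up_t$state
      }
    }
    if (ep %% 10 == 0 || ep == cfg$epochs_flow) {
      te <- -mean(flow_log_density(flow, Yn_test))
      hist <- rbind(hist, data.frame(epoch = ep, train = last, test = te))
    }
  }
  list(flow = flow, history = hist, noise_trace = noise_trace)
}

#' Closed-form KL divergence of the variational latent space
#'
#' KL between `N(mu, diag(sigma^2))` and the standard normal prior:
#' `0.5 * sum_k (mu_k^2 + sigma_k^2 - log sigma_k^2 - 1)`, always >= 0.
#'
#' @param mu mean vector, or matrix with one row per sample
#' @param sigma standard deviations (same shape, > 0)
#' @return scalar (vector input) or per-sample vector (matrix input)
#' @export
kl_term <- function(mu, sigma) {
  stopifnot(all(sigma > 0))
  v <- 0.5 * (mu^2 + sigma^2 - log(sigma^2) - 1)
  if (is.matrix(v)) rowSums(v) else sum(v)
}

#' Train the variational encoder and decoder jointly
#'
#' Minimizes `beta_d * |v - dec(y', w)|^2 + (beta_v/2) * KL +
#' beta_r * |y' - emu(dec(y', w))|^2` with `w = mu + eps * sigma`
#' (reparameterized) from the encoder, the emulator frozen, and `y'` a
#' fresh noise corruption of the outputs at every epoch (`y' = y` when
#' `cfg$delta = 0`).
#'
#' With `cfg$reeval_prior_w = TRUE` (the default) the re-evaluation term
#' is evaluated at latent draws from the standard-normal prior -- the
#' distribution the decoder sees at inversion time -- while the
#' input-reconstruction and KL terms keep the reparameterized posterior
#' draw. This trains output-consistency over the whole latent space
#' rather than only in the thin shells the encoder posterior visits.
#'
#' @param V_train,Y_train,V_test,Y_test physical-unit splits
#' @param emulator the trained (frozen) emulator network
#' @param norm_v,norm_y normalization statistics
#' @param cfg a [training_config]
#' @param noise a [noise_model]
#' @return list with `encoder`, `decoder`, `history`, `noise_trace`
#' @export
train_encoder_decoder <- function(V_train, Y_train, V_test, Y_test,
                                  emulator, norm_v, norm_y, cfg,
                                  noise = noise_model(cfg$delta)) {
  set.seed(cfg$seed + 303)
  dw <- cfg$dim_w
  enc <- mlp_init(c(cfg$dim_v, cfg$hidden_encoder, 2 * dw))
  dec <- mlp_init(c(cfg$dim_y + dw, cfg$hidden_decoder, cfg$dim_v))
  st_e <- adam_init(enc); st_d <- adam_init(dec)
  Vn_train <- apply_norm(V_train, norm_v)
  Vn_test <- apply_norm(V_test, norm_v)
  Yn_test <- apply_norm(Y_test, norm_y)
  hist <- data.frame(epoch = integer(), train = numeric(), test = numeric())
  noise_trace <- numeric(cfg$epochs_vae)
  emu_w_checksum <- sum(vapply(emulator$W, sum, 0))  # frozen-weight guard

  prior_w <- isTRUE(cfg$reeval_prior_w)

  vae_loss <- function(Vn, Yn, eps, w_tilde = NULL) {
    fe <- mlp_forward(enc, Vn)
    mu <- fe$out[, 1:dw, drop = FALSE]
    logvar <- fe$out[, dw + (1:dw), drop = FALSE]
    sg <- exp(0.5 * logvar)
    w <- mu + eps * sg
    fd <- mlp_forward(dec, cbind(Yn, w))
    if (is.null(w_tilde)) w_tilde <- if (prior_w) matrix(rnorm(nrow(Vn) * dw), ncol = dw)
    fdr <- if (prior_w) mlp_forward(dec, cbind(Yn, w_tilde)) else fd
    fr <- mlp_forward(emulator, fdr$out)
    n <- nrow(Vn)
    loss <- cfg$beta_d * sum((fd$out - Vn)^2) / n +
      0.5 * cfg$beta_v * sum(mu^2 + sg^2 - logvar - 1) / n +
      cfg$beta_r * sum((fr$out - Yn)^2) / n
    list(loss = loss, fe = fe, fd = fd, fdr = fdr, fr = fr,
         mu = mu, sg = sg, w = w)
  }

  for (ep in seq_len(cfg$epochs_vae)) {
    lr <- lr_at(cfg$lr, ep, cfg$epochs_vae)
    Yp <- if (noise$delta > 0) inject_noise(Y_train, noise) else Y_train
    noise_trace[ep] <- sum(Yp[1, ])
    Yn <- apply_norm(Yp, norm_y)
    for (bi in minibatches(nrow(Vn_train), cfg$batch_size)) {
      n <- length(bi)
      eps <- matrix(rnorm(n * dw), n, dw)
      fw <- vae_loss(Vn_train[bi, , drop = FALSE], Yn[bi, , drop = FALSE], eps)
      if (!is.finite(fw$loss))
        stop("NaN loss while training encoder/decoder at epoch ", ep)
      # gradient wrt decoded v: direct MSE + re-evaluation through frozen emulator
      d_vhat <- 2 * cfg$beta_d * (fw$fd$out - Vn_train[bi, , drop = FALSE]) / n
      g_emu <- mlp_backward(emulator, fw$fr,
                            2 * cfg$beta_r * (fw$fr$out - Yn[bi, , drop = FALSE]) / n)
      if (prior_w) {
        g_dec_r <- mlp_backward(dec, fw$fdr, g_emu$dX)
        g_dec <- mlp_backward(dec, fw$fd, d_vhat)
        g_dec <- list(dW = Map(`+`, g_dec$dW, g_dec_r$dW),
                      db = Map(`+`, g_dec$db, g_dec_r$db),
                      dX = g_dec$dX)
      } else {
        d_vhat <- d_vhat + g_emu$dX
        g_dec <- mlp_backward(dec, fw$fd, d_vhat)
      }
      d_w <- g_dec$dX[, cfg$dim_y + (1:dw), drop = FALSE]
      d_mu <- d_w + cfg$beta_v * fw$mu / n
      d_sg <- d_w * eps + cfg$beta_v * (fw$sg - 1 / fw$sg) / n
      d_logvar <- d_sg * fw$sg / 2
      g_enc <- mlp_backward(enc, fw$fe, cbind(d_mu, d_logvar))
      up <- adam_step(dec, g_dec, st_d, lr, weight_decay = cfg$weight_decay)
      dec <- up$net; st_d <- up$state
      up <- adam_step(enc, g_enc, st_e, lr, weight_decay = cfg$weight_decay)
      enc <- up$net; st_e <- up$state
    }
    if (ep %% 10 == 0 || ep == cfg$epochs_vae) {
      nt <- nrow(Vn_test)
      eps_t <- matrix(rnorm(nt * dw), nt, dw)
      te <- vae_loss(Vn_test, Yn_test, eps_t)$loss
      hist <- rbind(hist, data.frame(epoch = ep, train = fw$loss, test = te))
    }
  }
  stopifnot(sum(vapply(emulator$W, sum, 0)) == emu_w_checksum)
  list(encoder = enc, decoder = dec, history = hist, noise_trace = noise_trace)
}

#' Train a complete inVAErt model on a split dataset
#'
#' Orchestrates the three training stages in their required order: the
#' emulator first (frozen afterwards), the flow density estimator
#' independently, and the variational encoder/decoder last (using the
#' frozen emulator for the re-evaluation loss). Normalization statistics
#' are computed from the training split only and stored with the model.
#'
#' @param dataset a `cvsim_dataset` with a `split` column ([split_dataset])
#' @param cfg a [training_config]
#' @return object of class `invaert_model`: the four networks,
#'   normalization statistics, config, prior and training histories
#' @export
train_invaert <- function(dataset, cfg = training_config()) {
  stopifnot(inherits(dataset, "cvsim_dataset"), !is.null(dataset$split))
  tr <- dataset$split == "train"; te <- dataset$split == "test"
  norm_v <- normalize_stats(dataset$V[tr, , drop = FALSE])
  norm_y <- normalize_stats(dataset$Y[tr, , drop = FALSE])
  Vn_tr <- apply_norm(dataset$V[tr, , drop = FALSE], norm_v)
  Yn_tr <- apply_norm(dataset$Y[tr, , drop = FALSE], norm_y)
  Vn_te <- apply_norm(dataset$V[te, , drop = FALSE], norm_v)
  Yn_te <- apply_norm(dataset$Y[te, , drop = FALSE], norm_y)
  noise <- noise_model(cfg$delta)

  emu <- train_emulator(Vn_tr, Yn_tr, Vn_te, Yn_te, cfg)
  flw <- train_flow_density(dataset$Y[tr, , drop = FALSE],
                            dataset$Y[te, , drop = FALSE], norm_y, cfg, noise)
  vae <- train_encoder_decoder(dataset$V[tr, , drop = FALSE],
                               dataset$Y[tr, , drop = FALSE],
                               dataset$V[te, , drop = FALSE],
                               dataset$Y[te, , drop = FALSE],
                               emu$net, norm_v, norm_y, cfg, noise)
  structure(list(emulator = emu$net, flow = flw$flow,
                 encoder = vae$encoder, decoder = vae$decoder,
                 norm_v = norm_v, norm_y = norm_y, cfg = cfg,
                 prior = dataset$prior,
                 history = list(emulator = emu$history, flow = flw$history,
                                vae = vae$history,
                                noise_trace = list(flow = flw$noise_trace,
                                                   vae = vae$noise_trace))),
            class = "invaert_model")
}

#' @export
print.invaert_model <- function(x, ...) {
  cat("inVAErt model (profile:", x$cfg$profile, ")\n")
  cat("  emulator MSE (test):", utils::tail(x$history$emulator$test, 1), "\n")
  cat("  flow NLL (test):    ", utils::tail(x$history$flow$test, 1), "\n")
  cat("  vae loss (test):    ", utils::tail(x$history$vae$test, 1), "\n")
  invisible(x)
}

#' Predict clinical outputs with the trained emulator
#'
#' @param model an `invaert_model`
#' @param v parameter vector (23) or matrix (n x 23), physical units
#' @return outputs in Table-2 units (n x 16 matrix); the attribute
#'   `out_of_box` flags rows outside the training prior box (the network
#'   still predicts, with a warning)
#' @export
emulate <- function(model, v) {
  V <- if (is.null(dim(v))) matrix(v, 1, dimnames = list(NULL, names(v))) else v
  oob <- rep(FALSE, nrow(V))
  if (!is.null(model$prior)) {
    oob <- apply(V, 1, function(r)
      any(r < model$prior$lower - 1e-12) || any(r > model$prior$upper + 1e-12))
    if (any(oob)) warning(sum(oob), " input(s) outside the training prior box")
  }
  Y <- invert_norm(mlp_forward(model$emulator, apply_norm(V, model$norm_v))$out,
                   model$norm_y)
  colnames(Y) <- OUTPUT_NAMES
  structure(Y, out_of_box = oob)
}

#' Encode parameters into the variational latent space
#'
#' Reparameterized draw `w = mu + eps * sigma`, `eps ~ N(0, I)`.
#'
#' @param model an `invaert_model`
#' @param v parameter vector/matrix (physical units)
#' @param seed optional seed for `eps`
#' @param eps optional fixed standard-normal draw (overrides `seed`)
#' @return list with `w`, `mu`, `sigma` (n x dim_w matrices)
#' @export
encode <- function(model, v, seed = NULL, eps = NULL) {
  V <- if (is.null(dim(v))) matrix(v, 1, dimnames = list(NULL, names(v))) else v
  dw <- model$cfg$dim_w
  out <- mlp_forward(model$encoder, apply_norm(V, model$norm_v))$out
  mu <- out[, 1:dw, drop = FALSE]
  sigma <- exp(0.5 * out[, dw + (1:dw), drop = FALSE])
  if (is.null(eps)) {
    if (!is.null(seed)) set.seed(seed)
    eps <- matrix(rnorm(nrow(V) * dw), nrow(V), dw)
  }
  list(w = mu + eps * sigma, mu = mu, sigma = sigma)
}

#' Decode an observation and latent draw into parameters
#'
#' @param model an `invaert_model`
#' @param y output vector (16, Table-2 units) or n x 16 matrix
#' @param w latent vector (dim_w) or n x dim_w matrix
#' @return decoded parameter matrix (n x 23, physical units)
#' @export
decode <- function(model, y, w) {
  Y <- if (is.null(dim(y))) matrix(y, 1, dimnames = list(NULL, names(y))) else y
  W <- if (is.null(dim(w))) matrix(w, 1) else w
  if (nrow(Y) == 1 && nrow(W) > 1) Y <- Y[rep(1, nrow(W)), , drop = FALSE]
  Yn <- apply_norm(Y, model$norm_y)
  V <- invert_norm(mlp_forward(model$decoder, cbind(Yn, W))$out, model$norm_v)
  colnames(V) <- PARAM_NAMES
  V
}

# ---- serialization ----------------------------------------------------

mlp_to_list <- function(net) list(sizes = net$sizes, W = net$W, b = net$b)
mlp_from_list <- function(x) {
  structure(list(W = lapply(x$W, as.matrix), b = lapply(x$b, as.numeric),
                 sizes = as.numeric(x$sizes)), class = "mlp")
}

#' Save / load a trained inVAErt model (JSON bundle)
#'
#' All weights are written in full double precision so a round trip
#' reproduces network outputs bit-identically.
#'
#' @param model an `invaert_model`
#' @param path JSON file path
#' @return invisibly `path` / the restored model
#' @export
save_model <- function(model, path) {
  flow <- model$flow
  bundle <- list(
    emulator = mlp_to_list(model$emulator),
    encoder = mlp_to_list(model$encoder),
    decoder = mlp_to_list(model$decoder),
    flow = list(dim = flow$dim, s_cap = flow$s_cap,
                layers = lapply(flow$layers, function(l)
                  list(mask = l$mask, s_net = mlp_to_list(l$s_net),
                       t_net = mlp_to_list(l$t_net)))),
    norm_v = model$norm_v, norm_y = model$norm_y,
    cfg = unclass(model$cfg),
    prior = if (!is.null(model$prior)) list(
      preset = model$prior$preset,
      rel_lower = model$prior$rel_lower, rel_upper = model$prior$rel_upper,
      lower = model$prior$lower, upper = model$prior$upper))
  json <- jsonlite::serializeJSON(bundle, digits = 17)
  writeLines(json, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  b <- jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
  flow <- structure(list(dim = b$flow$dim, s_cap = b$flow$s_cap,
                         layers = lapply(b$flow$layers, function(l)
                           list(mask = as.numeric(l$mask),
                                s_net = mlp_from_list(l$s_net),
                                t_net = mlp_from_list(l$t_net)))),
                    class = "rnvp_flow")
  prior <- NULL
  if (!is.null(b$prior)) {
    prior <- structure(list(preset = b$prior$preset,
                            reference = default_parameters(),
                            rel_lower = b$prior$rel_lower,
                            rel_upper = b$prior$rel_upper,
                            lower = b$prior$lower, upper = b$prior$upper),
                       class = "cvsim_prior")
  }
  structure(list(emulator = mlp_from_list(b$emulator), flow = flow,
                 encoder = mlp_from_list(b$encoder),
                 decoder = mlp_from_list(b$decoder),
                 norm_v = b$norm_v, norm_y = b$norm_y,
                 cfg = structure(b$cfg, class = "invaert_config"),
                 prior = prior, history = NULL),
            class = "invaert_model")
}
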