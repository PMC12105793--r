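# Shared expensive fixtures, built lazily and cached for the whole run:
# a reference default-parameter trajectory, a 2000-sample synthetic-prior
# dataset, and a desk-profile trained inVAErt model.

.shared <- new.env(parent = emptyenv())

shared_default_trajectory <- function() {
  if (is.null(.shared$traj))
    .shared$traj <- simulate_cvsim(default_parameters())
  .shared$traj
}

shared_dataset <- function() {
  if (is.null(.shared$ds)) {
    prior <- prior_spec("synthetic")
    V <- sample_prior(prior, 2000, seed = 11)
    ds <- build_dataset(V, sim_config(), prior = prior, seed = 11)
    .shared$ds <- split_dataset(ds, "synthetic", seed = 11)
  }
  .shared$ds
}

shared_model <- function() {
  if (is.null(.shared$model))
    .shared$model <- train_invaert(shared_dataset(), desk_training_config())
  .shared$model
}

# the desk-scale training profile used across the suite
desk_training_config <- function() training_config("desk", seed = 1)

# componentwise relative errors against a target vector
relerr_rows <- function(y, Y_hat) {
  apply(abs(sweep(Y_hat, 2, y, "-")) /
          matrix(abs(y), nrow(Y_hat), length(y), byrow = TRUE), 1, max)
}

# vector-relative (l2) errors against a target vector
l2err_rows <- function(y, Y_hat) {
  sqrt(rowSums(sweep(Y_hat, 2, y, "-")^2) / sum(y^2))
}

# the inversion-quality quantities shared by the quality-gate tests:
# computed once, at the desk-scale study conditions
shared_gates <- function() {
  if (!is.null(.shared$gates)) return(.shared$gates)
  ds <- shared_dataset()
  model <- shared_model()
  val <- which(ds$split == "validation")

  # emulator accuracy on the offline validation split
  Yp <- emulate(model, ds$V[val, ])
  emu_l2 <- sqrt(rowSums((Yp - ds$Y[val, ])^2) / rowSums(ds$Y[val, ]^2))

  # decode-then-re-evaluate through the exact simulator on held-out outputs
  set.seed(5)
  pick <- sample(val, 80)
  set.seed(21)
  W <- matrix(rnorm(80 * model$cfg$dim_w), 80)
  Vhat <- decode(model, ds$Y[pick, ], W)
  dec_l2 <- dec_hr <- rep(NA_real_, 80)
  for (i in seq_len(80)) {
    traj <- simulate_cvsim(setNames(Vhat[i, ], PARAM_NAMES))
    if (inherits(traj, "cvsim_failure")) next
    yh <- as.numeric(extract_outputs(traj))
    dec_l2[i] <- sqrt(sum((yh - ds$Y[pick[i], ])^2) / sum(ds$Y[pick[i], ]^2))
    dec_hr[i] <- abs(yh[1] - ds$Y[pick[i], 1])
  }

  # manifold of a flow-sampled observation y*
  ystar <- invert_norm(flow_sample(model$flow, 1, seed = 3), model$norm_y)[1, ]
  names(ystar) <- OUTPUT_NAMES
  ms <- invert_observation(model, ystar, Nw = 100, seed = 4)
  rep_star <- verify_solutions(ms, "exact")
  star_l2 <- l2err_rows(ystar, rep_star$samples$Y_hat)
  ranges <- apply(ms$V_hat, 2, function(x) diff(range(x))) /
    (model$prior$upper - model$prior$lower)
  spectrum <- manifold_spectrum(ms$V_hat)

  # density-ranked completion of y* with seven components missing,
  # top four completions x five latent draws, re-simulated exactly
  y_miss <- ystar
  y_miss[c("Pa_dia", "Pr_dia", "Ppa_dia", "Pw", "Vl_sys", "SVR", "PVR")] <- NA
  imp <- impute_and_rank(model, y_miss, M = 60000, K = 4, seed = 6)
  obs <- imp$observed
  imp_l2 <- c()
  for (k in seq_len(nrow(imp$candidates))) for (w in 1:5) {
    msk <- invert_observation(model, imp$candidates[k, ], Nw = 1,
                              seed = 100 + 5 * k + w)
    traj <- simulate_cvsim(setNames(msk$V_hat[1, ], PARAM_NAMES))
    if (inherits(traj, "cvsim_failure")) next
    yh <- as.numeric(extract_outputs(traj))
    imp_l2 <- c(imp_l2, sqrt(sum((yh[obs] - ystar[obs])^2) / sum(ystar[obs]^2)))
  }

  .shared$gates <- list(emu_l2 = emu_l2, dec_l2 = dec_l2, dec_hr = dec_hr,
                        ystar = ystar, star_l2 = star_l2,
                        star_report = rep_star, ranges = ranges,
                        spectrum = spectrum, imp = imp, imp_l2 = imp_l2)
  .shared$gates
}
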