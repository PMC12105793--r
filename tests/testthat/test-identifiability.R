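test_that("inversion draws reproducible manifold samples", {
  model <- shared_model()
  ds <- shared_dataset()
  y <- ds$Y[10, ]
  ms1 <- invert_observation(model, y, Nw = 8, seed = 2)
  ms2 <- invert_observation(model, y, Nw = 8, seed = 2)
  expect_identical(ms1$V_hat, ms2$V_hat)
  expect_equal(dim(ms1$V_hat), c(8L, 23L))
  expect_equal(dim(ms1$W), c(8L, model$cfg$dim_w))
  # Nw = 1 is the single-point inversion
  ms3 <- invert_observation(model, y, Nw = 1, seed = 2)
  expect_equal(dim(ms3$V_hat), c(1L, 23L))
  # masked observations are rejected
  y_na <- y; y_na[3] <- NA
  expect_error(invert_observation(model, y_na, 4), "missing entries")
})

test_that("verify_solutions reports exact-zero error for ground-truth inputs", {
  ds <- shared_dataset()
  y <- ds$Y[7, ]
  ms <- structure(list(y = setNames(y, OUTPUT_NAMES), W = matrix(0, 1, 7),
                       V_hat = ds$V[7, , drop = FALSE], Y_hat = NULL,
                       evaluator = NA_character_),
                  class = "manifold_samples")
  rep <- verify_solutions(ms, "exact")
  expect_equal(rep$n_failed, 0)
  expect_lt(max(rep$abs_err), 1e-10)
  expect_lt(rep$max_rel_error, 1e-12)
})

test_that("error summaries match hand arithmetic on a two-row toy", {
  y <- setNames(c(70, rep(100, 15)), OUTPUT_NAMES)
  Y_hat <- rbind(y, y)
  Y_hat[1, "Hr"] <- 73    # |err| = 3
  Y_hat[2, "Hr"] <- 69    # |err| = 1
  ms <- structure(list(y = y, W = matrix(0, 2, 7),
                       V_hat = matrix(0, 2, 23), Y_hat = Y_hat,
                       evaluator = "precomputed"),
                  class = "manifold_samples")
  rep <- verify_solutions(ms, "precomputed")
  expect_equal(unname(rep$summary["average", "Hr"]), 2)
  expect_equal(unname(rep$summary["max", "Hr"]), 3)
  expect_equal(unname(rep$summary["SD", "Hr"]), sd(c(3, 1)))
  expect_equal(rep$max_rel_error, 3 / 70)
})

test_that("manifold spectrum yields monotone cumulative energy", {
  model <- shared_model()
  ms <- invert_observation(model, shared_dataset()$Y[12, ], Nw = 60, seed = 3)
  sp <- manifold_spectrum(ms$V_hat)
  ce <- sp$cumulative_energy
  expect_true(all(diff(ce) >= -1e-12))
  expect_equal(ce[length(ce)], 1, tolerance = 1e-12)
  expect_false(sp$degenerate)
  # near-repeated rows concentrate all energy in the first mode
  base <- matrix(rep(ms$V_hat[1, ], 10), 10, byrow = TRUE)
  jit <- base + matrix(rnorm(230, sd = 1e-9), 10)
  expect_gt(manifold_spectrum(jit)$cumulative_energy[1], 0.99 - 1e-6)
  expect_true(manifold_spectrum(base)$degenerate)
  expect_error(manifold_spectrum(ms$V_hat[1, , drop = FALSE]))
})

test_that("identifiable parameters span far less of the prior than unidentifiable ones", {
  model <- shared_model()
  ystar <- invert_norm(flow_sample(model$flow, 1, seed = 3), model$norm_y)[1, ]
  names(ystar) <- OUTPUT_NAMES
  ms <- invert_observation(model, ystar, Nw = 100, seed = 4)
  rng <- apply(ms$V_hat, 2, function(x) diff(range(x))) /
    (model$prior$upper - model$prior$lower)
  narrow <- rng[c("Ra", "Rpv")]
  wide <- rng[c("Cv", "Cr_sys", "Cpv")]
  expect_lt(max(narrow), min(wide))
})

test_that("imputation passes measurements through and ranks by density", {
  model <- shared_model()
  y_full <- setNames(shared_dataset()$Y[15, ], OUTPUT_NAMES)
  # complete observation: returned unchanged with K = 1
  imp0 <- impute_and_rank(model, y_full, M = 500, K = 3, seed = 1)
  expect_equal(imp0$n_retained, 1L)
  expect_equal(imp0$candidates[1, ], y_full, tolerance = 1e-12)
  # missing entries: observed components equal the measurements exactly
  y_miss <- y_full
  y_miss[c("Pa_dia", "Pr_dia", "Ppa_dia", "Pw", "Vl_sys", "SVR", "PVR")] <- NA
  imp <- impute_and_rank(model, y_miss, M = 4000, K = 4, seed = 2)
  obs <- !is.na(y_miss)
  for (k in seq_len(nrow(imp$candidates)))
    expect_identical(unname(imp$candidates[k, obs]), unname(y_full[obs]))
  expect_true(all(diff(imp$log_density) <= 1e-12))   # non-increasing ranking
  expect_true(all(is.finite(imp$candidates)))
  expect_error(impute_and_rank(model, setNames(rep(NA_real_, 16), OUTPUT_NAMES)),
               "at least one observed")
})

test_that("componentwise cohort error matches the defining average", {
  # 2 patients, Nw = 2, single attribute with hand-set offsets {1,3} and {2,2}
  tab <- as.data.frame(matrix(NA_real_, 2, 16, dimnames = list(NULL, OUTPUT_NAMES)))
  tab$Hr <- c(70, 80)
  preds <- list(
    rbind(setNames(rep(0, 16), OUTPUT_NAMES), rep(0, 16)),
    rbind(setNames(rep(0, 16), OUTPUT_NAMES), rep(0, 16)))
  preds[[1]][, "Hr"] <- c(71, 73)   # |errs| 1, 3
  preds[[2]][, "Hr"] <- c(78, 78)   # |errs| 2, 2
  err <- componentwise_error(preds, tab)
  expect_equal(err$e[err$attribute == "Hr"], 2)
  expect_equal(err$count[err$attribute == "Hr"], 2)
  # attribute observed by no patient is undefined, not zero
  expect_true(is.na(err$e[err$attribute == "Vl_sys"]))
  expect_equal(err$count[err$attribute == "Vl_sys"], 0)
  # perfect predictions give zero error
  preds[[1]][, "Hr"] <- 70; preds[[2]][, "Hr"] <- 80
  expect_equal(componentwise_error(preds, tab)$e[1], 0)
})

test_that("the EHR pipeline filters, completes and inverts patients", {
  model <- shared_model()
  ds <- shared_dataset()
  tab <- synthesize_ehr_table(ds, n_patients = 84, noise = noise_model(0.5),
                              seed = 31)
  n_obs <- rowSums(!is.na(tab))
  expect_true(any(n_obs > 10) && any(n_obs <= 10))  # both strata present
  ehr <- suppressWarnings(
    ehr_pipeline(model, tab, Nw = 10, seed = 5, M = 4000))
  expect_equal(length(ehr$patients) + length(ehr$skipped), 84)
  expect_equal(sort(c(vapply(ehr$patients, function(p) p$row, 0L), ehr$skipped)),
               1:84)
  expect_true(all(n_obs[ehr$skipped] <= 10))
  p1 <- ehr$patients[[1]]
  expect_equal(dim(p1$samples$V_hat), c(10L, 23L))   # Nw x 23
  expect_equal(dim(p1$samples$Y_hat), c(10L, 16L))   # Nw x 16
  expect_false(anyNA(p1$completed))
  err <- componentwise_error(ehr, tab)
  expect_equal(nrow(err), 16)
  expect_true(is.na(err$e[err$attribute == "Vl_sys"]))  # never measured
  expect_true(all(err$e[err$count > 0] >= 0))
  # rows with no observations at all are rejected
  tab0 <- tab; tab0[1, ] <- NA
  expect_error(ehr_pipeline(model, tab0, Nw = 2), "zero observed")
})

test_that("parallel-coordinate export carries values and widened bounds", {
  model <- shared_model()
  prior <- prior_spec("synthetic")
  ms <- invert_observation(model, shared_dataset()$Y[20, ], Nw = 9, seed = 6)
  pc <- export_parallel_coordinates(ms, prior)
  expect_equal(nrow(pc), 9 * 23)
  span <- prior$upper - prior$lower
  for (nm in c("Ra", "Cv")) {
    rows <- pc[pc$parameter == nm, ]
    expect_equal(rows$lower[1], unname(prior$lower[[nm]] - 0.05 * span[[nm]]))
    expect_equal(rows$upper[1], unname(prior$upper[[nm]] + 0.05 * span[[nm]]))
    expect_equal(rows$value, unname(ms$V_hat[, nm]))
  }
  f <- tempfile(fileext = ".csv")
  write.csv(pc, f, row.names = FALSE)
  back <- read.csv(f)
  expect_equal(back$value, pc$value, tolerance = 1e-12)
})
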