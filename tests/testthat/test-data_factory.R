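test_that("prior presets produce the documented boxes", {
  pr <- prior_spec("synthetic")
  expect_equal(unname(pr$lower[["Ca"]]), 0.5 * 1.2e-3)
  expect_equal(unname(pr$upper[["Ca"]]), 1.5 * 1.2e-3)
  expect_equal(unname(pr$lower[["Ra"]]), 0.7 * 1333.22)
  # Pth is negative: the box straddles the reference magnitude correctly
  expect_equal(unname(sort(c(pr$lower[["Pth"]], pr$upper[["Pth"]]))),
               c(-5.2, -2.8))
  pe <- prior_spec("ehr")
  expect_equal(unname(pe$lower[["Hr"]]), 0.8 * 72)
  expect_equal(unname(pe$upper[["Hr"]]), 1.6 * 72)
  expect_equal(unname(pe$lower[["Ra"]]), 0.2 * 1333.22)
  expect_error(prior_spec("synthetic", rel_lower = c(Hr = 0.5),
                          rel_upper = c(Hr = 0.2)), "below upper")
})

test_that("prior sampling stays in the box and is seed-reproducible", {
  pr <- prior_spec("synthetic")
  V1 <- sample_prior(pr, 200, seed = 7)
  V2 <- sample_prior(pr, 200, seed = 7)
  expect_identical(V1, V2)
  expect_true(all(sweep(V1, 2, pr$lower, ">=")))
  expect_true(all(sweep(V1, 2, pr$upper, "<=")))
  expect_true(all(V1[, "Ca"] >= 0.5 * 1.2e-3 & V1[, "Ca"] <= 1.5 * 1.2e-3))
})

test_that("dataset generation is deterministic and drops invalid rows", {
  pr <- prior_spec("synthetic")
  V <- sample_prior(pr, 8, seed = 3)
  V[3, "rsys"] <- 1.5  # deliberately invalid row
  ds <- build_dataset(V, sim_config(n_cycles = 6), prior = pr, seed = 3)
  expect_equal(nrow(ds$V), 7)
  expect_equal(ds$failures$row, 3)
  expect_match(ds$failures$message, "rsys")
  # re-simulating rows reproduces the stored outputs exactly
  for (i in c(1, 5)) {
    traj <- simulate_cvsim(setNames(ds$V[i, ], PARAM_NAMES),
                           sim_config(n_cycles = 6))
    expect_equal(as.numeric(extract_outputs(traj)), ds$Y[i, ],
                 ignore_attr = TRUE, tolerance = 1e-14)
  }
})

test_that("splits reproduce the study proportions at full and reduced scale", {
  fake <- structure(list(V = matrix(0, 54000, 23), Y = matrix(0, 54000, 16),
                         failures = data.frame()), class = "cvsim_dataset")
  sp <- split_dataset(fake, "synthetic", seed = 1)
  expect_equal(as.numeric(table(sp$split)), c(37500, 12500, 4000))
  sp2 <- split_dataset(fake, "ehr", seed = 1)
  expect_equal(as.numeric(table(sp2$split)), c(37500, 12500, 4000))
  # reduced scale keeps the ratios: validation 4/54, remainder 3:1
  fake$V <- matrix(0, 2000, 23); fake$Y <- matrix(0, 2000, 16)
  sp3 <- split_dataset(fake, "synthetic", seed = 2)
  n <- as.numeric(table(sp3$split))
  expect_equal(n[3], round(2000 * 4000 / 54000))
  expect_equal(n[1], round((2000 - n[3]) * 3 / 4))
  expect_equal(sum(n), 2000)         # exhaustive
  expect_identical(split_dataset(fake, "synthetic", seed = 2)$split, sp3$split)
  fake$V <- matrix(0, 5, 23)
  expect_error(split_dataset(fake, "synthetic"), "too small")
})

test_that("normalization round trip is exact to 1e-12", {
  set.seed(1)
  X <- matrix(rnorm(600, mean = 5, sd = 3), 50, 12)
  st <- normalize_stats(X)
  expect_equal(invert_norm(apply_norm(X, st), st), X, tolerance = 1e-12)
  Z <- apply_norm(X, st)
  expect_equal(colMeans(Z), rep(0, 12), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(apply(Z, 2, sd), rep(1, 12), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("noise injection matches the heteroskedastic model", {
  expect_error(noise_model(-1), "delta")
  Y <- matrix(rep(c(72, 120), each = 1e5), ncol = 16, nrow = 1e5)
  colnames(Y) <- OUTPUT_NAMES
  # delta = 0 is the identity
  expect_identical(inject_noise(Y[1:10, ], noise_model(0)), Y[1:10, ])
  Y1 <- inject_noise(Y, noise_model(1), seed = 5)
  emp_sd <- apply(Y1 - Y, 2, sd)
  expect_equal(unname(emp_sd[1]), 3.0, tolerance = 0.02)   # Hr column
  expect_equal(unname(emp_sd), unname(OUTPUT_STD), tolerance = 0.02 * 20)
  expect_equal(unname(emp_sd / OUTPUT_STD), rep(1, 16), tolerance = 0.02)
  # delta = 2 doubles every column's std
  Y2 <- inject_noise(Y, noise_model(2), seed = 6)
  expect_equal(unname(apply(Y2 - Y, 2, sd) / emp_sd), rep(2, 16),
               tolerance = 0.03)
  # independence across entries
  E <- (Y1 - Y)
  cors <- cor(E[, c(1, 4, 9, 14)])
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.02)
})

test_that("synthetic EHR tables honour the missingness specification", {
  ds <- list(V = sample_prior(prior_spec("synthetic"), 300, seed = 2),
             Y = matrix(rnorm(300 * 16, 50, 5), 300, 16,
                        dimnames = list(NULL, OUTPUT_NAMES)))
  class(ds) <- "cvsim_dataset"
  # observation probability 1 everywhere: no missing cells
  tab <- synthesize_ehr_table(ds, 40, missingness = rep(1, 16),
                              noise = noise_model(0), seed = 1)
  expect_false(anyNA(tab))
  expect_equal(as.matrix(tab), attr(tab, "truth_Y"), ignore_attr = TRUE)
  # probabilities out of range rejected
  expect_error(synthesize_ehr_table(ds, 10, missingness = rep(1.4, 16)),
               "probabilities")
  # a spec with >= 11 expected observed attributes passes the >10 filter
  p11 <- c(rep(1, 12), rep(0, 4))
  tab11 <- synthesize_ehr_table(ds, 30, missingness = p11, seed = 2)
  expect_true(all(rowSums(!is.na(tab11)) > 10))
  # empirical missingness matches the spec within binomial error
  p <- c(rep(0.7, 8), rep(0.2, 8))
  tabp <- synthesize_ehr_table(ds, 1000, missingness = p, seed = 3,
                               noise = noise_model(0))
  obs_rate <- colMeans(!is.na(tabp))
  se <- sqrt(p * (1 - p) / 1000)
  expect_true(all(abs(obs_rate - p) < 4 * se + 1e-3))
})

test_that("EHR table CSV round trip preserves missing cells", {
  ds <- list(V = matrix(1, 20, 23), Y = matrix(rnorm(20 * 16, 60, 4), 20, 16,
                                               dimnames = list(NULL, OUTPUT_NAMES)))
  class(ds) <- "cvsim_dataset"
  tab <- synthesize_ehr_table(ds, 20, missingness = rep(0.6, 16), seed = 9)
  f <- tempfile(fileext = ".csv")
  write_ehr_table(tab, f)
  # empty cells on disk, not "NA" strings
  expect_false(grepl("NA", readLines(f)[2], fixed = TRUE) &&
                 !anyNA(tab[1, ]))
  back <- read_ehr_table(f)
  expect_equal(as.matrix(back), as.matrix(tab), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_identical(is.na(back), is.na(tab[OUTPUT_NAMES]), ignore_attr = TRUE)
})

test_that("dataset directory round trip preserves data and split", {
  pr <- prior_spec("synthetic")
  V <- sample_prior(pr, 12, seed = 4)
  ds <- build_dataset(V, sim_config(n_cycles = 4), prior = pr, seed = 4)
  ds <- split_dataset(ds, "synthetic", seed = 4)
  d <- file.path(tempdir(), "ds_roundtrip")
  write_dataset(ds, d)
  back <- read_dataset(d)
  expect_equal(back$V, ds$V, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(back$Y, ds$Y, tolerance = 1e-10, ignore_attr = TRUE)
  expect_identical(back$split, ds$split)
  expect_equal(back$seed, 4)
})
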