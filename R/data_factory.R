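#' Uniform prior over the CVSim-6 parameter box
#'
#' Per-parameter lower/upper bounds expressed as multiplicative
#' perturbations of the reference (default) parameter set. Two presets
#' are provided: `"synthetic"` lets every capacitance vary by +/-50% and
#' all other parameters by +/-30%; `"ehr"` widens the box for real-data
#' coverage (heart rate -20%..+60%, every capacitance and resistance
#' -80%..+60%, remaining parameters +/-30%).
#'
#' @param preset `"synthetic"` or `"ehr"`
#' @param reference reference parameter set (default [default_parameters])
#' @param rel_lower,rel_upper optional named numeric overrides of the
#'   per-parameter relative bounds (e.g. `c(Hr = -0.1)`)
#' @return object of class `cvsim_prior` with `lower`/`upper` absolute
#'   bounds (reference + rel * |reference|), the relative bounds, and the
#'   preset name
#' @export
prior_spec <- function(preset = c("synthetic", "ehr"),
                       reference = default_parameters(),
                       rel_lower = NULL, rel_upper = NULL) {
  preset <- match.arg(preset)
  reference <- as_cvsim_params(reference)
  caps <- c("Cl_dia", "Cl_sys", "Ca", "Cv", "Cr_dia", "Cr_sys", "Cpa", "Cpv")
  res <- c("Rl_in", "Rl_out", "Ra", "Rr_in", "Rr_out", "Rpv")
  lo <- setNames(rep(-0.3, 23), PARAM_NAMES)
  hi <- setNames(rep(0.3, 23), PARAM_NAMES)
  if (preset == "synthetic") {
    lo[caps] <- -0.5; hi[caps] <- 0.5
  } else {
    lo["Hr"] <- -0.2; hi["Hr"] <- 0.6
    lo[c(caps, res)] <- -0.8; hi[c(caps, res)] <- 0.6
  }
  if (!is.null(rel_lower)) lo[names(rel_lower)] <- rel_lower
  if (!is.null(rel_upper)) hi[names(rel_upper)] <- rel_upper
  if (any(lo >= hi)) stop("prior lower bounds must be below upper bounds")
  lower <- as.numeric(reference) + lo * abs(as.numeric(reference))
  upper <- as.numeric(reference) + hi * abs(as.numeric(reference))
  names(lower) <- names(upper) <- PARAM_NAMES
  structure(list(preset = preset, reference = reference,
                 rel_lower = lo, rel_upper = hi,
                 lower = lower, upper = upper),
            class = "cvsim_prior")
}

#' Sample parameter vectors from a uniform prior
#'
#' @param prior a [prior_spec] object
#' @param n number of draws
#' @param seed integer seed for reproducibility
#' @return n x 23 matrix, one parameter vector per row
#' @export
sample_prior <- function(prior, n, seed = NULL) {
  stopifnot(inherits(prior, "cvsim_prior"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  u <- matrix(runif(n * 23), n, 23)
  V <- sweep(sweep(u, 2, prior$upper - prior$lower, "*"), 2, prior$lower, "+")
  colnames(V) <- PARAM_NAMES
  V
}

#' Generate an input-output dataset by running the simulator
#'
#' Runs the CVSim-6 simulator and clinical-output extraction for every
#' parameter row. Invalid parameter combinations and solver failures are
#' dropped and logged (their row indices and messages retained); if more
#' than half of the rows fail the generation aborts with diagnostics.
#'
#' @param V n x 23 parameter matrix (e.g. from [sample_prior])
#' @param config a [sim_config]
#' @param prior the generating prior (stored for provenance), or `NULL`
#' @param seed generation seed (stored for provenance)
#' @param progress print a progress line every `progress` rows (0 = quiet)
#' @return object of class `cvsim_dataset`: list with `V` (kept rows),
#'   `Y` (matching outputs, Table-2 units), `failures` (data frame of
#'   dropped rows), `config`, `prior`, `seed`
#' @export
build_dataset <- function(V, config = sim_config(), prior = NULL,
                          seed = NULL, progress = 0) {
  stopifnot(is.matrix(V), ncol(V) == 23)
  n <- nrow(V)
  Y <- matrix(NA_real_, n, 16, dimnames = list(NULL, OUTPUT_NAMES))
  ok <- logical(n)
  msgs <- character(n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      traj <- simulate_cvsim(setNames(V[i, ], PARAM_NAMES), config)
      if (inherits(traj, "cvsim_failure")) traj else extract_outputs(traj)
    }, error = function(e) cvsim_failure(V[i, ], conditionMessage(e)))
    if (inherits(res, "cvsim_failure")) {
      msgs[i] <- res$message
    } else if (isTRUE(attr(res, "invalid_resistances")) || any(!is.finite(res))) {
      msgs[i] <- "non-finite or invalid clinical outputs"
    } else {
      Y[i, ] <- as.numeric(res)
      ok[i] <- TRUE
    }
    if (progress > 0 && i %% progress == 0)
      message(sprintf("simulated %d/%d (%d failures)", i, n, i - sum(ok[1:i])))
  }
  if (sum(ok) < n / 2)
    stop("more than 50% of simulations failed (", n - sum(ok), "/", n, "); ",
         "first failure: ", msgs[which(!ok)[1]])
  failures <- data.frame(row = which(!ok), message = msgs[!ok])
  structure(list(V = V[ok, , drop = FALSE], Y = Y[ok, , drop = FALSE],
                 failures = failures, config = config, prior = prior,
                 seed = seed),
            class = "cvsim_dataset")
}

#' @export
print.cvsim_dataset <- function(x, ...) {
  cat("CVSim-6 dataset:", nrow(x$V), "input-output pairs,",
      nrow(x$failures), "dropped\n")
  invisible(x)
}

#' Split a dataset into training / online-test / offline-validation
#'
#' Mirrors the study proportions: out of every 54 000 pairs, 4000 are
#' held out for offline validation and the remainder is divided 3-to-1
#' into training and online testing (37 500 / 12 500 at full scale); the
#' same proportions are used at reduced scale. Splits are disjoint,
#' exhaustive and seed-reproducible.
#'
#' @param dataset a `cvsim_dataset`
#' @param scheme `"synthetic"` or `"ehr"` (identical proportions; kept as
#'   a provenance label)
#' @param seed permutation seed
#' @return the dataset with an added `split` factor
#'   (`train`/`test`/`validation`) and `scheme`
#' @export
split_dataset <- function(dataset, scheme = c("synthetic", "ehr"), seed = 1) {
  scheme <- match.arg(scheme)
  n <- nrow(dataset$V)
  n_val <- round(n * 4000 / 54000)
  n_train <- round((n - n_val) * 3 / 4)
  n_test <- n - n_val - n_train
  if (min(n_val, n_train, n_test) < 1)
    stop("dataset too small to split (n = ", n, ")")
  set.seed(seed)
  lab <- factor(rep(c("train", "test", "validation"),
                    c(n_train, n_test, n_val))[sample.int(n)],
                levels = c("train", "test", "validation"))
  dataset$split <- lab
  dataset$scheme <- scheme
  dataset
}

#' Per-feature z-score normalization statistics
#'
#' @param X numeric matrix (observations in rows)
#' @return list with `mean` and `sd` per column (zero-variance columns
#'   get sd 1 so they pass through unchanged)
#' @export
normalize_stats <- function(X) {
  m <- colMeans(X)
  s <- apply(X, 2, sd)
  s[s == 0 | !is.finite(s)] <- 1
  list(mean = m, sd = s)
}

#' Apply / invert z-score normalization
#' @param X matrix or vector
#' @param stats a [normalize_stats] list
#' @return transformed matrix
#' @export
apply_norm <- function(X, stats) {
  if (is.null(dim(X))) X <- matrix(X, 1, dimnames = list(NULL, names(X)))
  sweep(sweep(X, 2, stats$mean, "-"), 2, stats$sd, "/")
}

#' @rdname apply_norm
#' @export
invert_norm <- function(X, stats) {
  if (is.null(dim(X))) X <- matrix(X, 1, dimnames = list(NULL, names(X)))
  sweep(sweep(X, 2, stats$sd, "*"), 2, stats$mean, "+")
}

#' Heteroskedastic Gaussian measurement-noise model
#'
#' Zero-mean, uncorrelated Gaussian noise per clinical attribute, with
#' per-attribute standard deviations `delta * s` where `s` defaults to
#' the literature-derived [OUTPUT_STD] values and `delta` is a global
#' scale factor (0 = no corruption).
#'
#' @param delta noise amplification factor, >= 0
#' @param s named 16-entry standard-deviation vector (Table-2 units)
#' @return list of class `cvsim_noise`
#' @export
noise_model <- function(delta = 1, s = OUTPUT_STD) {
  if (delta < 0) stop("delta must be >= 0")
  stopifnot(length(s) == 16)
  structure(list(delta = delta, s = setNames(as.numeric(s), OUTPUT_NAMES)),
            class = "cvsim_noise")
}

#' Corrupt clinical outputs with measurement noise
#'
#' `Y' = Y + eta`, `eta ~ N(0, diag((delta s)^2))`, independent across
#' entries, applied in physical Table-2 units. A fresh realization is
#' drawn at each call (the per-epoch semantics are owned by the
#' trainer); the neural emulator is always trained without noise.
#'
#' @param Y n x 16 output matrix (Table-2 units)
#' @param noise a [noise_model]
#' @param seed optional seed
#' @return corrupted copy of `Y`
#' @export
inject_noise <- function(Y, noise = noise_model(), seed = NULL) {
  stopifnot(inherits(noise, "cvsim_noise"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dim(Y))) Y <- matrix(Y, 1, dimnames = list(NULL, names(Y)))
  if (noise$delta == 0) return(Y)
  E <- matrix(rnorm(length(Y)), nrow(Y), ncol(Y))
  Y + sweep(E, 2, noise$delta * noise$s, "*")
}

#' Default per-attribute observation probabilities for synthetic EHR tables
#'
#' Emulates the structure of a real anonymized EHR cohort: vital-sign
#' attributes (heart rate, arterial pressures, pulmonary pressures,
#' cardiac output, resistances) are almost always recorded, invasive or
#' imaging-derived attributes (right ventricular diastolic pressure,
#' central venous pressure, ventricular volumes) rarely; the systolic
#' left ventricular volume is never measured. Two patient strata are
#' used: a richly measured stratum whose records pass the
#' more-than-10-measurements filter and a sparse stratum that does not.
#'
#' @return list with `p_rich`, `p_sparse` (16 observation probabilities
#'   each) and `frac_rich` (fraction of patients in the rich stratum)
#' @export
ehr_missingness_preset <- function() {
  p_rich <- setNames(c(1, 1, 1, 44/46, 11/46, 1, 1, 44/46, 1, 3/46,
                       0, 3/46, 45/46, 1, 1, 1), OUTPUT_NAMES)
  p_sparse <- setNames(c(1, 1, 1, rep(0.15, 5), 0.15, 0.05,
                         0, 0.05, 0.5, 0.5, 0.3, 0.3), OUTPUT_NAMES)
  list(p_rich = p_rich, p_sparse = p_sparse, frac_rich = 46 / 84)
}

#' Synthesize an EHR-style table with missing entries
#'
#' Draws patients from a simulated dataset, corrupts the observed
#' clinical attributes with measurement noise and blanks entries
#' according to per-attribute observation probabilities. Ground-truth
#' parameters and noiseless outputs are retained as attributes for
#' recovery tests. Patients are guaranteed at least one observed
#' attribute.
#'
#' @param dataset a `cvsim_dataset` supplying ground-truth rows
#' @param n_patients number of patients (default 84)
#' @param missingness either a probability vector (16 entries), or a
#'   two-stratum list as returned by [ehr_missingness_preset] (default)
#' @param noise a [noise_model] (default delta 0.5)
#' @param seed seed
#' @return data frame (n_patients x 16, `NA` = missing) with attributes
#'   `truth_V`, `truth_Y`
#' @export
synthesize_ehr_table <- function(dataset, n_patients = 84,
                                 missingness = ehr_missingness_preset(),
                                 noise = noise_model(0.5), seed = 1) {
  set.seed(seed)
  idx <- sample.int(nrow(dataset$Y), n_patients, replace = n_patients > nrow(dataset$Y))
  Y <- dataset$Y[idx, , drop = FALSE]
  Yn <- inject_noise(Y, noise)
  if (is.list(missingness)) {
    rich <- runif(n_patients) < missingness$frac_rich
    P <- matrix(NA_real_, n_patients, 16)
    P[rich, ] <- matrix(missingness$p_rich, sum(rich), 16, byrow = TRUE)
    P[!rich, ] <- matrix(missingness$p_sparse, sum(!rich), 16, byrow = TRUE)
  } else {
    stopifnot(length(missingness) == 16)
    if (any(missingness < 0 | missingness > 1))
      stop("observation probabilities must lie in [0, 1]")
    P <- matrix(missingness, n_patients, 16, byrow = TRUE)
  }
  obs <- matrix(runif(n_patients * 16), n_patients, 16) < P
  none <- rowSums(obs) == 0
  obs[none, 1] <- TRUE  # heart rate is always measurable
  Yn[!obs] <- NA_real_
  tab <- as.data.frame(Yn)
  names(tab) <- OUTPUT_NAMES
  attr(tab, "truth_V") <- dataset$V[idx, , drop = FALSE]
  attr(tab, "truth_Y") <- Y
  tab
}

#' Write / read an EHR-style table (CSV, empty cell = missing)
#' @param tab data frame with the 16 clinical attribute columns
#' @param path CSV path
#' @return invisibly `path` / the parsed data frame
#' @export
write_ehr_table <- function(tab, path) {
  write.csv(tab, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_ehr_table
#' @export
read_ehr_table <- function(path) {
  tab <- read.csv(path, na.strings = c("", "NA"), check.names = FALSE)
  missing_cols <- setdiff(OUTPUT_NAMES, names(tab))
  if (length(missing_cols))
    stop("EHR table lacks columns: ", paste(missing_cols, collapse = ", "))
  tab[OUTPUT_NAMES]
}

#' Write / read a dataset as CSV + JSON metadata
#'
#' `V.csv`, `Y.csv`, `split.csv` (if present) and `meta.json` under `dir`.
#' @param dataset a `cvsim_dataset`
#' @param dir destination directory (created if needed)
#' @return invisibly `dir` / the reconstructed dataset
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(as.data.frame(dataset$V), file.path(dir, "V.csv"), row.names = FALSE)
  write.csv(as.data.frame(dataset$Y), file.path(dir, "Y.csv"), row.names = FALSE)
  if (!is.null(dataset$split))
    write.csv(data.frame(split = dataset$split), file.path(dir, "split.csv"),
              row.names = FALSE)
  meta <- list(seed = dataset$seed, scheme = dataset$scheme,
               preset = if (!is.null(dataset$prior)) dataset$prior$preset,
               n = nrow(dataset$V), n_failed = nrow(dataset$failures))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  V <- as.matrix(read.csv(file.path(dir, "V.csv")))
  Y <- as.matrix(read.csv(file.path(dir, "Y.csv")))
  colnames(V) <- PARAM_NAMES; colnames(Y) <- OUTPUT_NAMES
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  ds <- structure(list(V = V, Y = Y,
                       failures = data.frame(row = integer(), message = character()),
                       config = NULL, prior = NULL, seed = meta$seed),
                  class = "cvsim_dataset")
  sp <- file.path(dir, "split.csv")
  if (file.exists(sp))
    ds$split <- factor(read.csv(sp)$split, levels = c("train", "test", "validation"))
  ds$scheme <- meta$scheme
  ds
}
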