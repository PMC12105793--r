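#' Amortized inversion: sample the non-identifiable manifold
#'
#' For a complete observation `y`, draws `Nw` standard-normal latent
#' realizations and decodes each `[y, w]` pair, producing `Nw` candidate
#' parameter vectors from the manifold of inputs mapping to `y`. Masked
#' observations are rejected: complete them first with
#' [impute_and_rank].
#'
#' @param model an `invaert_model`
#' @param y complete 16-entry observation (Table-2 units)
#' @param Nw number of latent draws (>= 1)
#' @param seed seed for the latent draws
#' @return object of class `manifold_samples`: list with `y`, `W`
#'   (Nw x dim_w), `V_hat` (Nw x 23), `Y_hat` (filled by
#'   [verify_solutions]), `evaluator`
#' @export
invert_observation <- function(model, y, Nw = 100, seed = 1) {
  y <- unlist(y)
  if (!is.null(names(y))) y <- y[OUTPUT_NAMES]
  if (any(is.na(y)))
    stop("observation has missing entries; complete it with impute_and_rank() first")
  stopifnot(Nw >= 1)
  set.seed(seed)
  W <- matrix(rnorm(Nw * model$cfg$dim_w), Nw, model$cfg$dim_w)
  V_hat <- decode(model, setNames(as.numeric(y), OUTPUT_NAMES), W)
  structure(list(y = setNames(as.numeric(y), OUTPUT_NAMES), W = W,
                 V_hat = V_hat, Y_hat = NULL, evaluator = NA_character_),
            class = "manifold_samples")
}

# componentwise relative error |delta| / |target|, aggregated
rel_error <- function(y, Y_hat, aggregate = c("max", "median", "l2")) {
  aggregate <- match.arg(aggregate)
  R <- abs(sweep(Y_hat, 2, y, "-")) / matrix(abs(y), nrow(Y_hat), length(y),
                                             byrow = TRUE)
  switch(aggregate,
         max = max(R),
         median = stats::median(R),
         l2 = max(sqrt(rowSums(sweep(Y_hat, 2, y, "-")^2) / sum(y^2))))
}

#' Re-evaluate manifold samples and report reconstruction errors
#'
#' Pushes every decoded parameter vector back through the forward map --
#' either the exact simulator (default for synthetic studies) or the
#' neural emulator (default inside the EHR pipeline) -- and records the
#' componentwise absolute reconstruction differences `|y - y_hat|` with
#' average/max/SD summaries, plus the maximum componentwise relative
#' error. Simulator failures are excluded from the statistics and
#' counted.
#'
#' @param samples a `manifold_samples` object
#' @param evaluator `"exact"`, `"emulator"`, or `"precomputed"` (use the
#'   `Y_hat` already stored in `samples`)
#' @param model the `invaert_model` (required for `"emulator"`)
#' @param config [sim_config] for the exact evaluator
#' @return object of class `error_report`: list with `samples` (with
#'   `Y_hat` filled), `abs_err` (rows x 16), `summary` (average/max/SD
#'   per component), `max_rel_error`, `n_failed`
#' @export
verify_solutions <- function(samples, evaluator = c("exact", "emulator", "precomputed"),
                             model = NULL, config = sim_config()) {
  evaluator <- match.arg(evaluator)
  V <- samples$V_hat
  n <- nrow(V)
  if (evaluator == "precomputed") {
    stopifnot(!is.null(samples$Y_hat))
    Y_hat <- samples$Y_hat
    ok <- rep(TRUE, n)
  } else if (evaluator == "emulator") {
    stopifnot(!is.null(model))
    Y_hat <- suppressWarnings(emulate(model, V))
    ok <- rep(TRUE, n)
  } else {
    Y_hat <- matrix(NA_real_, n, 16, dimnames = list(NULL, OUTPUT_NAMES))
    ok <- logical(n)
    for (i in seq_len(n)) {
      res <- tryCatch({
        traj <- simulate_cvsim(setNames(V[i, ], PARAM_NAMES), config)
        if (inherits(traj, "cvsim_failure")) traj else extract_outputs(traj)
      }, error = function(e) cvsim_failure(V[i, ], conditionMessage(e)))
      if (!inherits(res, "cvsim_failure") && all(is.finite(res))) {
        Y_hat[i, ] <- as.numeric(res)
        ok[i] <- TRUE
      }
    }
  }
  samples$Y_hat <- Y_hat
  samples$evaluator <- evaluator
  E <- abs(sweep(Y_hat[ok, , drop = FALSE], 2, samples$y, "-"))
  summary <- rbind(average = colMeans(E), max = apply(E, 2, max),
                   SD = apply(E, 2, sd))
  colnames(summary) <- OUTPUT_NAMES
  structure(list(samples = samples, abs_err = E, summary = summary,
                 max_rel_error = rel_error(samples$y, Y_hat[ok, , drop = FALSE]),
                 n_failed = n - sum(ok)),
            class = "error_report")
}

#' Singular-value spectrum and cumulative energy of a manifold sample
#'
#' Column-centers the decoded parameter matrix, computes its singular
#' values, and the cumulative energy `CE_n` = fraction of the summed
#' squared singular values captured by the first n modes (non-decreasing
#' to 1). A rank-0 input (all rows identical) is flagged degenerate with
#' `CE_1 = 1`.
#'
#' @param V_hat n x p matrix of manifold samples (n >= 2)
#' @return list with `singular_values`, `cumulative_energy`, `degenerate`
#' @export
manifold_spectrum <- function(V_hat) {
  stopifnot(nrow(V_hat) >= 2)
  Xc <- scale(V_hat, center = TRUE, scale = FALSE)
  s <- svd(Xc, nu = 0, nv = 0)$d
  tot <- sum(s^2)
  if (tot < .Machine$double.eps * nrow(V_hat) * max(abs(V_hat), 1)^2) {
    return(list(singular_values = s,
                cumulative_energy = c(1, rep(1, length(s) - 1)),
                degenerate = TRUE))
  }
  list(singular_values = s, cumulative_energy = cumsum(s^2) / tot,
       degenerate = FALSE)
}

#' Physics-based multiple imputation by density ranking
#'
#' Draws a pool of `M` synthetic outputs from the flow density
#' estimator, keeps the candidates whose observed components match the
#' measurements within `match_tol` measurement standard deviations
#' componentwise, overwrites the observed entries with the measurements,
#' ranks the completed candidates by their flow log-density and returns
#' the top `K`. The ranking promotes completions most frequently
#' observed in the simulated physiology. If no candidate matches, the
#' tolerance is effectively widened by falling back to the `K` nearest
#' candidates in standard-deviation-scaled distance, with a warning.
#'
#' @param model an `invaert_model` (its flow and normalization are used)
#' @param y_partial named 16-entry vector with `NA` for missing entries
#' @param M candidate pool size
#' @param K number of ranked completions to return
#' @param match_tol componentwise tolerance in units of [OUTPUT_STD]
#' @param seed seed for the flow draws
#' @return object of class `imputation_result`: list with `candidates`
#'   (K x 16, observed entries equal the measurements), `log_density`
#'   (non-increasing), `n_retained`, `M`, `observed` (logical mask)
#' @export
impute_and_rank <- function(model, y_partial, M = 5000, K = 4,
                            match_tol = 3, seed = 1) {
  y <- unlist(y_partial)[OUTPUT_NAMES]
  obs <- !is.na(y)
  if (!any(obs)) stop("at least one observed component is required")
  if (all(obs)) {
    out <- matrix(y, 1, dimnames = list(NULL, OUTPUT_NAMES))
    return(structure(list(candidates = out,
                          log_density = flow_log_density(
                            model$flow, apply_norm(out, model$norm_y)),
                          n_retained = 1L, M = 0L, observed = obs),
                     class = "imputation_result"))
  }
  set.seed(seed)
  cand <- invert_norm(flow_sample(model$flow, M), model$norm_y)
  colnames(cand) <- OUTPUT_NAMES
  dev <- abs(sweep(cand[, obs, drop = FALSE], 2, y[obs], "-"))
  dev <- sweep(dev, 2, OUTPUT_STD[obs], "/")
  keep <- which(apply(dev, 1, max) <= match_tol)
  if (length(keep) == 0) {
    warning("no flow sample within match_tol = ", match_tol,
            " stds of the observations; falling back to the ", K,
            " nearest candidates")
    keep <- order(apply(dev, 1, max))[seq_len(min(K, M))]
  }
  completed <- cand[keep, , drop = FALSE]
  completed[, obs] <- matrix(y[obs], length(keep), sum(obs), byrow = TRUE)
  ld <- flow_log_density(model$flow, apply_norm(completed, model$norm_y))
  ord <- order(ld, decreasing = TRUE)[seq_len(min(K, length(keep)))]
  structure(list(candidates = completed[ord, , drop = FALSE],
                 log_density = ld[ord], n_retained = length(keep),
                 M = M, observed = obs),
            class = "imputation_result")
}

#' Amortized inversion of an EHR-style table
#'
#' For every patient with more than `min_observed` recorded attributes:
#' complete the record with the top-ranked candidate from
#' [impute_and_rank], decode `Nw` latent draws against the completed
#' observation, and re-evaluate the decoded parameters through the
#' neural emulator (or the exact simulator). Patients at or below the
#' threshold are skipped and listed; rows with no observed attribute are
#' rejected by the imputation step.
#'
#' @param model an `invaert_model`
#' @param table data frame with the 16 clinical attribute columns
#'   (`NA` = missing), e.g. from [read_ehr_table] or
#'   [synthesize_ehr_table]
#' @param Nw latent draws per patient
#' @param seed master seed (per-patient streams derived from it)
#' @param evaluator `"emulator"` (default) or `"exact"`
#' @param min_observed inversion requires strictly more than this many
#'   observed attributes (default 10)
#' @param M,match_tol imputation pool size and tolerance
#' @return object of class `ehr_inversion`: list with `patients` (per
#'   qualifying patient: `row`, `completed` observation, `samples`
#'   `manifold_samples` with `Y_hat` filled), `skipped` row indices,
#'   `masks` (observed flags per analysed patient)
#' @export
ehr_pipeline <- function(model, table, Nw = 100, seed = 1,
                         evaluator = c("emulator", "exact"),
                         min_observed = 10, M = 5000, match_tol = 3) {
  evaluator <- match.arg(evaluator)
  stopifnot(all(OUTPUT_NAMES %in% names(table)))
  Yobs <- as.matrix(table[OUTPUT_NAMES])
  n_obs <- rowSums(!is.na(Yobs))
  if (any(n_obs == 0)) stop("rows with zero observed attributes: ",
                            paste(which(n_obs == 0), collapse = ", "))
  qualify <- which(n_obs > min_observed)
  skipped <- which(n_obs <= min_observed)
  patients <- vector("list", length(qualify))
  masks <- matrix(FALSE, length(qualify), 16, dimnames = list(NULL, OUTPUT_NAMES))
  for (j in seq_along(qualify)) {
    q <- qualify[j]
    y_q <- setNames(Yobs[q, ], OUTPUT_NAMES)
    imp <- impute_and_rank(model, y_q, M = M, K = 1, match_tol = match_tol,
                           seed = seed + 7 * q)
    samples <- invert_observation(model, imp$candidates[1, ], Nw,
                                  seed = seed + 7 * q + 1)
    rep_q <- verify_solutions(samples, evaluator, model = model)
    patients[[j]] <- list(row = q, completed = imp$candidates[1, ],
                          samples = rep_q$samples)
    masks[j, ] <- !is.na(Yobs[q, ])
  }
  structure(list(patients = patients, skipped = skipped, masks = masks,
                 Nw = Nw, evaluator = evaluator),
            class = "ehr_inversion")
}

#' Per-attribute inversion error across an EHR cohort
#'
#' For attribute k, averages `|y_k - Y_hat_ik|` over the latent draws
#' and over the patients whose attribute k was actually measured;
#' attributes measured in no patient are reported as `NA` (undefined),
#' never zero.
#'
#' @param ehr an `ehr_inversion` object (or a list of Y_hat matrices)
#' @param table the EHR table the inversion was run on
#' @return data frame with `attribute`, `e` (error, attribute units),
#'   `count` (number of patients measuring the attribute)
#' @export
componentwise_error <- function(ehr, table) {
  Yobs <- as.matrix(table[OUTPUT_NAMES])
  if (inherits(ehr, "ehr_inversion")) {
    rows <- vapply(ehr$patients, function(p) p$row, 0L)
    preds <- lapply(ehr$patients, function(p) p$samples$Y_hat)
  } else {
    rows <- seq_along(ehr); preds <- ehr
  }
  e <- counts <- setNames(numeric(16), OUTPUT_NAMES)
  for (k in seq_len(16)) {
    has_k <- which(!is.na(Yobs[rows, k]))
    counts[k] <- length(has_k)
    if (length(has_k) == 0) { e[k] <- NA_real_; next }
    per_patient <- vapply(has_k, function(j)
      mean(abs(Yobs[rows[j], k] - preds[[j]][, k])), 0)
    e[k] <- mean(per_patient)
  }
  data.frame(attribute = OUTPUT_NAMES, e = e, count = counts,
             row.names = NULL)
}

#' Export manifold samples for parallel-coordinate plotting
#'
#' Long-format table with one row per (parameter, sample) pair plus the
#' prior-box bounds widened by a 5% display margin.
#'
#' @param samples a `manifold_samples` object
#' @param prior a [prior_spec]
#' @return data frame with `parameter`, `sample`, `value`, `lower`,
#'   `upper`
#' @export
export_parallel_coordinates <- function(samples, prior) {
  V <- samples$V_hat
  stopifnot(nrow(V) >= 1)
  span <- prior$upper - prior$lower
  data.frame(
    parameter = rep(PARAM_NAMES, each = nrow(V)),
    sample = rep(seq_len(nrow(V)), times = 23),
    value = as.numeric(V),
    lower = rep(prior$lower - 0.05 * span, each = nrow(V)),
    upper = rep(prior$upper + 0.05 * span, each = nrow(V)))
}
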