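# Known run-configuration fields and their defaults. Paths are resolved
# relative to the working directory; `NULL` means "not supplied".
config_defaults <- function() {
  list(profile = "desk",              # desk | synthetic | ehr
       seed = 1L,
       params = NULL,                 # parameter CSV/JSON (default set if NULL)
       data = NULL,                   # dataset directory
       model = NULL,                  # model JSON bundle
       table = NULL,                  # EHR table CSV
       out = "invaert_out",           # output file or directory
       n_samples = 2000L,             # dataset size
       n_cycles = 12L, solver = "radau", rel_tol = 1e-9, abs_tol = 1e-7,
       output_dt = 1e-3, total_blood_volume = 5000,
       delta = 0, Nw = 100L, M = 5000L, K = 4L, match_tol = 3,
       training = list())             # training_config(...) overrides
}

#' Load and validate a YAML run configuration
#'
#' Unknown keys are rejected with field-level messages; defaults are
#' filled for missing keys; an MD5 provenance hash of the file is
#' attached.
#'
#' @param path YAML file path
#' @return list of class `invaert_runconfig`
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  defaults <- config_defaults()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, user)
  if (!cfg$profile %in% c("desk", "synthetic", "ehr"))
    stop("config field 'profile' must be desk, synthetic or ehr")
  if (cfg$delta < 0) stop("config field 'delta' must be >= 0")
  if (cfg$n_samples < 1) stop("config field 'n_samples' must be >= 1")
  if (!cfg$solver %in% c("radau", "rk4"))
    stop("config field 'solver' must be radau or rk4")
  cfg$config_hash <- unname(tools::md5sum(path))
  structure(cfg, class = "invaert_runconfig")
}

#' Write a run configuration to YAML
#' @param config a config list
#' @param path destination
#' @return invisibly `path`
#' @export
write_config <- function(config, path) {
  drop <- intersect(names(config), "config_hash")
  yaml::write_yaml(config[setdiff(names(config), drop)], path)
  invisible(path)
}

runconfig_sim <- function(cfg) {
  sim_config(n_cycles = cfg$n_cycles, solver = cfg$solver,
             rel_tol = cfg$rel_tol, abs_tol = cfg$abs_tol,
             output_dt = cfg$output_dt,
             total_blood_volume = cfg$total_blood_volume)
}

runconfig_params <- function(cfg) {
  if (is.null(cfg$params)) default_parameters() else read_parameters(cfg$params)
}

runconfig_log <- function(cfg, command, artifacts) {
  list(command = command, seed = cfg$seed, profile = cfg$profile,
       config_hash = cfg$config_hash,
       package_version = as.character(utils::packageVersion("invaertcv")),
       artifacts = artifacts)
}

#' Run a pipeline command
#'
#' Dispatches one of the pipeline stages and writes its artifacts:
#' \describe{
#'   \item{simulate}{trajectory CSV + clinical outputs JSON}
#'   \item{stiffness}{eigenvalue/stiffness-ratio profile CSV}
#'   \item{generate-data}{prior samples -> simulated dataset directory}
#'   \item{train}{trained model JSON bundle}
#'   \item{invert}{decoded manifold samples CSV (+ re-evaluation errors)}
#'   \item{impute}{density-ranked completions CSV}
#'   \item{manifold}{manifold samples, SVD spectrum and
#'     parallel-coordinate export}
#'   \item{ehr-run}{per-patient inversion + componentwise error CSV}
#' }
#' A JSON run log with seeds, config hash and artifact paths is written
#' next to the artifacts. Failures raise structured R errors (nonzero
#' exit through the command-line wrapper).
#'
#' @param command one of the commands above
#' @param config an `invaert_runconfig` (or plain list of overrides)
#' @return invisibly a list with `status` (0 on success) and `artifacts`
#' @export
run_command <- function(command, config) {
  commands <- c("simulate", "stiffness", "generate-data", "train",
                "invert", "impute", "manifold", "ehr-run")
  if (!command %in% commands)
    stop("unknown command '", command, "'; expected one of: ",
         paste(commands, collapse = ", "))
  cfg <- utils::modifyList(config_defaults(), unclass(config))
  out <- cfg$out
  artifacts <- character()

  need_model <- function() {
    if (is.null(cfg$model)) stop("command '", command, "' requires 'model'")
    load_model(cfg$model)
  }
  obs_from_table <- function() {
    if (is.null(cfg$table)) stop("command '", command, "' requires 'table'")
    read_ehr_table(cfg$table)
  }

  if (command == "simulate") {
    traj <- simulate_cvsim(runconfig_params(cfg), runconfig_sim(cfg))
    if (inherits(traj, "cvsim_failure")) stop("solver failure: ", traj$message)
    dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
    write_trajectory(traj, paste0(out, "_trajectory.csv"))
    y <- extract_outputs(traj)
    jsonlite::write_json(as.list(unclass(y)), paste0(out, "_outputs.json"),
                         auto_unbox = TRUE, digits = NA)
    artifacts <- paste0(out, c("_trajectory.csv", "_outputs.json"))
  } else if (command == "stiffness") {
    traj <- simulate_cvsim(runconfig_params(cfg), runconfig_sim(cfg))
    if (inherits(traj, "cvsim_failure")) stop("solver failure: ", traj$message)
    prof <- eigen_history(traj)
    dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
    write.csv(as.data.frame(prof), paste0(out, "_stiffness.csv"),
              row.names = FALSE)
    artifacts <- paste0(out, "_stiffness.csv")
  } else if (command == "generate-data") {
    preset <- if (cfg$profile == "ehr") "ehr" else "synthetic"
    prior <- prior_spec(preset)
    V <- sample_prior(prior, cfg$n_samples, seed = cfg$seed)
    ds <- build_dataset(V, runconfig_sim(cfg), prior = prior, seed = cfg$seed)
    ds <- split_dataset(ds, preset, seed = cfg$seed)
    write_dataset(ds, out)
    artifacts <- out
  } else if (command == "train") {
    if (is.null(cfg$data)) stop("command 'train' requires 'data'")
    ds <- read_dataset(cfg$data)
    profile <- if (cfg$profile == "ehr") "ehr"
               else if (cfg$profile == "synthetic") "synthetic" else "desk"
    tc <- do.call(training_config,
                  c(list(profile = profile, seed = cfg$seed), cfg$training))
    model <- train_invaert(ds, tc)
    dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
    save_model(model, paste0(out, "_model.json"))
    artifacts <- paste0(out, "_model.json")
  } else if (command %in% c("invert", "manifold")) {
    model <- need_model()
    tab <- obs_from_table()
    y <- setNames(as.numeric(tab[1, OUTPUT_NAMES]), OUTPUT_NAMES)
    samples <- invert_observation(model, y, Nw = cfg$Nw, seed = cfg$seed)
    dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
    write.csv(as.data.frame(samples$V_hat), paste0(out, "_vhat.csv"),
              row.names = FALSE)
    artifacts <- paste0(out, "_vhat.csv")
    if (command == "manifold") {
      spec <- manifold_spectrum(samples$V_hat)
      write.csv(data.frame(mode = seq_along(spec$singular_values),
                           singular_value = spec$singular_values,
                           cumulative_energy = spec$cumulative_energy),
                paste0(out, "_spectrum.csv"), row.names = FALSE)
      prior <- if (!is.null(model$prior)) model$prior else prior_spec("synthetic")
      write.csv(export_parallel_coordinates(samples, prior),
                paste0(out, "_parallel.csv"), row.names = FALSE)
      artifacts <- c(artifacts, paste0(out, c("_spectrum.csv", "_parallel.csv")))
    }
  } else if (command == "impute") {
    model <- need_model()
    tab <- obs_from_table()
    y <- setNames(as.numeric(tab[1, OUTPUT_NAMES]), OUTPUT_NAMES)
    imp <- impute_and_rank(model, y, M = cfg$M, K = cfg$K,
                           match_tol = cfg$match_tol, seed = cfg$seed)
    dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
    write.csv(cbind(as.data.frame(imp$candidates),
                    log_density = imp$log_density),
              paste0(out, "_completions.csv"), row.names = FALSE)
    artifacts <- paste0(out, "_completions.csv")
  } else if (command == "ehr-run") {
    model <- need_model()
    tab <- obs_from_table()
    ehr <- ehr_pipeline(model, tab, Nw = cfg$Nw, seed = cfg$seed,
                        M = cfg$M, match_tol = cfg$match_tol)
    err <- componentwise_error(ehr, tab)
    dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
    write.csv(err, paste0(out, "_errors.csv"), row.names = FALSE)
    artifacts <- paste0(out, "_errors.csv")
  }

  log <- runconfig_log(cfg, command, artifacts)
  log_path <- paste0(sub("/$", "", out), "_run.json")
  dir.create(dirname(log_path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(log, log_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(list(status = 0L, artifacts = artifacts, log = log_path))
}
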