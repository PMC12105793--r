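#' @useDynLib invaertcv
#' @importFrom stats rnorm runif sd setNames
#' @importFrom utils read.csv write.csv head
"_PACKAGE"

#' Conversion factor between mmHg and Barye (CGS pressure unit)
#'
#' 1 mmHg = 1333.22 Barye, consistent with the reference value of the
#' arterial resistance (1333.22 Barye s/ml = 1 mmHg s/ml).
#' @export
MMHG_TO_BARYE <- 1333.22

#' Names of the 23 CVSim-6 input parameters, in canonical order
#' @export
PARAM_NAMES <- c("Hr", "Pth", "rsys",
                 "Cl_dia", "Cl_sys", "Ca", "Cv", "Cr_dia", "Cr_sys", "Cpa", "Cpv",
                 "Rl_in", "Rl_out", "Ra", "Rr_in", "Rr_out", "Rpv",
                 "Vl0", "Va0", "Vv0", "Vr0", "Vpa0", "Vpv0")

#' Names of the 16 CVSim-6 clinical outputs, in canonical order
#' @export
OUTPUT_NAMES <- c("Hr", "Pa_sys", "Pa_dia", "Pr_sys", "Pr_dia",
                  "Ppa_sys", "Ppa_dia", "Pr_edp", "Pw", "Pcvp",
                  "Vl_sys", "Vl_dia", "LVEF", "CO", "SVR", "PVR")

#' Measurement standard deviations for the 16 clinical outputs
#'
#' Literature-derived per-attribute uncertainty, in each output's units
#' (bpm, mmHg, ml, -, L/min, dyn s/cm^5). Used by the heteroskedastic
#' Gaussian noise model and by the imputation tolerance.
#' @export
OUTPUT_STD <- setNames(
  c(3.0, 1.5, 1.5, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 0.5,
    10.0, 20.0, 0.02, 0.2, 50.0, 5.0),
  OUTPUT_NAMES)

#' Reference (default) CVSim-6 parameter set
#'
#' The 23 baseline physiological inputs: heart rate (bpm), transthoracic
#' pressure (mmHg), systolic fraction of the cycle, six compartment
#' capacitances plus systolic/diastolic ventricular capacitances
#' (ml/Barye), six resistances (Barye s/ml) and six unstressed volumes (ml).
#'
#' @return A named numeric vector of class `cvsim_params`.
#' @examples
#' p <- default_parameters()
#' p[["Hr"]]  # 72 bpm
#' @export
default_parameters <- function() {
  # rsys: systole occupies one third of the cycle (displayed rounded as
  # 0.33 in two-decimal tables, like the repeating-decimal resistances)
  p <- c(Hr = 72.00, Pth = -4.00, rsys = 1 / 3,
         Cl_dia = 7.50e-3, Cl_sys = 3.00e-4, Ca = 1.20e-3, Cv = 7.50e-2,
         Cr_dia = 1.50e-2, Cr_sys = 9.00e-4, Cpa = 3.23e-3, Cpv = 6.30e-3,
         Rl_in = 13.33, Rl_out = 8.00, Ra = 1333.22, Rr_in = 66.66,
         Rr_out = 4.00, Rpv = 106.66,
         Vl0 = 15.00, Va0 = 715.00, Vv0 = 2500.00, Vr0 = 15.00,
         Vpa0 = 90.00, Vpv0 = 490.00)
  as_cvsim_params(p)
}

#' Coerce and validate a CVSim-6 parameter vector
#'
#' @param x named numeric vector or list containing the 23 entries of
#'   [PARAM_NAMES] (any order).
#' @return validated named numeric vector of class `cvsim_params`
#' @export
as_cvsim_params <- function(x) {
  x <- unlist(x)
  if (!all(PARAM_NAMES %in% names(x)))
    stop("missing parameters: ",
         paste(setdiff(PARAM_NAMES, names(x)), collapse = ", "))
  p <- as.numeric(x[PARAM_NAMES])
  names(p) <- PARAM_NAMES
  validate_parameters(p)
  class(p) <- c("cvsim_params", "numeric")
  p
}

#' Validate CVSim-6 parameter invariants
#'
#' Checks positivity of heart rate, capacitances and resistances,
#' non-negativity of unstressed volumes, the systolic fraction lying in
#' (0, 1) and systolic < diastolic ventricular capacitance. The
#' transthoracic pressure may be negative.
#'
#' @param p named numeric vector with the entries of [PARAM_NAMES]
#' @return invisibly `TRUE`; otherwise an error naming the violation
#' @export
validate_parameters <- function(p) {
  bad <- function(msg) stop("invalid parameters: ", msg, call. = FALSE)
  if (!all(is.finite(p[PARAM_NAMES]))) bad("non-finite entry")
  if (p[["Hr"]] <= 0) bad("Hr must be > 0")
  if (p[["rsys"]] <= 0 || p[["rsys"]] >= 1) bad("rsys must lie in (0, 1)")
  caps <- c("Cl_dia", "Cl_sys", "Ca", "Cv", "Cr_dia", "Cr_sys", "Cpa", "Cpv")
  if (any(p[caps] <= 0)) bad("capacitances must be > 0")
  res <- c("Rl_in", "Rl_out", "Ra", "Rr_in", "Rr_out", "Rpv")
  if (any(p[res] <= 0)) bad("resistances must be > 0")
  vols <- c("Vl0", "Va0", "Vv0", "Vr0", "Vpa0", "Vpv0")
  if (any(p[vols] < 0)) bad("unstressed volumes must be >= 0")
  if (p[["Cl_sys"]] >= p[["Cl_dia"]]) bad("Cl_sys must be < Cl_dia")
  if (p[["Cr_sys"]] >= p[["Cr_dia"]]) bad("Cr_sys must be < Cr_dia")
  invisible(TRUE)
}

#' Read a parameter set from CSV or JSON
#'
#' CSV files must have columns `name,value` (one row per parameter) or one
#' column per parameter; JSON files a flat object keyed by parameter name.
#'
#' @param path file path ending in `.csv` or `.json`
#' @return a `cvsim_params` vector
#' @export
read_parameters <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE)
    if (all(c("name", "value") %in% names(df))) {
      x <- setNames(df$value, df$name)
    } else {
      x <- unlist(df[1, , drop = TRUE])
    }
  }
  as_cvsim_params(x)
}

#' Write a parameter set to CSV or JSON
#'
#' @param p a `cvsim_params` vector
#' @param path destination ending in `.csv` (long `name,value` layout) or `.json`
#' @return invisibly `path`
#' @export
write_parameters <- function(p, path) {
  p <- as_cvsim_params(p)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.list(p), path, auto_unbox = TRUE, digits = NA)
  } else {
    write.csv(data.frame(name = names(p), value = as.numeric(p)),
              path, row.names = FALSE)
  }
  invisible(path)
}

#' @export
print.cvsim_params <- function(x, ...) {
  cat("CVSim-6 parameter set (23 entries)\n")
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}
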