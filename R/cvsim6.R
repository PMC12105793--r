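#' State variable names (compartment pressures), in canonical order
#' @export
STATE_NAMES <- c("Pl", "Pa", "Pv", "Pr", "Ppa", "Ppv")

#' Flow variable names, in canonical order
#' @export
FLOW_NAMES <- c("Ql_in", "Ql_out", "Qa", "Qr_in", "Qr_out", "Qpv")

# reference pressure of each compartment: intrathoracic compartments
# (both ventricles, pulmonary arteries and veins) are referenced to the
# transthoracic pressure Pth, systemic arteries and veins to zero.
thoracic_mask <- c(Pl = TRUE, Pa = FALSE, Pv = FALSE,
                   Pr = TRUE, Ppa = TRUE, Ppv = TRUE)

reference_pressures <- function(params) {
  ifelse(thoracic_mask, params[["Pth"]], 0)  # mmHg
}

#' Time-varying ventricular capacitances
#'
#' Ventricular contraction is modelled through a time-varying elastance
#' E(t) = 1/C(t): a half-cosine rise from the diastolic to the systolic
#' elastance over systole `[0, Ts]` (Ts = rsys * 60/Hr), a half-cosine
#' recovery over `[Ts, 1.5 Ts]`, and a constant diastolic elastance for
#' the remainder of the cycle. Left and right waveforms are perfectly
#' synchronized. C(t) is periodic with the cardiac period, starts at the
#' diastolic value and attains its minimum (the systolic capacitance) at
#' end systole; the derivative is returned in closed form.
#'
#' @param t time(s) in seconds (vectorized)
#' @param params a [cvsim_params][as_cvsim_params] vector
#' @return list with elements `Cl`, `dCl`, `Cr`, `dCr` (ml/Barye and
#'   ml/Barye/s), each of length `length(t)`
#' @export
ventricular_capacitances <- function(t, params) {
  params <- as_cvsim_params(params)
  Ttot <- 60 / params[["Hr"]]
  one <- function(Cdia, Csys) {
    Ts <- params[["rsys"]] * Ttot
    u <- t %% Ttot
    Edia <- 1 / Cdia; Esys <- 1 / Csys; dE <- Esys - Edia
    E <- rep(Edia, length(u)); Edot <- numeric(length(u))
    sys <- u <= Ts
    E[sys] <- Edia + 0.5 * dE * (1 - cos(pi * u[sys] / Ts))
    Edot[sys] <- 0.5 * dE * (pi / Ts) * sin(pi * u[sys] / Ts)
    rel <- !sys & u <= 1.5 * Ts
    v <- 2 * pi * (u[rel] - Ts) / Ts
    E[rel] <- Edia + 0.5 * dE * (1 + cos(v))
    Edot[rel] <- -dE * (pi / Ts) * sin(v)
    list(C = 1 / E, dC = -Edot / E^2)
  }
  l <- one(params[["Cl_dia"]], params[["Cl_sys"]])
  r <- one(params[["Cr_dia"]], params[["Cr_sys"]])
  list(Cl = l$C, dCl = l$dC, Cr = r$C, dCr = r$dC)
}

#' Compartment flows from a pressure state
#'
#' Generalized Ohm relations between neighbouring compartments. The four
#' heart-valve flows (ventricular in/outflows) are ideal unidirectional
#' valves: flow equals the pressure drop over the resistance when the
#' upstream pressure exceeds the downstream pressure and is zero
#' otherwise. The arterial and pulmonary venous flows are unvalved and
#' may take either sign.
#'
#' @param P named state vector (mmHg), names as in [STATE_NAMES]
#' @param params a [cvsim_params][as_cvsim_params] vector
#' @return named flow vector (ml/s), names as in [FLOW_NAMES]
#' @export
valve_flows <- function(P, params) {
  params <- as_cvsim_params(params)
  stopifnot(all(is.finite(P)))
  p <- P[STATE_NAMES] * MMHG_TO_BARYE  # Barye
  drop_or_zero <- function(up, dn, R) if (up > dn) (up - dn) / R else 0
  c(Ql_in  = drop_or_zero(p[["Ppv"]], p[["Pl"]], params[["Rl_in"]]),
    Ql_out = drop_or_zero(p[["Pl"]],  p[["Pa"]], params[["Rl_out"]]),
    Qa     = (p[["Pa"]] - p[["Pv"]]) / params[["Ra"]],
    Qr_in  = drop_or_zero(p[["Pv"]],  p[["Pr"]], params[["Rr_in"]]),
    Qr_out = drop_or_zero(p[["Pr"]],  p[["Ppa"]], params[["Rr_out"]]),
    Qpv    = (p[["Ppa"]] - p[["Ppv"]]) / params[["Rpv"]])
}

#' Right-hand side of the CVSim-6 pressure ODEs
#'
#' One balance equation per compartment: the net inflow divided by the
#' compartment capacitance, with the additional `-(P - Pth) * dC/C` terms
#' for the two ventricles arising from the time derivative of the
#' stressed volume `C(t) (P - Pth)`.
#'
#' @param t time (s)
#' @param P named state vector (mmHg)
#' @param params a [cvsim_params][as_cvsim_params] vector
#' @return named derivative vector dP/dt (mmHg/s)
#' @export
cvsim_rhs <- function(t, P, params) {
  params <- as_cvsim_params(params)
  stopifnot(all(is.finite(P)))
  Q <- valve_flows(P, params)
  cap <- ventricular_capacitances(t, params)
  p <- P[STATE_NAMES] * MMHG_TO_BARYE
  Pth <- params[["Pth"]] * MMHG_TO_BARYE
  dp <- c(
    Pl  = (Q[["Ql_in"]] - Q[["Ql_out"]]) / cap$Cl -
      (p[["Pl"]] - Pth) * cap$dCl / cap$Cl,
    Pa  = (Q[["Ql_out"]] - Q[["Qa"]]) / params[["Ca"]],
    Pv  = (Q[["Qa"]] - Q[["Qr_in"]]) / params[["Cv"]],
    Pr  = (Q[["Qr_in"]] - Q[["Qr_out"]]) / cap$Cr -
      (p[["Pr"]] - Pth) * cap$dCr / cap$Cr,
    Ppa = (Q[["Qr_out"]] - Q[["Qpv"]]) / params[["Cpa"]],
    Ppv = (Q[["Qpv"]] - Q[["Ql_in"]]) / params[["Cpv"]])
  dp / MMHG_TO_BARYE  # mmHg/s
}

# transmural-pressure profile (mmHg) along which the excess stressed
# volume is distributed when building mass-conserving initial conditions
init_profile <- c(Pl = 8, Pa = 85, Pv = 7, Pr = 5, Ppa = 16, Ppv = 9)

#' Mass-conserving initial pressures
#'
#' Solves a 6x6 linear system for the initial compartment pressures: the
#' first equation enforces that the stressed volumes (diastolic
#' ventricular capacitances at t = 0) sum to
#' `total_blood_volume - sum(V0)`, and the remaining five constrain the
#' transmural pressures to a fixed physiological profile, so the excess
#' volume is distributed across compartments in physiological
#' proportions. When the total blood volume equals the total unstressed
#' volume, every transmural pressure is zero.
#'
#' @param params a [cvsim_params][as_cvsim_params] vector
#' @param total_blood_volume total volume (ml); must be at least the sum
#'   of the unstressed volumes
#' @return named initial state vector (mmHg)
#' @export
initial_conditions <- function(params, total_blood_volume = 5000) {
  params <- as_cvsim_params(params)
  v0 <- sum(params[c("Vl0", "Va0", "Vv0", "Vr0", "Vpa0", "Vpv0")])
  if (total_blood_volume < v0)
    stop("total_blood_volume (", total_blood_volume,
         " ml) below total unstressed volume (", v0, " ml)")
  C <- params[c("Cl_dia", "Ca", "Cv", "Cr_dia", "Cpa", "Cpv")]  # ml/Barye
  pref <- reference_pressures(params) * MMHG_TO_BARYE           # Barye
  pi_b <- init_profile * MMHG_TO_BARYE                          # Barye

  M <- matrix(0, 6, 6, dimnames = list(NULL, STATE_NAMES))
  r <- numeric(6)
  M[1, ] <- C
  r[1] <- (total_blood_volume - v0) + sum(C * pref)
  for (i in 1:5) {            # pi[i+1]*(P_i - pref_i) = pi[i]*(P_{i+1} - pref_{i+1})
    M[i + 1, i] <- pi_b[i + 1]
    M[i + 1, i + 1] <- -pi_b[i]
    r[i + 1] <- pi_b[i + 1] * pref[i] - pi_b[i] * pref[i + 1]
  }
  P <- tryCatch(solve(M, r), error = function(e)
    stop("singular initial-condition system for parameters: ",
         paste(sprintf("%s=%.4g", PARAM_NAMES, params), collapse = ", "),
         call. = FALSE))
  setNames(P / MMHG_TO_BARYE, STATE_NAMES)
}

#' Simulation configuration
#'
#' @param n_cycles number of cardiac cycles to simulate (default 12)
#' @param solver `"radau"` (adaptive implicit Runge-Kutta of order 5, the
#'   default and reference) or `"rk4"` (explicit fourth-order Runge-Kutta
#'   with fixed step `output_dt`, for time-step instability studies)
#' @param rel_tol,abs_tol solver tolerances (radau only; absolute
#'   tolerance applies to pressures in Barye)
#' @param output_dt uniform dense-output step (s); for `"rk4"` this is
#'   also the integration step
#' @param total_blood_volume total blood volume (ml) used by the
#'   initial-condition solve
#' @return a list of class `cvsim_config`
#' @export
sim_config <- function(n_cycles = 12, solver = c("radau", "rk4"),
                       rel_tol = 1e-9, abs_tol = 1e-7,
                       output_dt = 1e-3, total_blood_volume = 5000) {
  solver <- match.arg(solver)
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  if (output_dt <= 0) stop("output_dt must be > 0")
  if (rel_tol <= 0 || abs_tol <= 0) stop("solver tolerances must be > 0")
  structure(list(n_cycles = as.integer(n_cycles), solver = solver,
                 rel_tol = rel_tol, abs_tol = abs_tol, output_dt = output_dt,
                 total_blood_volume = total_blood_volume),
            class = "cvsim_config")
}

#' Simulate the CVSim-6 system
#'
#' Integrates the six pressure ODEs over `n_cycles` cardiac cycles from
#' mass-conserving initial conditions and post-processes flows,
#' time-varying capacitances, compartment volumes and the total stressed
#' volume on a uniform output grid. Solver failures are returned as a
#' structured `cvsim_failure` record (never an R error), so batch dataset
#' generation can log and skip.
#'
#' @param params a [cvsim_params][as_cvsim_params] vector
#' @param config a [sim_config] list
#' @return an object of class `cvsim_trajectory`: list with `time` (s),
#'   `pressures` (n x 6, mmHg), `flows` (n x 6, ml/s), `Cl`, `dCl`, `Cr`,
#'   `dCr`, `volumes` (n x 6, ml), `total_stressed_volume` (ml),
#'   `params`, `config`; or a `cvsim_failure` record
#' @export
simulate_cvsim <- function(params, config = sim_config()) {
  params <- tryCatch(as_cvsim_params(params), error = function(e)
    stop(conditionMessage(e), call. = FALSE))
  stopifnot(inherits(config, "cvsim_config"))
  Ttot <- 60 / params[["Hr"]]
  times <- seq(0, config$n_cycles * Ttot, by = config$output_dt)
  y0 <- initial_conditions(params, config$total_blood_volume) * MMHG_TO_BARYE
  parms <- as.numeric(params)

  out <- tryCatch({
    if (config$solver == "radau") {
      deSolve::radau(y = y0, times = times, func = "cvsim6_derivs",
                     parms = parms, dllname = "invaertcv",
                     initfunc = "cvsim6_initmod",
                     rtol = config$rel_tol, atol = config$abs_tol)
    } else {
      deSolve::rk4(y = y0, times = times, func = "cvsim6_derivs",
                   parms = parms, dllname = "invaertcv",
                   initfunc = "cvsim6_initmod")
    }
  }, error = function(e) e, warning = function(w) w)

  if (inherits(out, "condition"))
    return(cvsim_failure(params, conditionMessage(out)))
  if (nrow(out) < length(times) || any(!is.finite(out)))
    return(cvsim_failure(params, "non-finite solution or early solver exit"))

  P <- out[, 1 + seq_len(6), drop = FALSE] / MMHG_TO_BARYE
  colnames(P) <- STATE_NAMES
  cap <- ventricular_capacitances(times, params)
  flows <- flows_from_pressures(P, params)
  traj <- structure(list(time = times, pressures = P, flows = flows,
                         Cl = cap$Cl, dCl = cap$dCl, Cr = cap$Cr, dCr = cap$dCr,
                         params = params, config = config),
                    class = "cvsim_trajectory")
  vol <- compartment_volumes(traj, params)
  traj$volumes <- vol$volumes
  traj$total_stressed_volume <- vol$total_stressed_volume
  traj
}

#' @rdname simulate_cvsim
#' @param message failure description
#' @export
cvsim_failure <- function(params, message) {
  structure(list(params = params, message = message), class = "cvsim_failure")
}

#' @export
print.cvsim_failure <- function(x, ...) {
  cat("CVSim-6 solver failure:", x$message, "\n")
  invisible(x)
}

# vectorized flow computation along a trajectory (rows of P in mmHg)
flows_from_pressures <- function(P, params) {
  p <- P * MMHG_TO_BARYE
  valved <- function(up, dn, R) pmax(up - dn, 0) / R
  flows <- cbind(
    Ql_in  = valved(p[, "Ppv"], p[, "Pl"], params[["Rl_in"]]),
    Ql_out = valved(p[, "Pl"], p[, "Pa"], params[["Rl_out"]]),
    Qa     = (p[, "Pa"] - p[, "Pv"]) / params[["Ra"]],
    Qr_in  = valved(p[, "Pv"], p[, "Pr"], params[["Rr_in"]]),
    Qr_out = valved(p[, "Pr"], p[, "Ppa"], params[["Rr_out"]]),
    Qpv    = (p[, "Ppa"] - p[, "Ppv"]) / params[["Rpv"]])
  flows
}

#' Compartment volumes along a trajectory
#'
#' `V_i(t) = C_i(t) (P_i(t) - Pref_i) + V0_i`, where the reference
#' pressure is the transthoracic pressure for intrathoracic compartments
#' (ventricles, pulmonary arteries/veins) and zero for the systemic
#' arteries and veins. The total stressed volume `sum(C (P - Pref))` is a
#' conserved quantity of the closed loop.
#'
#' @param traj a `cvsim_trajectory`
#' @param params a [cvsim_params][as_cvsim_params] vector
#' @return list with `volumes` (n x 6 matrix, ml) and
#'   `total_stressed_volume` (length-n vector, ml)
#' @export
compartment_volumes <- function(traj, params = traj$params) {
  params <- as_cvsim_params(params)
  P <- traj$pressures
  pref <- reference_pressures(params)
  Cmat <- cbind(Pl = traj$Cl, Pa = params[["Ca"]], Pv = params[["Cv"]],
                Pr = traj$Cr, Ppa = params[["Cpa"]], Ppv = params[["Cpv"]])
  stressed <- Cmat * sweep(P, 2, pref, "-") * MMHG_TO_BARYE
  v0 <- params[c("Vl0", "Va0", "Vv0", "Vr0", "Vpa0", "Vpv0")]
  volumes <- sweep(stressed, 2, v0, "+")
  colnames(volumes) <- c("Vl", "Va", "Vv", "Vr", "Vpa", "Vpv")
  list(volumes = volumes, total_stressed_volume = rowSums(stressed))
}

# composite trapezoid integral on a uniform grid
trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Extract the 16 clinical outputs from a trajectory
#'
#' Computes the clinical attribute vector over the final three cardiac
#' cycles (`Tp`): systolic/diastolic pressures and ventricular volumes as
#' extrema over `Tp`; pulmonary wedge pressure, central venous pressure
#' and cardiac output as trapezoidal time averages; the right ventricular
#' end-diastolic pressure as the final sample of `Tp`; ejection fraction,
#' systemic and pulmonary vascular resistances from their defining
#' ratios. Units: bpm, mmHg, ml, L/min and dyn s/cm^5.
#'
#' @param traj a `cvsim_trajectory` covering at least three full cycles
#' @param params a [cvsim_params][as_cvsim_params] vector
#' @return named numeric vector of class `cvsim_outputs` with entries
#'   [OUTPUT_NAMES] and attribute `mask` (logical, observed flags). If
#'   the cardiac output is non-positive, `SVR` and `PVR` are `NA` and the
#'   attribute `invalid_resistances` is set.
#' @export
extract_outputs <- function(traj, params = traj$params) {
  params <- as_cvsim_params(params)
  if (inherits(traj, "cvsim_failure")) stop("cannot extract outputs from a solver failure")
  Ttot <- 60 / params[["Hr"]]
  n_cyc <- traj$config$n_cycles
  if (n_cyc < 3) stop("trajectory must cover at least 3 full cycles")
  sel <- traj$time >= (n_cyc - 3) * Ttot - 1e-12
  t <- traj$time[sel]
  P <- traj$pressures[sel, , drop = FALSE]
  V <- traj$volumes[sel, , drop = FALSE]
  Qa <- traj$flows[sel, "Qa"]
  span <- t[length(t)] - t[1]
  tavg <- function(y) trapz(t, y) / span

  Pw <- tavg(P[, "Ppv"]); Pcvp <- tavg(P[, "Pv"])
  Pa_mean <- tavg(P[, "Pa"]); Ppa_mean <- tavg(P[, "Ppa"])
  co_mls <- tavg(Qa)                      # ml/s
  Vl_sys <- min(V[, "Vl"]); Vl_dia <- max(V[, "Vl"])
  y <- c(Hr = params[["Hr"]],
         Pa_sys = max(P[, "Pa"]), Pa_dia = min(P[, "Pa"]),
         Pr_sys = max(P[, "Pr"]), Pr_dia = min(P[, "Pr"]),
         Ppa_sys = max(P[, "Ppa"]), Ppa_dia = min(P[, "Ppa"]),
         Pr_edp = unname(P[nrow(P), "Pr"]),
         Pw = Pw, Pcvp = Pcvp,
         Vl_sys = Vl_sys, Vl_dia = Vl_dia,
         LVEF = (Vl_dia - Vl_sys) / Vl_dia,
         CO = co_mls * 60 / 1000,         # L/min
         SVR = NA_real_, PVR = NA_real_)
  invalid <- co_mls <= 0
  if (!invalid) {
    y[["SVR"]] <- (Pa_mean - Pcvp) * MMHG_TO_BARYE / co_mls  # Barye s/ml = dyn s/cm^5
    y[["PVR"]] <- (Ppa_mean - Pw) * MMHG_TO_BARYE / co_mls
  }
  structure(y, mask = setNames(rep(TRUE, 16), OUTPUT_NAMES),
            invalid_resistances = invalid, class = "cvsim_outputs")
}

#' Trajectory as a tidy data frame
#'
#' @param x a `cvsim_trajectory`
#' @param ... unused
#' @return data frame with time plus all named series
#' @export
as.data.frame.cvsim_trajectory <- function(x, ...) {
  data.frame(time = x$time, x$pressures, x$flows,
             Cl = x$Cl, dCl = x$dCl, Cr = x$Cr, dCr = x$dCr,
             x$volumes, total_stressed_volume = x$total_stressed_volume,
             check.names = FALSE)
}

#' Write a trajectory to tidy CSV
#' @param traj a `cvsim_trajectory`
#' @param path destination path
#' @return invisibly `path`
#' @export
write_trajectory <- function(traj, path) {
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
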