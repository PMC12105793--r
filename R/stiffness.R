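#' Linearize the CVSim-6 system at a state
#'
#' Writes the pressure ODEs as `dP/dt = A(t) P + b(t)` with the valve
#' indicator functions frozen at the linearization state. `A` collects
#' every pressure-linear term, including the `-dC/C` diagonal
#' contributions of the two ventricles; `b` collects the transthoracic
#' pressure forcing `Pth * dC/C`. The identity `A P + b = rhs(t, P)`
#' holds exactly at the linearization state.
#'
#' @param t time (s)
#' @param P named state vector (mmHg)
#' @param params a [cvsim_params][as_cvsim_params] vector
#' @return list of class `cvsim_linearization` with `A` (6 x 6, 1/s),
#'   `b` (length 6, mmHg/s), `t`
#' @export
linearize <- function(t, P, params) {
  params <- as_cvsim_params(params)
  p <- P[STATE_NAMES] * MMHG_TO_BARYE
  cap <- ventricular_capacitances(t, params)
  Pth <- params[["Pth"]] * MMHG_TO_BARYE

  # valve indicators frozen at the linearization state
  i_mi <- as.numeric(p[["Ppv"]] > p[["Pl"]])   # mitral
  i_ao <- as.numeric(p[["Pl"]] > p[["Pa"]])    # aortic
  i_tr <- as.numeric(p[["Pv"]] > p[["Pr"]])    # tricuspid
  i_pu <- as.numeric(p[["Pr"]] > p[["Ppa"]])   # pulmonary

  A <- matrix(0, 6, 6, dimnames = list(STATE_NAMES, STATE_NAMES))
  b <- setNames(numeric(6), STATE_NAMES)

  Cl <- cap$Cl; Cr <- cap$Cr
  # Pl row
  A["Pl", "Ppv"] <- i_mi / (params[["Rl_in"]] * Cl)
  A["Pl", "Pl"]  <- -i_mi / (params[["Rl_in"]] * Cl) -
    i_ao / (params[["Rl_out"]] * Cl) - cap$dCl / Cl
  A["Pl", "Pa"]  <- i_ao / (params[["Rl_out"]] * Cl)
  b["Pl"] <- Pth * cap$dCl / Cl
  # Pa row
  A["Pa", "Pl"] <- i_ao / (params[["Rl_out"]] * params[["Ca"]])
  A["Pa", "Pa"] <- -i_ao / (params[["Rl_out"]] * params[["Ca"]]) -
    1 / (params[["Ra"]] * params[["Ca"]])
  A["Pa", "Pv"] <- 1 / (params[["Ra"]] * params[["Ca"]])
  # Pv row
  A["Pv", "Pa"] <- 1 / (params[["Ra"]] * params[["Cv"]])
  A["Pv", "Pv"] <- -1 / (params[["Ra"]] * params[["Cv"]]) -
    i_tr / (params[["Rr_in"]] * params[["Cv"]])
  A["Pv", "Pr"] <- i_tr / (params[["Rr_in"]] * params[["Cv"]])
  # Pr row
  A["Pr", "Pv"]  <- i_tr / (params[["Rr_in"]] * Cr)
  A["Pr", "Pr"]  <- -i_tr / (params[["Rr_in"]] * Cr) -
    i_pu / (params[["Rr_out"]] * Cr) - cap$dCr / Cr
  A["Pr", "Ppa"] <- i_pu / (params[["Rr_out"]] * Cr)
  b["Pr"] <- Pth * cap$dCr / Cr
  # Ppa row
  A["Ppa", "Pr"]  <- i_pu / (params[["Rr_out"]] * params[["Cpa"]])
  A["Ppa", "Ppa"] <- -i_pu / (params[["Rr_out"]] * params[["Cpa"]]) -
    1 / (params[["Rpv"]] * params[["Cpa"]])
  A["Ppa", "Ppv"] <- 1 / (params[["Rpv"]] * params[["Cpa"]])
  # Ppv row
  A["Ppv", "Ppa"] <- 1 / (params[["Rpv"]] * params[["Cpv"]])
  A["Ppv", "Ppv"] <- -1 / (params[["Rpv"]] * params[["Cpv"]]) -
    i_mi / (params[["Rl_in"]] * params[["Cpv"]])
  A["Ppv", "Pl"]  <- i_mi / (params[["Rl_in"]] * params[["Cpv"]])

  structure(list(A = A, b = b / MMHG_TO_BARYE, t = t),
            class = "cvsim_linearization")
}

# order eigenvalues by |Re| descending, ties broken by signed value descending
order_eigen <- function(lambda) {
  order(-abs(Re(lambda)), -Re(lambda))
}

#' Stiffness ratio of an eigenvalue set
#'
#' `SR = max|Re(lambda)| / min|Re(lambda)|`, where the denominator uses
#' the eigenvalue of smallest magnitude whose magnitude exceeds `tol`
#' (numerically zero eigenvalues, which occur when a solution component
#' is momentarily conserved, are excluded).
#'
#' @param eigenvalues numeric/complex vector of eigenvalues
#' @param tol zero-eigenvalue tolerance (default 1e-14)
#' @return the stiffness ratio (>= 1), or `NA` with a warning if every
#'   eigenvalue magnitude falls below `tol`
#' @export
stiffness_ratio <- function(eigenvalues, tol = 1e-14) {
  mags <- abs(Re(eigenvalues))
  nz <- mags[mags > tol]
  if (length(nz) == 0) {
    warning("all eigenvalue magnitudes below tol; stiffness ratio undefined")
    return(NA_real_)
  }
  max(mags) / min(nz)
}

#' Intrinsic timescales of a set of eigenvalues
#'
#' `tau_i = 1 / |Re(lambda_i)|` in seconds; zero eigenvalues are excluded.
#'
#' @param eigenvalues numeric/complex eigenvalues
#' @param tol magnitudes below this are treated as zero (default 1e-14)
#' @return numeric vector of timescales (s), one per nonzero eigenvalue
#' @export
characteristic_timescales <- function(eigenvalues, tol = 1e-14) {
  mags <- abs(Re(eigenvalues))
  1 / mags[mags > tol]
}

#' RC constants for neighbouring compartment pairs
#'
#' For a resistance R between compartments with capacitances Cj and Ck,
#' the characteristic response time is `R Cj Ck / (Cj + Ck)` (the series
#' capacitance seen by the resistor). Ventricular capacitances enter at
#' their systolic values for the outflow pairs (the configuration in
#' which these timescales govern the fast dynamics) and diastolic values
#' for the inflow pairs.
#'
#' @param params a [cvsim_params][as_cvsim_params] vector
#' @return named numeric vector of RC constants (s)
#' @export
rc_constants <- function(params) {
  params <- as_cvsim_params(params)
  rc <- function(R, Cj, Ck) R * Cj * Ck / (Cj + Ck)
  c(lv_inflow  = rc(params[["Rl_in"]],  params[["Cpv"]],   params[["Cl_dia"]]),
    lv_outflow = rc(params[["Rl_out"]], params[["Cl_sys"]], params[["Ca"]]),
    systemic   = rc(params[["Ra"]],     params[["Ca"]],    params[["Cv"]]),
    rv_inflow  = rc(params[["Rr_in"]],  params[["Cv"]],    params[["Cr_dia"]]),
    rv_outflow = rc(params[["Rr_out"]], params[["Cr_sys"]], params[["Cpa"]]),
    pulmonary  = rc(params[["Rpv"]],    params[["Cpa"]],   params[["Cpv"]]))
}

#' Eigenvalue time history and stiffness profile along a trajectory
#'
#' Assembles the linearized coefficient matrix `A(t)` at every output
#' sample in the requested window (by default the last two cardiac
#' cycles), eigendecomposes it, sorts eigenvalues by magnitude of the
#' real part (descending), and computes the stiffness-ratio series. All
#' eigenvalues of the CVSim-6 `A(t)` are real; an imaginary part larger
#' than `imag_tol` relative to the spectral radius is reported as an
#' error rather than silently truncated.
#'
#' The analysis grid is laid out uniformly from the start of the window
#' with step `dt`; compartment pressures are interpolated from the dense
#' trajectory to decide the valve states (the entries of `A(t)` are
#' otherwise closed-form in `t`). The closed loop conserves volume per
#' connected compartment group, so `A(t)` carries structural zero
#' eigenvalues whose numerical images are of order machine precision
#' times the spectral radius; these are deflated to exact zeros below
#' `zero_floor` (relative to the spectral radius) before the
#' stiffness-ratio tolerance rule is applied.
#'
#' @param traj a `cvsim_trajectory`
#' @param params a [cvsim_params][as_cvsim_params] vector
#' @param window numeric length-2 time interval (s); default the last two
#'   cycles of the trajectory
#' @param dt sampling step of the analysis grid (s); defaults to the
#'   trajectory output step
#' @param tol zero-eigenvalue tolerance for the stiffness ratio
#' @param imag_tol relative tolerance on imaginary parts (default 1e-8)
#' @param zero_floor structural-zero deflation threshold, relative to the
#'   spectral radius (default 1e-12)
#' @return object of class `cvsim_stiffness`: list with `time`,
#'   `eigenvalues` (n x 6, sorted), `eigenvectors` (6 x 6 x n), `SR`,
#'   `tol`
#' @export
eigen_history <- function(traj, params = traj$params, window = NULL,
                          dt = traj$config$output_dt, tol = 1e-14,
                          imag_tol = 1e-8, zero_floor = 1e-12) {
  params <- as_cvsim_params(params)
  Ttot <- 60 / params[["Hr"]]
  tend <- traj$time[length(traj$time)]
  if (is.null(window)) window <- c(tend - 2 * Ttot, tend)
  if (window[1] < traj$time[1] - 1e-9 || window[2] > tend + 1e-9)
    stop("trajectory does not cover the requested window")
  tg <- seq(window[1], window[2], by = dt)
  Pg <- vapply(STATE_NAMES, function(nm)
    stats::approx(traj$time, traj$pressures[, nm], xout = tg)$y,
    numeric(length(tg)))
  n <- length(tg)
  lam <- matrix(NA_real_, n, 6)
  vec <- array(NA_real_, c(6, 6, n))
  SR <- numeric(n)
  for (i in seq_len(n)) {
    lin <- linearize(tg[i], setNames(Pg[i, ], STATE_NAMES), params)
    e <- eigen(lin$A)
    rho <- max(abs(e$values), 1e-300)
    if (max(abs(Im(e$values))) > imag_tol * rho)
      stop(sprintf("non-real eigenvalue beyond tolerance at t = %.4f", tg[i]))
    ord <- order_eigen(e$values)
    ev <- Re(e$values)[ord]
    ev[abs(ev) < zero_floor * rho] <- 0
    lam[i, ] <- ev
    vec[, , i] <- Re(e$vectors)[, ord]
    SR[i] <- stiffness_ratio(lam[i, ], tol)
  }
  structure(list(time = tg, eigenvalues = lam,
                 eigenvectors = vec, SR = SR, tol = tol),
            class = "cvsim_stiffness")
}

#' Stiffness profile as a tidy data frame
#' @param x a `cvsim_stiffness` object
#' @param ... unused
#' @return data frame with time, lambda1..lambda6 and SR
#' @export
as.data.frame.cvsim_stiffness <- function(x, ...) {
  lam <- as.data.frame(x$eigenvalues)
  names(lam) <- paste0("lambda", 1:6)
  cbind(data.frame(time = x$time), lam, SR = x$SR)
}

#' Locate the stiffness-ratio extrema of a profile
#'
#' @param profile a `cvsim_stiffness` object
#' @return list with `t_max`, `t_min` (s), `SR_max`, `SR_min` and
#'   `eig_max`, `eig_min` (the sorted eigenvalues at each instant)
#' @export
sr_extrema <- function(profile) {
  i_max <- which.max(profile$SR)
  i_min <- which.min(profile$SR)
  list(t_max = profile$time[i_max], t_min = profile$time[i_min],
       SR_max = profile$SR[i_max], SR_min = profile$SR[i_min],
       eig_max = profile$eigenvalues[i_max, ],
       eig_min = profile$eigenvalues[i_min, ])
}
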