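test_that("parameter validation enforces physiological invariants", {
  p <- default_parameters()
  expect_s3_class(p, "cvsim_params")
  expect_equal(unname(p[["Hr"]]), 72)
  expect_equal(unname(p[["Ra"]]), 1333.22)

  bad <- function(name, value) {
    q <- unclass(p); q[name] <- value
    expect_error(as_cvsim_params(q), "invalid parameters")
  }
  bad("rsys", 1.5)
  bad("Hr", -10)
  bad("Ca", 0)
  bad("Cl_sys", 8e-3)   # must stay below Cl_dia
  bad("Vv0", -1)
  expect_error(as_cvsim_params(c(Hr = 72)), "missing parameters")
})

test_that("parameter CSV and JSON round trips are exact", {
  p <- default_parameters()
  for (ext in c("csv", "json")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_parameters(p, f)
    expect_equal(as.numeric(read_parameters(f)), as.numeric(p), tolerance = 1e-12)
  }
})

test_that("ventricular capacitance waveform has the required shape", {
  p <- default_parameters()
  Ttot <- 60 / p[["Hr"]]
  Ts <- p[["rsys"]] * Ttot
  cap0 <- ventricular_capacitances(0, p)
  expect_equal(cap0$Cl, unname(p[["Cl_dia"]]))   # diastolic value at cycle start
  expect_equal(cap0$Cr, unname(p[["Cr_dia"]]))
  capTs <- ventricular_capacitances(Ts, p)
  expect_equal(capTs$Cl, unname(p[["Cl_sys"]]))  # systolic minimum at end systole
  expect_equal(capTs$Cr, unname(p[["Cr_sys"]]))
  tseq <- seq(0, Ttot, length.out = 97)
  cmin <- min(ventricular_capacitances(tseq, p)$Cl)
  expect_gte(cmin, p[["Cl_sys"]] - 1e-15)

  # periodicity over several cycles
  ts <- seq(0, Ttot, length.out = 37)
  c1 <- ventricular_capacitances(ts, p)
  c2 <- ventricular_capacitances(ts + 3 * Ttot, p)
  expect_equal(c1$Cl, c2$Cl, tolerance = 1e-12)
  expect_equal(c1$dCr, c2$dCr, tolerance = 1e-9)

  # analytic derivative matches centred finite differences to O(h^2)
  h <- 1e-6
  tt <- c(0.1, 0.5 * Ts, Ts + 0.01, 0.6 * Ttot)
  fd <- (ventricular_capacitances(tt + h, p)$Cl -
           ventricular_capacitances(tt - h, p)$Cl) / (2 * h)
  expect_equal(ventricular_capacitances(tt, p)$dCl, fd, tolerance = 1e-6)
})

test_that("valve flows follow the generalized Ohm relations with indicators", {
  p <- default_parameters()
  P <- c(Pl = 5, Pa = 100, Pv = 5, Pr = 2, Ppa = 15, Ppv = 10)
  Q <- valve_flows(P, p)
  expect_equal(unname(Q[["Ql_in"]]), (10 - 5) * 1333.22 / 13.33, tolerance = 1e-10)
  expect_equal(unname(Q[["Qa"]]), 95 * 1333.22 / 1333.22, tolerance = 1e-10)
  # closed mitral valve: no backflow
  P2 <- P; P2["Pl"] <- 12
  expect_identical(unname(valve_flows(P2, p)[["Ql_in"]]), 0)
  # unvalved flows may be negative
  P3 <- P; P3["Pv"] <- 120
  expect_lt(valve_flows(P3, p)[["Qa"]], 0)
})

test_that("rhs matches the compartment balance equations", {
  p <- default_parameters()
  # all flows zero and dC = 0 at end-diastole -> all derivatives zero
  Peq <- c(Pl = 5, Pa = 5, Pv = 5, Pr = 5, Ppa = 5, Ppv = 5)
  d <- cvsim_rhs(0.8, Peq, p)   # late diastole: capacitances constant
  expect_equal(unname(d), rep(0, 6), tolerance = 1e-12)
  # arterial line: dPa = (Ql_out - Qa)/Ca; aortic closed, Qa = 95 ml/s
  P <- c(Pl = 5, Pa = 100, Pv = 5, Pr = 2, Ppa = 15, Ppv = 10)
  d2 <- cvsim_rhs(0.8, P, p)
  expect_equal(unname(d2[["Pa"]]), -95 / 1.2e-3 / 1333.22, tolerance = 1e-6)
})

test_that("R rhs is consistent with the compiled trajectory", {
  traj <- shared_default_trajectory()
  dt <- traj$config$output_dt
  idx <- seq(3000, 9000, by = 500)
  for (k in idx) {
    fd <- (traj$pressures[k + 1, ] - traj$pressures[k - 1, ]) / (2 * dt)
    an <- cvsim_rhs(traj$time[k], traj$pressures[k, ], traj$params)
    # centred differences across valve switchings are only O(dt); compare
    # where the local rhs is smooth
    if (max(abs(fd - an)) < 50)
      expect_equal(unname(an), unname(fd), tolerance = 2e-2)
  }
})

test_that("initial conditions conserve mass and handle the degenerate volume", {
  p <- default_parameters()
  v0 <- sum(p[c("Vl0", "Va0", "Vv0", "Vr0", "Vpa0", "Vpv0")])
  # zero stressed volume: every pressure equals its reference pressure
  P0 <- initial_conditions(p, v0)
  expect_equal(unname(P0), c(p[["Pth"]], 0, 0, p[["Pth"]], p[["Pth"]], p[["Pth"]]),
               tolerance = 1e-10)
  # conservation by construction for arbitrary valid volumes
  for (tbv in c(4000, 5000, 6000)) {
    P <- initial_conditions(p, tbv)
    C <- p[c("Cl_dia", "Ca", "Cv", "Cr_dia", "Cpa", "Cpv")]
    pref <- c(p[["Pth"]], 0, 0, p[["Pth"]], p[["Pth"]], p[["Pth"]])
    expect_equal(sum(C * (P - pref) * MMHG_TO_BARYE), tbv - v0, tolerance = 1e-8)
  }
  expect_error(initial_conditions(p, 1000), "below total unstressed volume")
})

test_that("initial-condition solve agrees with a dense least-squares oracle", {
  p <- default_parameters()
  # rebuild the same 6x6 system independently and solve by QR least squares
  C <- p[c("Cl_dia", "Ca", "Cv", "Cr_dia", "Cpa", "Cpv")]
  pref <- c(p[["Pth"]], 0, 0, p[["Pth"]], p[["Pth"]], p[["Pth"]]) * MMHG_TO_BARYE
  prof <- c(8, 85, 7, 5, 16, 9) * MMHG_TO_BARYE
  tbv <- 5000
  v0 <- sum(p[c("Vl0", "Va0", "Vv0", "Vr0", "Vpa0", "Vpv0")])
  M <- rbind(C, matrix(0, 5, 6))
  r <- c(tbv - v0 + sum(C * pref), numeric(5))
  for (i in 1:5) {
    M[i + 1, i] <- prof[i + 1]; M[i + 1, i + 1] <- -prof[i]
    r[i + 1] <- prof[i + 1] * pref[i] - prof[i] * pref[i + 1]
  }
  ls <- qr.coef(qr(M), r) / MMHG_TO_BARYE
  expect_equal(unname(initial_conditions(p, tbv)), unname(ls), tolerance = 1e-10)
})

test_that("default simulation conserves total stressed volume to 1e-6", {
  traj <- shared_default_trajectory()
  sv <- traj$total_stressed_volume
  expect_lt(max(abs(sv - sv[1])) / sv[1], 1e-6)
})

test_that("conservation holds across random prior draws", {
  V <- sample_prior(prior_spec("synthetic"), 20, seed = 99)
  for (i in seq_len(20)) {
    traj <- simulate_cvsim(setNames(V[i, ], PARAM_NAMES),
                           sim_config(n_cycles = 6))
    expect_s3_class(traj, "cvsim_trajectory")
    sv <- traj$total_stressed_volume
    expect_lt(max(abs(sv - sv[1])) / sv[1], 1e-6)
  }
})

test_that("valved flows are non-negative along the trajectory", {
  traj <- shared_default_trajectory()
  expect_gte(min(traj$flows[, c("Ql_in", "Ql_out", "Qr_in", "Qr_out")]), 0)
})

test_that("simulation config rejects invalid settings", {
  expect_error(sim_config(n_cycles = 0), "n_cycles")
  expect_error(sim_config(output_dt = 0), "output_dt")
  expect_error(sim_config(rel_tol = -1), "tolerances")
})

test_that("compartment volumes follow the pressure-volume relations", {
  traj <- shared_default_trajectory()
  p <- traj$params
  vol <- compartment_volumes(traj, p)
  # Vl at t = 0 from the diastolic capacitance
  expect_equal(vol$volumes[1, "Vl"],
               unname(p[["Cl_dia"]] * (traj$pressures[1, "Pl"] - p[["Pth"]]) *
                        MMHG_TO_BARYE + p[["Vl0"]]),
               tolerance = 1e-10, ignore_attr = TRUE)
  # total equals the stressed sum plus unstressed volumes
  expect_equal(rowSums(vol$volumes) -
                 sum(p[c("Vl0", "Va0", "Vv0", "Vr0", "Vpa0", "Vpv0")]),
               vol$total_stressed_volume, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("clinical outputs have Table-2 structure and internal consistency", {
  traj <- shared_default_trajectory()
  y <- extract_outputs(traj)
  expect_named(unclass(y), OUTPUT_NAMES)
  expect_equal(unname(y[["Hr"]]), unname(traj$params[["Hr"]]))  # copied from input
  expect_gte(y[["Pa_sys"]], y[["Pa_dia"]])
  expect_gte(y[["Ppa_sys"]], y[["Ppa_dia"]])
  expect_gte(y[["Vl_dia"]], y[["Vl_sys"]])
  expect_true(y[["LVEF"]] >= 0 && y[["LVEF"]] <= 1)
  expect_equal(unname(y[["LVEF"]]),
               unname((y[["Vl_dia"]] - y[["Vl_sys"]]) / y[["Vl_dia"]]))
  # cardiac output from the mean arterial flow agrees with SV x Hr within 2%
  sv_ml <- y[["Vl_dia"]] - y[["Vl_sys"]]
  co_sv <- sv_ml * y[["Hr"]] / 1000            # L/min
  expect_lt(abs(co_sv - y[["CO"]]) / y[["CO"]], 0.02)
  expect_error(extract_outputs(simulate_cvsim(default_parameters(),
                                              sim_config(n_cycles = 2))),
               "at least 3 full cycles")
})

test_that("the final cycles are periodic: cycles 10-12 match 9-11 within 0.5%", {
  traj <- shared_default_trajectory()
  p <- traj$params
  Ttot <- 60 / p[["Hr"]]
  win <- function(a, b) {
    sel <- traj$time >= a * Ttot - 1e-12 & traj$time <= b * Ttot + 1e-12
    t <- traj$time[sel]; P <- traj$pressures[sel, ]; V <- traj$volumes[sel, ]
    c(Pa_sys = max(P[, "Pa"]), Pa_dia = min(P[, "Pa"]),
      Ppa_sys = max(P[, "Ppa"]), Vl_dia = max(V[, "Vl"]),
      Vl_sys = min(V[, "Vl"]))
  }
  a <- win(9, 12); b <- win(8, 11)
  expect_lt(max(abs(a - b) / abs(b)), 0.005)
})

test_that("solver failures are structured records, not crashes", {
  p <- default_parameters()
  f <- cvsim_failure(p, "test failure")
  expect_s3_class(f, "cvsim_failure")
  expect_output(print(f), "solver failure")
  expect_error(extract_outputs(f), "solver failure")
})

test_that("trajectory exports a tidy data frame and CSV", {
  traj <- simulate_cvsim(default_parameters(), sim_config(n_cycles = 3))
  df <- as.data.frame(traj)
  expect_true(all(c("time", "Pl", "Qa", "Cl", "Vl", "total_stressed_volume")
                  %in% names(df)))
  f <- tempfile(fileext = ".csv")
  write_trajectory(traj, f)
  back <- read.csv(f)
  expect_equal(nrow(back), nrow(df))
  expect_equal(back$Pl, df$Pl, tolerance = 1e-6)
})
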