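# invaertcv

Stiff-ODE simulation, stiffness analysis and amortized inversion for the
CVSim-6 six-compartment cardiovascular model.

Lumped-parameter (0D) haemodynamic models map a vector of 23
physiological parameters **v** (heart rate, transthoracic pressure,
systolic fraction, compartment capacitances, resistances and unstressed
volumes) to 16 clinical attributes **y** (systolic/diastolic pressures,
ventricular volumes, ejection fraction, cardiac output, vascular
resistances). The map is many-to-one: a whole *non-identifiable
manifold* M<sub>y</sub> = {v : f(v) = y} produces the same clinical
picture, which defeats classical regularized inversion. This package is
for researchers in computational physiology and uncertainty
quantification who need

1. a tested CVSim-6 forward solver — six pressure ODEs with
   time-varying ventricular elastance and ideal valves, integrated with
   adaptive implicit Radau (`simulate_cvsim`, `extract_outputs`);
2. a quantitative stiffness analysis — the linearization
   dP/dt = A(t) P + b(t), eigenvalue time histories, the stiffness
   ratio SR(t) = max|Re λ|/min|Re λ| and compartment RC timescales
   (`linearize`, `eigen_history`, `stiffness_ratio`, `rc_constants`);
3. an inVAErt network — a neural emulator of f, a Real-NVP
   normalizing-flow density estimator of p(y), a variational encoder
   providing the latent coordinates w that restore bijectivity, and a
   decoder (y, w) ↦ v̂, trained jointly with an
   MSE + KL + re-evaluation objective (`train_invaert`) — enabling
   amortized inversion (`invert_observation`), manifold
   characterization (`manifold_spectrum`,
   `export_parallel_coordinates`) and density-ranked multiple
   imputation of missing clinical measurements (`impute_and_rank`,
   `ehr_pipeline`).

All networks are implemented in base R with analytic backpropagation
(verified against finite differences in the tests); the ODE right-hand
side is compiled C shared with `deSolve`.

## Worked example

```r
library(invaertcv)

p <- default_parameters()          # reference 23-parameter set
traj <- simulate_cvsim(p)          # 12 cardiac cycles, Radau, dt = 1 ms
round(unclass(extract_outputs(traj)), 2)
#>     Hr  Pa_sys  Pa_dia  Pr_sys  Pr_dia Ppa_sys Ppa_dia  Pr_edp
#>  72.00  109.30   74.44   22.20   -2.15   21.72   10.33    0.91
#>     Pw    Pcvp  Vl_sys  Vl_dia    LVEF      CO     SVR     PVR
#>   8.91    6.84   59.89  131.74    0.55    5.15 1333.22  107.09
```

A resting adult at 72 bpm: arterial pressure 109/74 mmHg, ejection
fraction 0.55, cardiac output 5.1 L/min, systemic vascular resistance
1333 dyn·s·cm⁻⁵ — the model's reference operating point. The total
stressed volume is conserved to < 1e−6 (relative) across the run.

Stiffness analysis over the last two cycles:

```r
prof <- eigen_history(traj)
ex <- sr_extrema(prof)
ex$t_max; round(ex$eig_max, 2)
#> [1] 9.444333
#> [1] -520.95 -355.81   -3.75   -0.51    0.00    0.00
ex$t_min; round(ex$eig_min, 2)
#> [1] 8.619333
#> [1] -4.39 -2.02 -1.98 -0.64  0.00  0.00
```

The stiffness ratio peaks at end systole, just before the outflow
valves close: the two fastest modes (|λ| ≈ 521 and 356 s⁻¹, timescales
1.9 and 2.8 ms) match the RC constants of the ventricular outflows
(`rc_constants(p)`), which is why an explicit solver needs
millisecond steps while the dynamics of interest unfold over seconds.

Inversion at the reduced (desk) scale:

```r
prior <- prior_spec("synthetic")
V <- sample_prior(prior, 2000, seed = 11)
ds <- split_dataset(build_dataset(V, prior = prior, seed = 11), "synthetic")
model <- train_invaert(ds, training_config("desk"))   # ~5 min, one CPU

y <- ds$Y[ds$split == "validation", ][1, ]            # a held-out observation
ms <- invert_observation(model, y, Nw = 100, seed = 4)
rep <- verify_solutions(ms, "exact")                  # re-simulate all 100
rep$summary[, c("Hr", "Pa_sys", "CO")]
```

The 100 decoded parameter vectors all reproduce the observation when
pushed back through the exact simulator (vector-relative error ~1%),
yet span most of the prior range in the unidentifiable directions
(venous and pulmonary venous capacitances, unstressed volumes) while
pinning the identifiable ones (arterial and pulmonary venous
resistances) — the non-identifiability structure of the model, read off
in one decoder pass per sample.

A thin command-line wrapper is included:

```sh
inst/cli/invaert-cvsim simulate --out run
inst/cli/invaert-cvsim stiffness --out run
```

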