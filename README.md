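# glycosim

Closed-loop simulation toolkit for glycemic control in type-1 diabetes
(T1DM). An artificial pancreas closes the loop between a continuous glucose
monitor and an insulin pump; the control law in the middle must drive a
hyperglycemic patient (here 200 mg/dL) to a basal reference (70 mg/dL)
quickly, without hypoglycemic undershoot, and despite disturbances.
glycosim implements and compares the three classical candidates on an
identified patient model:

* **PID** — `u = kp·e + ki∫e dt + kd·de/dt` on the glucose error, as a
  sampled discrete law (trapezoidal integral, backward-difference
  derivative);
* **LQR** — state feedback `u = -Kx` minimizing `∫(xᵀQx + uᵀRu)dt`, with
  `K = R⁻¹BᵀP` from the continuous algebraic Riccati equation (or its
  discrete counterpart, by domain dispatch);
* **SMC** — first-order sliding-mode control `u = u_eq + u_disc` on the
  surface `s = c₁x₁ + c₂x₂ + c₃x₃`, with equivalent control
  `u_eq = -(a·x)/b` and switching term `u_disc = -k₁s - k₂·sign(s)`
  satisfying the Lyapunov reaching condition `V̇ = -k₁s² - k₂|s| ≤ 0`.

The plant is the identified third-order glucose-insulin deviation model

    G(z) = -C0 / ((z - p1)(z - p2)(z - p3)),   C0 = 0.132,
    (p1, p2, p3) = (0.965, 0.95, 0.93)

with its exact zero-order-hold continuous equivalent (poles `log(p)/Ts`,
`Ts = 600 s`), state-space realizations, controllability/observability
analysis, a virtual-patient cohort generator, a fixed-step RK4/Euler
closed-loop engine (C++ core) with matched sinusoidal disturbances, and
time-response metrics (settling time, rise time, overshoot, steady-state
error, chattering index with first-order low-pass mitigation).

## Worked example

```r
library(glycosim)

plant <- tf_to_state_space(printed_continuous_tf())   # simulation realization
cmd_analyze("printed_tf")
#> plant source: printed_tf (continuous)
#> poles: -1.20732e-04, -8.57836e-05, -5.92847e-05
#> zeros: 0.00243374+0.00144098i, 0.00243374-0.00144098i
#> DC gain: -1076.55
#> open loop: stable
#> rank(controllability) = 3 (controllable)
#> rank(observability) = 3 (observable)
#> unity feedback: UNSTABLE (pole with Re>0)
```

The open-loop plant is stable but glacial (hours-scale modes) and unity
feedback destabilizes it — hence the controllers. Compare them on the
200 → 70 mg/dL task:

```r
ctrls <- list(pid = reference_pid_gains(),
              lqr = lqr_design(plant, reference_lqr_weights()$Q, 1),
              smc = reference_smc_params(plant = plant))
compare_controllers(plant, ctrls,
    list(pid = simulation_config(dt = 0.1,  horizon = 400000),
         lqr = simulation_config(dt = 0.1,  horizon = 600),
         smc = simulation_config(dt = 0.01, horizon = 100)))
#> Controller comparison (config fingerprint 3afd1203+9dab75bd+0a5ec4bf)
#>  controller settling_time_s settled rise_time_s overshoot_pct ...
#>         pid        306071.4    TRUE     25503.5    5.3982e+01
#>         lqr            30.6    TRUE         4.6    2.2656e+06
#>         smc            29.3    TRUE         4.4    6.5866e+06
```

Reading the numbers: the sliding-mode loop settles into the 2% band around
70 mg/dL fastest (29.3 s), LQR close behind (30.6 s), and the PID loop —
whose small gains fight the plant's -1077 mg/dL-per-unit DC gain through
an output-only error signal — needs ~3.1 days. The strict ordering
SMC < LQR < PID is the robust qualitative result; the giant transient
overshoot percentages of the state-feedback laws are an artifact of the
canonical realization's state scaling (see the methods vignette). The SMC
run holds the reference exactly:

```r
tr <- simulate_closed_loop(plant, ctrls$smc,
                           simulation_config(dt = 0.01, horizon = 200))
mean(tr$glucose_mg_dl[tr$time_s >= 180])
#> [1] 70.00000
```

Experiments are reproducible from flat TOML-style config files via the
command-line layer (`cmd_simulate()`, `cmd_compare()`, `cmd_analyze()`, or
the `inst/cli/glycosim` launcher); trajectories and comparison reports are
written as CSV with a config fingerprint.

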