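---
title: "Closed-loop glycemic control on an identified glucose-insulin model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop glycemic control: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycosim)
```

## The model

glycosim is built around a third-order linear deviation model of the
glucose-insulin system of a type-1 diabetic patient, identified from
simulator data around a basal operating point. The discrete transfer
function from the insulin input `u` (abstract insulin input units; the
identification literature does not fix pmol/min vs U/h) to the glucose
deviation `y = G - G_ref` (mg/dL) is

$$G(z) = \frac{-C_0}{(z-p_1)(z-p_2)(z-p_3)},$$

with nominal parameters `C0 = 0.132` and poles `(0.965, 0.95, 0.93)`; the
negative sign encodes that insulin lowers glucose, and the poles vary from
patient to patient. `sample_patient_cohort()` emulates that variability by
multiplicative uniform perturbation of the nominal `(C0, p1, p2, p3)`
(element 1 is always the nominal patient, poles are clipped into (0, 1)).
What the generator does **not** emulate: meal and exercise disturbances,
CGM sensor noise, insulin pump quantization, or any nonlinearity of the
real physiology. Passing tests therefore certify the control mathematics on
the identified linear model, not clinical performance.

### Sampling period

The identification narrative never states the sampling period. We ship
`Ts = 600` s (10 min, a typical CGM-era identification interval) because
the elementary symmetric functions of `log(p_i)/600` reproduce the
reference continuous denominator `(2.658e-4, 2.26e-8, 6.14e-13)` to three
significant figures — strong evidence this was the original value. `Ts` is
an ordinary parameter of `patient_params()`.

### Discrete-to-continuous conversion

`discrete_to_continuous()` implements the exact zero-order-hold inverse
through the companion realization (`Ac = log(Ad)/Ts`,
`Bc = Ac (Ad - I)^{-1} Bd`). We chose this over a matched-pole +
least-squares numerator fit after observing that the ZOH inverse reproduces
*all six* reference continuous coefficients to at least three significant
figures (the least-squares route recovers the denominator and DC constant
but misplaces the `s^2` numerator coefficient by a factor ~3, because the
fit absorbs hold distortion). Poles map to `log(p_i)/Ts` and the DC gain
(about -1077 mg/dL per input unit) is preserved exactly in either case.
The implementation requires distinct real positive discrete poles, which
all valid patient models have almost surely.

### The two state-space realizations, and why they disagree

The toolkit ships two realizations and is explicit about their conflict:

* `tf_to_state_space(printed_continuous_tf())` — the controllable-canonical
  realization of the reference continuous transfer function. This is the
  **simulation plant** for every reproduction run.
* `printed_state_space()` — the verbatim reference `(A, B, C, D)` fixture.
  Its numbers are *not* a realization of the continuous model: the trace of
  `A` (2.805) does not match the sum of the discrete poles (2.845), and its
  characteristic polynomial has one real eigenvalue at 1.0135 — just
  outside the unit circle and in the right half plane, so the fixture is
  marginally unstable under **either** domain reading. We keep the
  `"discrete"` tag (its remaining pair is discrete-stable and its entries
  look like a balanced/scaled discrete companion form), use it for the
  structural analysis it was printed for, and never integrate it as the
  default plant. `resolve_plant()` exposes both plus the `Ts`-parametric
  derived conversion as a config switch.

Initial conditions place the whole deviation on the output-coupled third
state, `x0 = (0, 0, (G0 - G_ref)/C_3)`, the minimal assumption giving
`y(0) = G0 - G_ref`. On the canonical realization `C_3` is the numerator
constant (~ -6.6e-10), so the internal states are numerically huge
(~2e11); this is a property of that realization, not a bug, and it is why
the state-weighted controllers act far more aggressively there than their
small printed weights might suggest.

## The three control laws

**PID** (`pid_gains()`, `pid_step()`): `u = kp e + ki ∫e + kd de/dt` on the
error `e = G_ref - G`, realized discretely with a trapezoidal integral and
a backward-difference derivative on the error; the first sample uses a zero
derivative. No anti-windup and no derivative filter — the reference design
specifies none — and both are natural extension points. The reference gains
are `(-1.51e-4, -2.75e-8, -0.207)`.

**LQR** (`lqr_design()`): minimizes `∫ x'Qx + u'Ru dt` and dispatches on
the plant's domain tag — continuous algebraic Riccati equation solved by
the stable invariant subspace of the Hamiltonian matrix with
`K = R^{-1}B'P`, or the discrete equation by fixed-point iteration of the
Riccati recursion with `K = (R + B'PB)^{-1}B'PA`. Both validate the weight
signs, report the algebraic residual, and refuse to return a
non-stabilizing solution. Whether the original design was continuous or
discrete is unstated, so both solvers are first-class. The reference
weights are `Q = diag(0.001, 0.2341, 0.22)`, `R = 1`. The reference *gain*
`K = (0.231, 0.4947, 0.4687)` is shipped only as
`reference_lqr_gain_fixture()`: it stabilizes the fixture `A` under
neither reading (eigenvalues of `A - BK` are `1.23 ± 1.02i, 0.228`), a
negative result the test suite pins so it cannot be silently "fixed".

**SMC** (`smc_params()`, `smc_control()`): sliding surface
`s = c1 x1 + c2 x2 + c3 x3` with `c = (1, 2.5, 1)`; control
`u = u_eq + u_disc` where `u_eq = -(a·x)/b` annihilates the drift of the
surface dynamics `ṡ = a·x + b u`, and `u_disc = -k1 s - k2 sign(s)`
(`k1 = 6`, `k2 = 9`) enforces the Lyapunov reaching condition
`V̇ = -k1 s² - k2|s| ≤ 0` for `V = s²/2`. The reaching time from `s0` is
bounded by `(1/k1) log(1 + k1|s0|/k2)` (`reaching_time_bound()`).
Numerical conventions: `sign(0) = 0` by default so the control is bounded
on the surface (configurable to ±1); the surface dynamics default to the
symbolic `(c'A, c'B)` of the configured plant, with a `"reference"` preset
that injects the literally reported coefficients
`(2.416e-4, 5.7105e-4, -9.105e-5, 0.25)`. Those reported coefficients
equal `(c'A, c'B)` for *neither* shipped realization (for the fixture
`c'B = 0.5`, not 0.25); both presets are kept so either reading can be
reproduced. On the canonical plant the two presets give nearly identical
closed-loop behavior because the reaching term dominates the (tiny)
equivalent control.

## Simulation engine

`simulate_closed_loop()` integrates `ẋ = Ax + B(u + d(t))` with a
fixed-step integrator written in C++: classical RK4 by default, explicit
Euler as an option, and exact stepping at `Ts` for discrete plants. The
state-feedback laws (LQR, SMC) are re-evaluated at every RK4 substage — in
particular `sign(s)` — with no event detection; the PID is a sampled
(zero-order-held) law updated once per step, which is how a digital
controller runs. Default steps: `dt = 0.1` s for PID/LQR, `0.01` s for SMC
(to resolve the switching). A non-finite state aborts with the blow-up
time. Matched disturbances enter additively on the input as a sinusoid
(default preset: amplitude 1 input unit, period 300 s, configurable).

Two numerical observations worth knowing:

* Fourth-order convergence holds for the smooth runs (verified by
  Richardson extrapolation on the LQR loop; the sampled PID loop is
  formally limited by its own zero-order hold, so the integrator-order
  check uses the fully continuous feedback law).
* With per-substage sign evaluation, RK4 averages the switching almost
  perfectly and realizes near-ideal sliding: the control ripple is ~1e-9.
  The finite-switching-frequency chattering one expects of first-order SMC
  appears in the Euler run (peak-to-peak ~19 input units at `dt = 0.01`),
  so chattering metrics and the low-pass mitigation
  (`low_pass_filter()`, exact first-order discretization, unit DC gain)
  are demonstrated on Euler-stepped runs.

`chattering_index()` detrends the control with a centered 100-sample moving
average (wide enough to pass a ripple of tens of samples per cycle through
to the residual essentially unattenuated), discards the half-window at each
end where the average is clamped, and reports sign changes per second and
the peak-to-peak residual over the final 20% of the horizon.

`settling_time()` is the earliest time after which the glucose stays within
a band (default 2%, 5% preset) of the initial deviation around the
reference; `overshoot()` measures the excursion past the reference in the
direction opposite the start — for a hyperglycemic start, the clinically
dangerous hypoglycemic undershoot.

## Reproduction fidelity and known limitations

The canonical comparison (200 mg/dL bolus start, 70 mg/dL reference, 2%
band) yields, under the documented defaults:

```{r compare, eval = FALSE}
plant <- tf_to_state_space(printed_continuous_tf())
ctrls <- list(pid = reference_pid_gains(),
              lqr = lqr_design(plant, reference_lqr_weights()$Q, 1),
              smc = reference_smc_params(plant = plant))
compare_controllers(plant, ctrls,
                    list(pid = simulation_config(dt = 0.1, horizon = 400000),
                         lqr = simulation_config(dt = 0.1, horizon = 600),
                         smc = simulation_config(dt = 0.01, horizon = 100)))
```

One honest caveat about the transients: because the canonical realization
carries the initial deviation on a state of magnitude ~2e11, the
state-feedback laws slam the output through physically meaningless values
(overshoot percentages in the millions) during the first seconds before
settling crisply on 70 mg/dL. This is the documented deviation-coordinate
convention at work, not a solver artifact; a clinical-scale realization
would need the identification's original state coordinates, which are not
available.

SMC settles fastest, then LQR, then PID — the qualitative ordering reported
for this comparison study — and the SMC loop holds the 70 mg/dL target to
within numerical precision. The *absolute* settling times of the original
study (430 s PID, 113 s LQR, 15 s SMC) are **not** reproduced: the printed
continuous plant has hours-scale open-loop modes, against which the printed
PID gains yield a ~3.1e5 s settling time, while the state-feedback laws on
the canonical realization settle in ~30 s. We verified that no combination
of the printed artifacts (continuous transfer function, state-space
fixture, discrete model at unit sampling) reproduces the reported trio;
the original figures evidently came from a simulation configuration that
the printed model does not determine. The suite pins the measured values
instead of tuning toward the reported ones.

Other limitations, by design: no meal/exercise physiology, no sensor or
actuator model, no observer (the state-feedback laws assume state access),
no gain scheduling or higher-order SMC; subspace identification from raw
simulator sweeps is documented but not implemented (no data). Problem
sizes used by the test suite and the reproduction script — up to ~5e6 RK4
steps for the PID settling measurement, 1e4-state property sweeps, 50
random Riccati cross-checks — were chosen to exercise the numerics at
full fidelity while staying lightweight.
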