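# Reference controller tunings for the glycemic-control comparison study.

#' Reference PID tuning
#'
#' The PID gains tuned for the identified glucose-insulin plant:
#' `kp = -0.000151`, `ki = -2.75e-8`, `kd = -0.207`. All negative because
#' the plant gain is negative.
#'
#' @return A [pid_gains()] object.
#' @export
reference_pid_gains <- function() {
  pid_gains(kp = -0.000151, ki = -0.0000000275, kd = -0.207)
}

#' Reference LQR weights
#'
#' The quadratic-cost weights of the reference design:
#' `Q = diag(0.001, 0.2341, 0.22)`, `R = 1` (identity).
#'
#' @return A list with elements `Q` (3 x 3) and `R` (scalar 1).
#' @export
reference_lqr_weights <- function() {
  list(Q = diag(c(0.001, 0.2341, 0.22)), R = 1)
}

#' Reference LQR gain (comparison fixture only)
#'
#' The state-feedback gain `K = (0.231, 0.4947, 0.4687)` reported alongside
#' the reference weights. It is shipped as a documented fixture, not used
#' for simulation: it does not stabilize the reference state-space fixture
#' under either the continuous or the discrete reading (a pinned negative
#' result in the test suite), so the toolkit always recomputes `K` from
#' `(Q, R)` via [lqr_design()].
#'
#' @return A numeric length-3 gain vector.
#' @export
reference_lqr_gain_fixture <- function() {
  c(0.231, 0.4947, 0.4687)
}

#' Reference sliding-mode tuning
#'
#' Surface coefficients `c = (1, 2.5, 1)` and reaching gains `k1 = 6`,
#' `k2 = 9`. Two surface-dynamics presets are available:
#' \describe{
#'   \item{`"derived"`}{`(c'A, c'B)` computed symbolically from the supplied
#'     plant realization (the default, self-consistent choice);}
#'   \item{`"reference"`}{the literal reported coefficients
#'     `(2.416e-4, 5.7105e-4, -9.105e-5, 0.25)`, kept for reproduction runs.
#'     They do not equal `(c'A, c'B)` for either shipped realization; see
#'     the methods vignette.}
#' }
#'
#' @param preset `"derived"` or `"reference"`.
#' @param plant plant realization (`ss_model`) used when
#'   `preset = "derived"`; defaults to the canonical continuous plant.
#' @return An [smc_params()] object.
#' @export
reference_smc_params <- function(preset = c("derived", "reference"),
                                 plant = tf_to_state_space(printed_continuous_tf())) {
  preset <- match.arg(preset)
  if (preset == "derived") {
    smc_params(c1 = 1, c2 = 2.5, c3 = 1, k1 = 6, k2 = 9, plant = plant)
  } else {
    smc_params(c1 = 1, c2 = 2.5, c3 = 1, k1 = 6, k2 = 9,
               surface_dynamics = c(2.416e-4, 5.7105e-4, -9.105e-5, 0.25))
  }
}
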