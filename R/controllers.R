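# Controller specifications and stepwise control laws: discrete PID and
# first-order sliding-mode control.

#' PID gains
#'
#' Gains of the control law `u = kp e + ki int(e dt) + kd de/dt`. Signs are
#' unconstrained: the reference glycemic gains are all negative because the
#' plant gain is negative (insulin lowers glucose).
#'
#' @param kp proportional gain.
#' @param ki integral gain (1/s).
#' @param kd derivative gain (s).
#' @return A `pid_gains` object.
#' @export
pid_gains <- function(kp, ki, kd) {
  for (nm in c("kp", "ki", "kd")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("`", nm, "` must be a single finite number", call. = FALSE)
  }
  structure(list(kp = kp, ki = ki, kd = kd), class = "pid_gains")
}

#' Fresh PID internal state
#'
#' Accumulator, previous error and initialization flag of the discrete PID
#' realization. The accumulator starts at zero; the first step uses a zero
#' derivative (there is no previous error to difference against).
#'
#' @return A `pid_state` object.
#' @export
pid_state <- function() {
  structure(list(integral = 0, prev_error = 0, initialized = FALSE),
            class = "pid_state")
}

#' One discrete PID step
#'
#' Advances the discrete PID realization by one sample: trapezoidal
#' integral, backward-difference derivative on the error, no anti-windup or
#' derivative filtering. On the first call the derivative term is zero and
#' the trapezoid is taken against an implicit prior error of zero.
#'
#' @param gains a [pid_gains()] object.
#' @param state a [pid_state()] object.
#' @param error tracking error (mg/dL), `reference - measured`.
#' @param dt sample interval in seconds (> 0).
#' @return A list `(u, state)`: the control value and the advanced state.
#' @examples
#' st <- pid_state()
#' pid_step(pid_gains(2, 0, 0), st, error = 1, dt = 1)$u  # 2
#' @export
pid_step <- function(gains, state, error, dt) {
  stopifnot(inherits(gains, "pid_gains"), inherits(state, "pid_state"))
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("`dt` must be > 0", call. = FALSE)
  if (!is.numeric(error) || length(error) != 1L || !is.finite(error))
    stop("`error` must be a single finite number", call. = FALSE)
  integral <- state$integral + dt * (state$prev_error + error) / 2
  deriv <- if (state$initialized) (error - state$prev_error) / dt else 0
  u <- gains$kp * error + gains$ki * integral + gains$kd * deriv
  list(u = u,
       state = structure(list(integral = integral, prev_error = error,
                              initialized = TRUE),
                         class = "pid_state"))
}

#' PID transfer function
#'
#' The s-domain form `H(s) = kp + ki/s + kd s = (kd s^2 + kp s + ki) / s`.
#'
#' @param gains a [pid_gains()] object.
#' @return A `continuous_tf` with numerator `(kd, kp, ki)` and denominator
#'   `(1, 0)`.
#' @export
pid_transfer_function <- function(gains) {
  stopifnot(inherits(gains, "pid_gains"))
  new_ctf(num = c(gains$kd, gains$kp, gains$ki), den = c(1, 0))
}

#' Sliding-mode controller parameters
#'
#' The sliding surface is `s = c1 x1 + c2 x2 + c3 x3`; surface dynamics are
#' `sdot = a . x + b u`, obtained symbolically as `(c'A, c'B)` from a plant
#' realization or supplied literally. The control is
#' `u = ueq + udisc` with `ueq = -(a . x)/b` (annihilates the drift on the
#' surface) and `udisc = -k1 s - k2 sign(s)` (drives the reaching phase and
#' rejects matched disturbances).
#'
#' @param c1,c2,c3 sliding-surface coefficients. The reference tuning keeps
#'   `c1 = c3 = 1` and chooses `c2` so the reduced-order sliding dynamics
#'   are Hurwitz.
#' @param k1 proportional reaching gain (>= 0).
#' @param k2 switching gain (> 0).
#' @param surface_dynamics numeric length-4 vector `(a1, a2, a3, b)`, or
#'   `NULL` to derive `(c'A, c'B)` from `plant`.
#' @param plant optional `ss_model` used to derive the surface dynamics.
#' @param sign_zero value of `sign(0)` used by the switching term: `0`
#'   (default; control bounded on the surface) or `+1`/`-1`.
#' @return An `smc_params` object.
#' @examples
#' smc_params(plant = tf_to_state_space(printed_continuous_tf()))
#' @export
smc_params <- function(c1 = 1, c2 = 2.5, c3 = 1, k1 = 6, k2 = 9,
                       surface_dynamics = NULL, plant = NULL,
                       sign_zero = 0) {
  if (k1 < 0) stop("`k1` must be >= 0", call. = FALSE)
  if (k2 <= 0) stop("`k2` must be > 0", call. = FALSE)
  if (!sign_zero %in% c(-1, 0, 1))
    stop("`sign_zero` must be one of -1, 0, 1", call. = FALSE)
  cvec <- c(c1, c2, c3)
  if (is.null(surface_dynamics)) {
    if (is.null(plant))
      stop("supply either `surface_dynamics` or a `plant` to derive them",
           call. = FALSE)
    stopifnot(inherits(plant, "ss_model"))
    a <- as.numeric(cvec %*% plant$A)
    b <- as.numeric(cvec %*% plant$B)
  } else {
    if (length(surface_dynamics) != 4L)
      stop("`surface_dynamics` must be (a1, a2, a3, b)", call. = FALSE)
    a <- as.numeric(surface_dynamics[1:3])
    b <- as.numeric(surface_dynamics[4])
  }
  if (b == 0) stop("surface input coefficient `b` must be nonzero",
                   call. = FALSE)
  structure(list(c = cvec, k1 = k1, k2 = k2, a = a, b = b,
                 sign_zero = sign_zero),
            class = "smc_params")
}

#' @export
print.smc_params <- function(x, ...) {
  cat("Sliding-mode controller\n")
  cat("  surface c =", x$c, "  gains k1 =", x$k1, ", k2 =", x$k2, "\n")
  cat("  sdot = a.x + b u with a =", signif(x$a, 6), ", b =", signif(x$b, 6), "\n")
  invisible(x)
}

sgn <- function(s, zero = 0) if (s > 0) 1 else if (s < 0) -1 else zero

#' Sliding variable
#'
#' `s = c1 x1 + c2 x2 + c3 x3`. The controller forces trajectories onto and
#' along `s = 0`, where the reduced-order dynamics are Hurwitz by design.
#'
#' @param params an [smc_params()] object.
#' @param x state vector of length 3.
#' @return The scalar sliding value.
#' @export
smc_surface <- function(params, x) {
  stopifnot(inherits(params, "smc_params"), length(x) == 3L)
  sum(params$c * x)
}

#' Equivalent control
#'
#' The continuous control that makes `sdot = 0` exactly under the surface
#' dynamics `sdot = a . x + b u`: `ueq = -(a . x)/b`.
#'
#' @inheritParams smc_surface
#' @return The scalar equivalent control.
#' @export
smc_equivalent_control <- function(params, x) {
  stopifnot(inherits(params, "smc_params"), length(x) == 3L)
  -sum(params$a * x) / params$b
}

#' Discontinuous (switching) control
#'
#' `udisc = -k1 s - k2 sign(s)`, with `sign(0)` given by the controller's
#' `sign_zero` convention (default 0, so the control is bounded on the
#' surface).
#'
#' @param params an [smc_params()] object.
#' @param s sliding value.
#' @return The scalar switching control.
#' @export
smc_discontinuous_control <- function(params, s) {
  stopifnot(inherits(params, "smc_params"))
  -params$k1 * s - params$k2 * sgn(s, params$sign_zero)
}

#' Full sliding-mode control with Lyapunov diagnostics
#'
#' `u = ueq + udisc`, together with the sliding variable, the Lyapunov value
#' `V = s^2/2` and its decrement along the ideal dynamics
#' `Vdot = -k1 s^2 - k2 |s|` (non-positive for admissible gains, zero only
#' on the surface: the reaching condition).
#'
#' @inheritParams smc_surface
#' @return A list `(u, diagnostics)` where `diagnostics` holds `s`, `V`,
#'   `Vdot`, `ueq`, `udisc`.
#' @examples
#' p <- smc_params(surface_dynamics = c(2.416e-4, 5.7105e-4, -9.105e-5, 0.25))
#' smc_control(p, c(1, 1, 1))$u
#' @export
smc_control <- function(params, x) {
  s <- smc_surface(params, x)
  ueq <- smc_equivalent_control(params, x)
  udisc <- smc_discontinuous_control(params, s)
  list(u = ueq + udisc,
       diagnostics = list(s = s, V = s^2 / 2,
                          Vdot = -params$k1 * s^2 - params$k2 * abs(s),
                          ueq = ueq, udisc = udisc))
}

#' Reaching-time bound
#'
#' Upper bound on the time the ideal sliding dynamics
#' `sdot = -k1 s - k2 sign(s)` take to reach the surface from `s0`:
#' `(1/k1) log(1 + k1 |s0| / k2)` for `k1 > 0`, and `|s0| / k2` in the
#' constant-rate limit `k1 = 0`.
#'
#' @param params an [smc_params()] object (requires `k2 > 0`).
#' @param s0 initial sliding value.
#' @return The bound in seconds.
#' @export
reaching_time_bound <- function(params, s0) {
  stopifnot(inherits(params, "smc_params"))
  if (params$k2 <= 0) stop("`k2` must be > 0", call. = FALSE)
  if (s0 == 0) return(0)
  if (params$k1 > 0) {
    log(1 + params$k1 * abs(s0) / params$k2) / params$k1
  } else {
    abs(s0) / params$k2
  }
}
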