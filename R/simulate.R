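# Closed-loop simulation engine: configuration, trajectory container and
# the dispatcher over controller types.

#' Closed-loop simulation configuration
#'
#' @param G_ref reference (basal) glucose in mg/dL; default 70.
#' @param G0 initial glucose in mg/dL; default 200 (the hyperglycemic bolus
#'   start of the reproduction runs).
#' @param dt integration step in seconds.
#' @param horizon simulation duration in seconds (>= 10 dt).
#' @param settling_band settling band as a fraction of the initial
#'   deviation; default 0.02.
#' @param disturbance `NULL`, or a list with `amplitude` (insulin input
#'   units), `omega` (rad/s) and optional `phase` — an input-additive
#'   (matched) sinusoid.
#' @param integrator `"rk4"` (default) or `"euler"`.
#' @param seed integer seed recorded for any randomized element (the core
#'   engine is deterministic; the seed participates in the config
#'   fingerprint).
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(G_ref = 70, G0 = 200, dt = 0.1,
                              horizon = 600, settling_band = 0.02,
                              disturbance = NULL,
                              integrator = c("rk4", "euler"),
                              seed = 1L) {
  integrator <- match.arg(integrator)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be > 0", call. = FALSE)
  if (!is.numeric(horizon) || horizon < 10 * dt)
    stop("`horizon` must be >= 10 * dt", call. = FALSE)
  if (settling_band <= 0 || settling_band >= 1)
    stop("`settling_band` must lie in (0, 1)", call. = FALSE)
  if (G_ref <= 0 || G0 <= 0)
    stop("`G_ref` and `G0` must be physiologically positive", call. = FALSE)
  if (!is.null(disturbance)) {
    if (!is.list(disturbance) ||
        !all(c("amplitude", "omega") %in% names(disturbance)))
      stop("`disturbance` must be a list with `amplitude` and `omega`",
           call. = FALSE)
    if (is.null(disturbance$phase)) disturbance$phase <- 0
  }
  structure(list(G_ref = G_ref, G0 = G0, dt = dt, horizon = horizon,
                 settling_band = settling_band, disturbance = disturbance,
                 integrator = integrator, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Default matched sinusoidal disturbance
#'
#' Amplitude 1 insulin input unit, period 300 s, zero phase. Used by
#' robustness experiments; the headline reproduction runs are
#' disturbance-free.
#'
#' @return A disturbance list for [simulation_config()].
#' @export
default_disturbance <- function() {
  list(amplitude = 1, omega = 2 * pi / 300, phase = 0)
}

ctrl_code <- function(controller) {
  if (is.null(controller)) 0L
  else if (inherits(controller, "pid_gains")) 1L
  else if (inherits(controller, "lqr_solution")) 2L
  else if (inherits(controller, "smc_params")) 3L
  else stop("unsupported controller specification of class ",
            paste(class(controller), collapse = "/"), call. = FALSE)
}

ctrl_par <- function(controller, code) {
  switch(code + 1L,
         numeric(0),
         c(controller$kp, controller$ki, controller$kd),
         as.numeric(controller$K),
         c(controller$c, controller$k1, controller$k2,
           controller$a, controller$b))
}

controller_label <- function(controller) {
  switch(ctrl_code(controller) + 1L, "none", "pid", "lqr", "smc")
}

#' Simulate the closed glucose-insulin loop
#'
#' Integrates the deviation model `xdot = A x + B (u + d(t))`,
#' `y = C x` under the given controller and returns the sampled trajectory
#' in absolute glucose units `G = y + G_ref`. The initial state places the
#' whole initial deviation on the output-coupled third state,
#' `x0 = (0, 0, (G0 - G_ref) / C3)`, so `G(0) = G0`. The PID consumes the
#' error `e = G_ref - G` as a sampled (zero-order-held) discrete law; LQR
#' applies `u = -K x`; SMC applies the equivalent-plus-switching law with
#' `sign(s)` re-evaluated at every integrator substage (chattering is
#' resolved, not suppressed). Deterministic for a fixed configuration.
#'
#' @param plant an `ss_model`. Continuous plants are integrated with the
#'   configured fixed-step scheme; discrete plants are stepped at their
#'   sampling period `Ts` (which overrides `config$dt`).
#' @param controller `NULL` (open loop), [pid_gains()], an `lqr_solution`
#'   from [lqr_design()], or [smc_params()].
#' @param config a [simulation_config()].
#' @return A `glyco_trajectory` data.frame with columns `time_s`,
#'   `glucose_mg_dl`, `control_u`, `sliding_s` (NA for non-SMC runs),
#'   `disturbance`, with the configuration attached as attributes.
#' @examples
#' plant <- tf_to_state_space(printed_continuous_tf())
#' sol <- lqr_design(plant, Q = reference_lqr_weights()$Q, R = 1)
#' traj <- simulate_closed_loop(plant, sol, simulation_config(horizon = 200))
#' settling_time(traj)
#' @export
simulate_closed_loop <- function(plant, controller, config = simulation_config()) {
  stopifnot(inherits(plant, "ss_model"), inherits(config, "simulation_config"))
  code <- ctrl_code(controller)
  if (inherits(controller, "lqr_solution") &&
      controller$domain != plant$domain)
    stop("controller/plant domain mismatch: LQR solution is ",
         controller$domain, " but the plant is ", plant$domain, call. = FALSE)
  c3 <- plant$C[1, 3]
  if (c3 == 0) stop("plant output must couple to the third state", call. = FALSE)
  dev0 <- config$G0 - config$G_ref
  x0 <- c(0, 0, dev0 / c3)
  if (plant$domain == "discrete") {
    dt <- plant$Ts
    integ <- 2L
    if (!is.finite(dt) || dt <= 0)
      stop("discrete plant requires a positive `Ts`", call. = FALSE)
  } else {
    dt <- config$dt
    integ <- if (config$integrator == "euler") 1L else 0L
  }
  nsteps <- as.integer(round(config$horizon / dt))
  dist <- config$disturbance
  M <- cl_loop_cpp(plant$A, as.numeric(plant$B), as.numeric(plant$C),
                   x0, code, ctrl_par(controller, code),
                   dt, nsteps, integ,
                   if (is.null(dist)) 0 else dist$amplitude,
                   if (is.null(dist)) 0 else dist$omega,
                   if (is.null(dist)) 0 else dist$phase,
                   if (code == 3L) controller$sign_zero else 0)
  traj <- data.frame(time_s = M[, 1],
                     glucose_mg_dl = M[, 2] + config$G_ref,
                     control_u = M[, 3],
                     sliding_s = M[, 4],
                     disturbance = M[, 5])
  attr(traj, "config") <- config
  attr(traj, "controller") <- controller_label(controller)
  class(traj) <- c("glyco_trajectory", "data.frame")
  traj
}

#' @export
print.glyco_trajectory <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("Closed-loop glucose trajectory (", attr(x, "controller"),
      " controller, ", nrow(x) - 1L, " steps of ",
      signif(x$time_s[2] - x$time_s[1], 6), " s)\n", sep = "")
  cat("  G_ref = ", cfg$G_ref, " mg/dL, final G = ",
      signif(x$glucose_mg_dl[nrow(x)], 6), " mg/dL\n", sep = "")
  invisible(x)
}
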