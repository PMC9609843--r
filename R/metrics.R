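# Time-response performance metrics and the controller comparison report.

traj_cols <- function(traj) {
  stopifnot(is.data.frame(traj),
            all(c("time_s", "glucose_mg_dl") %in% names(traj)),
            nrow(traj) >= 1L)
  invisible(traj)
}

#' Settling time
#'
#' Earliest time `T` such that the glucose trajectory stays within
#' `band * |G(0) - G_ref|` of the reference for all later samples inside
#' the horizon. Returns `NA` (not settled) if the trajectory is still
#' outside the band at the final sample, and 0 if the initial deviation is
#' zero or the trajectory never leaves the band.
#'
#' @param traj a trajectory data.frame with `time_s` and `glucose_mg_dl`.
#' @param G_ref reference glucose; defaults to the trajectory's configured
#'   reference.
#' @param band band fraction of the initial deviation; defaults to the
#'   configured settling band (0.02).
#' @return Settling time in seconds, or `NA` if not settled.
#' @export
settling_time <- function(traj, G_ref = NULL, band = NULL) {
  traj_cols(traj)
  cfg <- attr(traj, "config")
  if (is.null(G_ref)) G_ref <- if (!is.null(cfg)) cfg$G_ref else
    stop("`G_ref` required for a bare trajectory", call. = FALSE)
  if (is.null(band)) band <- if (!is.null(cfg)) cfg$settling_band else 0.02
  dev0 <- abs(traj$glucose_mg_dl[1] - G_ref)
  if (dev0 == 0) return(0)
  outside <- abs(traj$glucose_mg_dl - G_ref) > band * dev0
  if (!any(outside)) return(0)
  k <- max(which(outside))
  if (k == nrow(traj)) return(NA_real_)
  traj$time_s[k + 1L]
}

#' Rise time (10-90% of the deviation recovery)
#'
#' Time taken for the recovered fraction of the initial deviation to go
#' from 10% to 90%, i.e. for the glucose to cross from 90% to 10% of its
#' initial distance to the reference.
#'
#' @inheritParams settling_time
#' @return Rise time in seconds, or `NA` if the trajectory never recovers
#'   90% of the deviation.
#' @export
rise_time <- function(traj, G_ref = NULL) {
  traj_cols(traj)
  cfg <- attr(traj, "config")
  if (is.null(G_ref)) G_ref <- if (!is.null(cfg)) cfg$G_ref else
    stop("`G_ref` required for a bare trajectory", call. = FALSE)
  dev <- abs(traj$glucose_mg_dl - G_ref)
  dev0 <- dev[1]
  if (dev0 == 0) return(0)
  t10 <- traj$time_s[which(dev <= 0.9 * dev0)[1]]
  t90 <- traj$time_s[which(dev <= 0.1 * dev0)[1]]
  if (is.na(t10) || is.na(t90)) return(NA_real_)
  t90 - t10
}

#' Overshoot
#'
#' Maximum excursion past the reference in the direction opposite to the
#' starting glucose, as a percentage of the commanded change
#' `|G0 - G_ref|`. Zero when the trajectory never crosses the reference.
#' For a hyperglycemic start this measures the hypoglycemic undershoot --
#' the clinically dangerous direction.
#'
#' @inheritParams settling_time
#' @param G0 initial glucose; defaults to the first trajectory sample.
#' @return Overshoot in percent (>= 0).
#' @export
overshoot <- function(traj, G_ref = NULL, G0 = NULL) {
  traj_cols(traj)
  cfg <- attr(traj, "config")
  if (is.null(G_ref)) G_ref <- if (!is.null(cfg)) cfg$G_ref else
    stop("`G_ref` required for a bare trajectory", call. = FALSE)
  if (is.null(G0)) G0 <- traj$glucose_mg_dl[1]
  if (G0 == G_ref) stop("`G0` must differ from `G_ref`", call. = FALSE)
  dir <- sign(G0 - G_ref)
  excursion <- max(0, dir * (G_ref - traj$glucose_mg_dl))
  100 * excursion / abs(G0 - G_ref)
}

#' Steady-state error
#'
#' Mean absolute glucose deviation from the reference over the final 5% of
#' the horizon.
#'
#' @inheritParams settling_time
#' @param final_fraction fraction of the horizon to average over.
#' @return Steady-state error in mg/dL.
#' @export
steady_state_error <- function(traj, G_ref = NULL, final_fraction = 0.05) {
  traj_cols(traj)
  cfg <- attr(traj, "config")
  if (is.null(G_ref)) G_ref <- if (!is.null(cfg)) cfg$G_ref else
    stop("`G_ref` required for a bare trajectory", call. = FALSE)
  n <- nrow(traj)
  k <- max(1L, n - as.integer(floor(final_fraction * n)) + 1L)
  mean(abs(traj$glucose_mg_dl[k:n] - G_ref))
}

moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width == 1L) return(x)
  cs <- cumsum(c(0, x))
  n <- length(x)
  half <- width %/% 2L
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Chattering metrics of the control signal
#'
#' Quantifies the high-frequency switching of the control input over the
#' final part of the run: the control is detrended by a centered moving
#' average (default width 100 samples, wide enough that an oscillation of
#' tens of samples per cycle passes through to the residual essentially
#' unattenuated), then the sign-change rate (changes per second) and the
#' peak-to-peak amplitude of the residual are reported.
#'
#' @param traj a trajectory with a `control_u` column.
#' @param window_fraction final fraction of the horizon analyzed
#'   (default 0.2). The window must contain at least 10 samples.
#' @param ma_width moving-average width in samples for detrending.
#' @return A list `(rate, amplitude)`: sign changes per second and
#'   peak-to-peak of the detrended control.
#' @export
chattering_index <- function(traj, window_fraction = 0.2, ma_width = 100L) {
  traj_cols(traj)
  if (!"control_u" %in% names(traj))
    stop("trajectory has no control samples", call. = FALSE)
  n <- nrow(traj)
  k0 <- n - as.integer(floor(window_fraction * n)) + 1L
  if (n - k0 + 1L < 10L)
    stop("chattering window must contain at least 10 samples", call. = FALSE)
  u <- traj$control_u[k0:n]
  t <- traj$time_s[k0:n]
  r <- u - moving_average(u, ma_width)
  # drop the half-window at each end where the centered average is clamped
  half <- min(as.integer(ma_width) %/% 2L, (length(r) - 10L) %/% 2L)
  if (half > 0L) {
    keep <- (half + 1L):(length(r) - half)
    r <- r[keep]
    t <- t[keep]
  }
  s <- sign(r)
  s <- s[s != 0]
  changes <- if (length(s) > 1L) sum(diff(s) != 0) else 0L
  span <- t[length(t)] - t[1]
  list(rate = if (span > 0) changes / span else 0,
       amplitude = if (length(r)) max(r) - min(r) else 0)
}

#' First-order low-pass filter
#'
#' Discretizes `ydot = cutoff (u - y)` exactly on a uniform grid
#' (exponential smoothing with factor `exp(-cutoff dt)`), giving unit DC
#' gain and -20 dB/decade rolloff. The standard chattering mitigation for
#' first-order sliding-mode control.
#'
#' @param u numeric control series.
#' @param dt sample interval in seconds.
#' @param cutoff filter cutoff in rad/s (> 0).
#' @param y0 initial filter state; defaults to the first sample.
#' @return The filtered series, same length as `u`.
#' @export
low_pass_filter <- function(u, dt, cutoff, y0 = u[1]) {
  if (!is.numeric(cutoff) || cutoff <= 0) stop("`cutoff` must be > 0",
                                               call. = FALSE)
  a <- exp(-cutoff * dt)
  y <- numeric(length(u))
  acc <- y0
  for (i in seq_along(u)) {
    acc <- a * acc + (1 - a) * u[i]
    y[i] <- acc
  }
  y
}

#' Performance metrics of one closed-loop run
#'
#' @inheritParams settling_time
#' @return A `performance_metrics` list: `settling_time_s`, `settled`,
#'   `rise_time_s`, `overshoot_pct`, `steady_state_error_mg_dl`,
#'   `chattering_rate_hz`, `chattering_amplitude`.
#' @export
performance_metrics <- function(traj, G_ref = NULL, band = NULL) {
  st <- settling_time(traj, G_ref, band)
  ch <- chattering_index(traj)
  structure(list(settling_time_s = st,
                 settled = !is.na(st),
                 rise_time_s = rise_time(traj, G_ref),
                 overshoot_pct = overshoot(traj, G_ref),
                 steady_state_error_mg_dl = steady_state_error(traj, G_ref),
                 chattering_rate_hz = ch$rate,
                 chattering_amplitude = ch$amplitude),
            class = "performance_metrics")
}

#' @export
print.performance_metrics <- function(x, ...) {
  cat(sprintf("settling %s s | rise %s s | overshoot %.3g%% | sse %.3g mg/dL | chatter %.3g /s (p-p %.3g)\n",
              if (x$settled) format(x$settling_time_s) else "not settled",
              format(x$rise_time_s), x$overshoot_pct,
              x$steady_state_error_mg_dl, x$chattering_rate_hz,
              x$chattering_amplitude))
  invisible(x)
}

# 32-bit FNV-1a hash of a string, as 8 hex digits (doubles, since the byte
# only touches the low 8 bits the xor reduces to the low byte)
fnv1a <- function(txt) {
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- (h %/% 256) * 256 + bitwXor(as.integer(h %% 256), b)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (16777619 * lo + ((16777619 * hi) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

config_fingerprint <- function(config) {
  fields <- c(sprintf("%.17g", c(config$G_ref, config$G0, config$dt,
                                 config$horizon, config$settling_band)),
              config$integrator, as.character(config$seed),
              if (is.null(config$disturbance)) "nodist" else
                sprintf("%.17g", c(config$disturbance$amplitude,
                                   config$disturbance$omega,
                                   config$disturbance$phase)))
  fnv1a(paste(fields, collapse = "|"))
}

#' Compare controllers on an identical plant and configuration
#'
#' Runs each controller through [simulate_closed_loop()] on the same plant
#' and configuration and tabulates the performance metrics, preserving the
#' given ordering. Individual simulation failures (e.g. divergence) are
#' recorded in the `error` column rather than aborting the report.
#'
#' @param plant an `ss_model`.
#' @param controllers named list of controller specifications.
#' @param config a [simulation_config()], or a named list of one
#'   configuration per controller (matched by name) when controllers need
#'   different step sizes.
#' @return A `controller_comparison` data.frame, one row per controller,
#'   with the config fingerprint in attribute `fingerprint`.
#' @examples
#' plant <- tf_to_state_space(printed_continuous_tf())
#' ctrls <- list(lqr = lqr_design(plant, reference_lqr_weights()$Q, 1),
#'               smc = reference_smc_params(plant = plant))
#' compare_controllers(plant, ctrls, simulation_config(dt = 0.01, horizon = 100))
#' @export
compare_controllers <- function(plant, controllers, config = simulation_config()) {
  if (!is.list(controllers) || length(controllers) < 1L)
    stop("need at least one controller", call. = FALSE)
  if (is.null(names(controllers)))
    names(controllers) <- vapply(controllers, controller_label, "")
  per_ctrl_cfg <- !inherits(config, "simulation_config")
  rows <- lapply(names(controllers), function(nm) {
    cfg <- if (per_ctrl_cfg) config[[nm]] else config
    res <- tryCatch({
      traj <- simulate_closed_loop(plant, controllers[[nm]], cfg)
      m <- performance_metrics(traj)
      data.frame(controller = nm,
                 settling_time_s = m$settling_time_s,
                 settled = m$settled,
                 rise_time_s = m$rise_time_s,
                 overshoot_pct = m$overshoot_pct,
                 steady_state_error_mg_dl = m$steady_state_error_mg_dl,
                 chattering_rate_hz = m$chattering_rate_hz,
                 chattering_amplitude = m$chattering_amplitude,
                 error = NA_character_,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(controller = nm, settling_time_s = NA_real_,
                 settled = FALSE, rise_time_s = NA_real_,
                 overshoot_pct = NA_real_,
                 steady_state_error_mg_dl = NA_real_,
                 chattering_rate_hz = NA_real_,
                 chattering_amplitude = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  fp <- if (per_ctrl_cfg)
    paste(vapply(config, config_fingerprint, ""), collapse = "+")
  else config_fingerprint(config)
  attr(out, "fingerprint") <- fp
  class(out) <- c("controller_comparison", "data.frame")
  out
}

#' @export
print.controller_comparison <- function(x, ...) {
  cat("Controller comparison (config fingerprint ",
      attr(x, "fingerprint"), ")\n", sep = "")
  print.data.frame(x, digits = 5, row.names = FALSE)
  invisible(x)
}
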