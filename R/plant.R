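# Identified glucose-insulin plant: discrete transfer function, continuous
# conversion, state-space realizations and structural analysis.

#' Identified patient model parameters
#'
#' Parameters of the identified third-order discrete glucose-insulin deviation
#' model \eqn{G(z) = -C_0 / ((z-p_1)(z-p_2)(z-p_3))}. The gain `C0` is
#' positive; the model carries an explicit negative sign (insulin lowers
#' glucose). The poles `p1`, `p2`, `p3` are patient-specific and must lie in
#' (0, 1): stable, non-oscillatory discrete dynamics.
#'
#' @param C0 positive plant gain (mg/dL glucose deviation per insulin input
#'   unit, after DC scaling).
#' @param p1,p2,p3 discrete poles, each strictly inside (0, 1).
#' @param Ts sampling period in seconds. The identification literature does
#'   not fix it; `600` (10 min) is the value under which the derived
#'   continuous model agrees with the reference continuous coefficients to
#'   three significant figures.
#' @return An object of class `patient_params`.
#' @examples
#' patient_params()                 # the nominal identified patient
#' patient_params(p2 = 0.94)       # a perturbed virtual patient
#' @export
patient_params <- function(C0 = 0.132, p1 = 0.965, p2 = 0.95, p3 = 0.93,
                           Ts = 600) {
  for (nm in c("C0", "p1", "p2", "p3", "Ts")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("`", nm, "` must be a single finite number", call. = FALSE)
  }
  if (C0 <= 0) stop("`C0` must be > 0", call. = FALSE)
  for (nm in c("p1", "p2", "p3")) {
    v <- get(nm)
    if (v <= 0 || v >= 1)
      stop("`", nm, "` must lie strictly in (0, 1)", call. = FALSE)
  }
  if (Ts <= 0) stop("`Ts` must be > 0", call. = FALSE)
  structure(list(C0 = C0, p1 = p1, p2 = p2, p3 = p3, Ts = Ts),
            class = "patient_params")
}

#' @export
print.patient_params <- function(x, ...) {
  cat("Identified glucose-insulin patient model\n")
  cat(sprintf("  C0 = %g, poles = (%g, %g, %g), Ts = %g s\n",
              x$C0, x$p1, x$p2, x$p3, x$Ts))
  invisible(x)
}

new_dtf <- function(num, den, Ts) {
  structure(list(num = as.numeric(num), den = as.numeric(den), Ts = Ts),
            class = "discrete_tf")
}

new_ctf <- function(num, den) {
  den <- as.numeric(den)
  if (abs(den[1] - 1) > 1e-12) {
    num <- num / den[1]
    den <- den / den[1]
  }
  structure(list(num = as.numeric(num), den = den), class = "continuous_tf")
}

#' @export
print.discrete_tf <- function(x, ...) {
  cat("Discrete transfer function (Ts =", x$Ts, "s)\n")
  cat("  num:", paste(signif(x$num, 6), collapse = " "), "\n")
  cat("  den:", paste(signif(x$den, 6), collapse = " "), "\n")
  invisible(x)
}

#' @export
print.continuous_tf <- function(x, ...) {
  cat("Continuous transfer function\n")
  cat("  num:", paste(signif(x$num, 6), collapse = " "), "\n")
  cat("  den:", paste(signif(x$den, 6), collapse = " "), "\n")
  invisible(x)
}

# expand monic polynomial with given roots; descending coefficients
poly_from_roots <- function(r) {
  p <- 1
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

# multiply two polynomials (descending coefficients)
poly_mul <- function(a, b) {
  r <- rep(0, length(a) + length(b) - 1L)
  for (i in seq_along(a)) r[i:(i + length(b) - 1L)] <- r[i:(i + length(b) - 1L)] + a[i] * b
  r
}

# evaluate polynomial (descending coefficients) at (possibly complex) x
poly_eval <- function(p, x) {
  acc <- rep(p[1], length(x))
  for (k in p[-1]) acc <- acc * x + k
  acc
}

# roots of a polynomial (descending coefficients), Newton-polished so that
# well-separated roots are recovered to near machine precision
poly_roots <- function(p) {
  r <- polyroot(rev(p))
  if (length(p) < 2L) return(r)
  dp <- p[-length(p)] * seq(length(p) - 1L, 1L)
  for (i in 1:3) {
    step <- poly_eval(p, r) / poly_eval(dp, r)
    step[!is.finite(step)] <- 0
    r <- r - step
  }
  r
}

#' Build the discrete glucose-insulin transfer function
#'
#' Constructs \eqn{G(z) = -C_0 / ((z-p_1)(z-p_2)(z-p_3))}: numerator `-C0`,
#' monic cubic denominator with roots at the patient's poles.
#'
#' @param params a [patient_params()] object.
#' @return A `discrete_tf` with fields `num`, `den` (descending powers of z)
#'   and `Ts`.
#' @examples
#' build_discrete_tf(patient_params())
#' @export
build_discrete_tf <- function(params) {
  stopifnot(inherits(params, "patient_params"))
  new_dtf(num = -params$C0,
          den = poly_from_roots(c(params$p1, params$p2, params$p3)),
          Ts = params$Ts)
}

#' DC gain of a transfer function
#'
#' Gain at zero frequency: `G(1)` for a discrete model, `G(0)` for a
#' continuous one. For the nominal patient both are close to -1077: one
#' insulin input unit lowers steady-state glucose by about 1077 mg/dL, the
#' deliberately overestimated-gain identification.
#'
#' @param tf a `discrete_tf` or `continuous_tf`.
#' @return The scalar DC gain.
#' @export
dc_gain <- function(tf) {
  if (inherits(tf, "discrete_tf")) {
    poly_eval(tf$num, 1) / poly_eval(tf$den, 1)
  } else if (inherits(tf, "continuous_tf")) {
    tf$num[length(tf$num)] / tf$den[length(tf$den)]
  } else stop("not a transfer function", call. = FALSE)
}

#' Convert the discrete plant to a continuous transfer function
#'
#' Exact zero-order-hold inverse: the unique continuous model whose
#' ZOH discretization at `Ts` reproduces the discrete plant. Each discrete
#' pole `p` maps to the continuous pole `log(p)/Ts` (so this is also a
#' matched-pole mapping), the DC gain is preserved exactly, and the
#' numerator is recovered through the companion realization:
#' `Ac = log(Ad)/Ts`, `Bc = Ac (Ad - I)^-1 Bd`, `Cc = Cd`. For the nominal
#' patient at `Ts = 600` s this reproduces every coefficient of
#' [printed_continuous_tf()] to at least three significant figures.
#'
#' Restricted to distinct real positive discrete poles (the identified
#' glycemic models); the matrix logarithm is taken through the
#' eigendecomposition.
#'
#' @param dtf a `discrete_tf` from [build_discrete_tf()].
#' @return A `continuous_tf`.
#' @examples
#' ctf <- discrete_to_continuous(build_discrete_tf(patient_params()))
#' ctf$den  # (1, 2.658e-4, 2.26e-8, 6.14e-13) to 3 s.f.
#' @export
discrete_to_continuous <- function(dtf) {
  stopifnot(inherits(dtf, "discrete_tf"))
  if (dtf$Ts <= 0) stop("`Ts` must be > 0", call. = FALSE)
  zroots <- poly_roots(dtf$den)
  if (any(abs(Im(zroots)) > 1e-9) || any(Re(zroots) <= 0))
    stop("discrete poles must be real and positive for the log mapping",
         call. = FALSE)
  if (any(abs(zroots) >= 1)) stop("discrete plant must be stable", call. = FALSE)
  n <- length(dtf$den) - 1L
  a <- dtf$den[-1] / dtf$den[1]
  Ad <- if (n == 1L) matrix(-a, 1, 1) else rbind(-a, cbind(diag(n - 1L), 0))
  dimnames(Ad) <- NULL
  Bd <- c(1, rep(0, n - 1L))
  Cd <- c(rep(0, n - length(dtf$num)), dtf$num / dtf$den[1])
  ev <- eigen(Ad)
  if (any(abs(outer(ev$values, ev$values, "-"))[lower.tri(diag(n))] < 1e-10))
    stop("repeated discrete poles are not supported by the log mapping",
         call. = FALSE)
  Ac <- Re(ev$vectors %*% diag(log(ev$values), n) %*% solve(ev$vectors)) / dtf$Ts
  Bc <- Ac %*% solve(Ad - diag(n), Bd)
  den <- char_poly(Ac)
  num <- (char_poly(Ac - Bc %*% t(Cd)) - den)[-1]
  while (length(num) > 1 && abs(num[1]) < 1e-14 * max(abs(num))) num <- num[-1]
  new_ctf(num = num, den = den)
}

#' Reference continuous plant (canonical coefficients)
#'
#' The canonical continuous glucose-insulin deviation model used by all
#' reproduction simulations:
#' \deqn{G(s) = \frac{-8.263\times10^{-5}s^2 + 4.022\times10^{-7}s
#'   - 6.61\times10^{-10}}{s^3 + 2.658\times10^{-4}s^2 + 2.26\times10^{-8}s
#'   + 6.14\times10^{-13}}.}
#' Open loop it is Hurwitz-stable (slow, hours-scale modes); under unity
#' feedback it is unstable, which is what motivates controller design.
#'
#' @return A `continuous_tf` with the reference coefficients.
#' @export
printed_continuous_tf <- function() {
  new_ctf(num = c(-8.263e-5, 4.022e-7, -6.61e-10),
          den = c(1, 2.658e-4, 2.26e-8, 6.14e-13))
}

new_ss <- function(A, B, C, D = 0, domain = c("continuous", "discrete"),
                   Ts = NA_real_) {
  domain <- match.arg(domain)
  A <- as.matrix(A)
  B <- matrix(as.numeric(B), ncol = 1)
  C <- matrix(as.numeric(C), nrow = 1)
  stopifnot(nrow(A) == ncol(A), nrow(B) == nrow(A), ncol(C) == nrow(A),
            length(D) == 1L)
  structure(list(A = A, B = B, C = C, D = as.numeric(D),
                 domain = domain, Ts = Ts),
            class = "ss_model")
}

#' @export
print.ss_model <- function(x, ...) {
  cat("State-space model (", x$domain,
      if (x$domain == "discrete" && is.finite(x$Ts)) paste0(", Ts = ", x$Ts, " s"),
      ")\n", sep = "")
  cat("A:\n"); print(x$A)
  cat("B:", as.numeric(x$B), "\nC:", as.numeric(x$C), "\nD:", x$D, "\n")
  invisible(x)
}

#' Reference state-space fixture
#'
#' The verbatim reference (A, B, C, D) realization that accompanies the
#' identified model. Its numeric content is not consistent with the
#' continuous coefficients of [printed_continuous_tf()] (trace of A is 2.805
#' while the discrete poles sum to 2.845, and its output map differs). Its
#' spectrum sits essentially on the unit circle (one real eigenvalue at
#' about 1.013 and a stable complex pair), so the fixture is marginally
#' unstable under either domain reading; it is shipped tagged `"discrete"`
#' and used for structural (controllability/observability) analysis and as
#' the LQR design fixture, while [tf_to_state_space()] of the continuous
#' plant is the simulation realization. Both are exposed; see the methods
#' vignette for the discussion of this discrepancy.
#'
#' @param domain domain tag to attach, `"discrete"` (default) or
#'   `"continuous"` for experimentation.
#' @return An `ss_model` with the reference matrices.
#' @export
printed_state_space <- function(domain = c("discrete", "continuous")) {
  domain <- match.arg(domain)
  new_ss(A = rbind(c(2.805, -1.311, 0.8172),
                   c(2,      0,     0),
                   c(0,      0.5,   0)),
         B = c(0.5, 0, 0),
         C = c(0, 0, -0.264),
         D = 0,
         domain = domain,
         Ts = if (domain == "discrete") 600 else NA_real_)
}

#' Controllable-canonical state-space realization
#'
#' Realizes a strictly proper degree-3 continuous transfer function in
#' controller canonical form: `A` is the companion matrix of the monic
#' denominator, `B = e1`, `C` holds the numerator coefficients, `D = 0`.
#'
#' @param ctf a `continuous_tf` with monic cubic denominator and numerator
#'   degree at most 2.
#' @return An `ss_model` (continuous domain).
#' @export
tf_to_state_space <- function(ctf) {
  stopifnot(inherits(ctf, "continuous_tf"))
  n <- length(ctf$den) - 1L
  if (n != 3L)
    stop("degree mismatch: expected a monic cubic denominator, got degree ",
         n, call. = FALSE)
  if (length(ctf$num) >= length(ctf$den))
    stop("degree mismatch: model must be strictly proper", call. = FALSE)
  num <- c(rep(0, n - length(ctf$num)), ctf$num)
  a <- ctf$den[-1]
  A <- rbind(-a, cbind(diag(n - 1L), 0))
  dimnames(A) <- NULL
  new_ss(A = A, B = c(1, rep(0, n - 1L)), C = num, D = 0,
         domain = "continuous")
}

#' Transfer function of a state-space model
#'
#' Recovers `C (sI - A)^-1 B + D` as numerator/denominator coefficient
#' vectors, using the identity `num(s) = det(sI - A + B C) - det(sI - A)`
#' for the strictly proper part.
#'
#' @param ss an `ss_model`.
#' @return A `continuous_tf` (coefficients are domain-agnostic; the same
#'   algebra applies in z for discrete models).
#' @export
ss_to_tf <- function(ss) {
  stopifnot(inherits(ss, "ss_model"))
  den <- char_poly(ss$A)
  num <- char_poly(ss$A - ss$B %*% ss$C) - den
  num <- num[-1]                       # leading term cancels
  while (length(num) > 1 && abs(num[1]) < 1e-14 * max(abs(num))) num <- num[-1]
  if (ss$D != 0) num <- c(rep(0, length(den) - length(num)), num) + ss$D * den
  new_ctf(num = num, den = den)
}

# characteristic polynomial, descending coefficients, via Faddeev-LeVerrier
char_poly <- function(A) {
  n <- nrow(A)
  coefs <- numeric(n + 1L)
  coefs[1] <- 1
  M <- diag(n)
  for (k in 1:n) {
    M <- A %*% M
    coefs[k + 1L] <- -sum(diag(M)) / k
    M <- M + coefs[k + 1L] * diag(n)
  }
  coefs
}

#' Controllability and observability analysis
#'
#' Builds the controllability matrix \eqn{\Phi = [B, AB, A^2B]} and the
#' observability matrix \eqn{\Psi = [C; CA; CA^2]} and reports their ranks.
#' Full rank of both certifies that every state can be steered by the
#' insulin input and reconstructed from the glucose output, the
#' prerequisites for state-feedback (LQR, SMC) design.
#'
#' @param ss an `ss_model`.
#' @param tol rank tolerance passed to [qr()], relative to the largest
#'   matrix entry.
#' @return A `structural_analysis` list: `controllability`, `observability`,
#'   `rank_controllability`, `rank_observability`, `controllable`,
#'   `observable`.
#' @examples
#' structural_analysis(printed_state_space())
#' @export
structural_analysis <- function(ss, tol = 1e-9) {
  stopifnot(inherits(ss, "ss_model"))
  n <- nrow(ss$A)
  ctrb <- ss$B
  obsv <- ss$C
  for (k in seq_len(n - 1L)) {
    ctrb <- cbind(ctrb, ss$A %*% ctrb[, k, drop = FALSE])
    obsv <- rbind(obsv, obsv[k, , drop = FALSE] %*% ss$A)
  }
  dimnames(ctrb) <- dimnames(obsv) <- NULL
  rk <- function(M) qr(M, tol = tol * max(1, max(abs(M))))$rank
  rc <- rk(ctrb); ro <- rk(obsv)
  structure(list(controllability = ctrb, observability = obsv,
                 rank_controllability = rc, rank_observability = ro,
                 controllable = rc == n, observable = ro == n),
            class = "structural_analysis")
}

#' @export
print.structural_analysis <- function(x, ...) {
  cat("Structural analysis\n")
  cat("  rank(controllability) =", x$rank_controllability,
      if (x$controllable) "(controllable)" else "(NOT controllable)", "\n")
  cat("  rank(observability)   =", x$rank_observability,
      if (x$observable) "(observable)" else "(NOT observable)", "\n")
  invisible(x)
}

#' Poles of the unity negative-feedback loop
#'
#' Roots of `den(s) + num(s)`, the characteristic polynomial of the loop
#' `y = G(s)(r - y)`. For the reference glucose plant at least one root has
#' positive real part: closing the loop with no controller destabilizes the
#' (open-loop stable) plant, because of its large negative DC gain.
#'
#' @param ctf a `continuous_tf`.
#' @return Complex vector of closed-loop poles.
#' @examples
#' max(Re(unity_feedback_poles(printed_continuous_tf())))  # > 0
#' @export
unity_feedback_poles <- function(ctf) {
  stopifnot(inherits(ctf, "continuous_tf"))
  num <- c(rep(0, length(ctf$den) - length(ctf$num)), ctf$num)
  poly_roots(ctf$den + num)
}

#' Open-loop poles of a continuous transfer function
#' @param ctf a `continuous_tf`.
#' @return Complex vector of denominator roots.
#' @export
open_loop_poles <- function(ctf) {
  stopifnot(inherits(ctf, "continuous_tf"))
  poly_roots(ctf$den)
}

#' Frequency response of a continuous transfer function
#'
#' Evaluates `G(j omega)` pointwise and returns magnitude in dB and phase in
#' degrees (the numeric content of a Bode plot).
#'
#' @param ctf a `continuous_tf`.
#' @param frequencies angular frequencies in rad/s, all strictly positive.
#' @return A data.frame with columns `omega`, `magnitude_db`, `phase_deg`.
#' @export
frequency_response <- function(ctf, frequencies) {
  stopifnot(inherits(ctf, "continuous_tf"))
  if (any(!is.finite(frequencies)) || any(frequencies <= 0))
    stop("`frequencies` must be positive", call. = FALSE)
  g <- poly_eval(ctf$num, 1i * frequencies) / poly_eval(ctf$den, 1i * frequencies)
  data.frame(omega = frequencies,
             magnitude_db = 20 * log10(Mod(g)),
             phase_deg = Arg(g) * 180 / pi)
}

#' Sample a virtual-patient cohort
#'
#' The identified poles and gain vary from patient to patient; this
#' generator emulates that inter-patient variability by perturbing the
#' nominal parameters multiplicatively with independent uniform factors
#' `1 + U(-spread, spread)`. Element 1 is always the nominal patient.
#' Perturbed poles are clipped into (0, 1) (with a warning) so every sampled
#' patient is a valid stable model. Deterministic for a fixed seed.
#'
#' @param n cohort size (>= 1).
#' @param seed integer RNG seed.
#' @param spread relative perturbation fraction, in [0, 0.05).
#' @return A list of [patient_params()] objects of length `n`.
#' @examples
#' cohort <- sample_patient_cohort(5, seed = 7, spread = 0.01)
#' @export
sample_patient_cohort <- function(n, seed, spread = 0.01) {
  if (!is.numeric(n) || n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (!is.numeric(spread) || spread < 0 || spread >= 0.05)
    stop("`spread` must lie in [0, 0.05)", call. = FALSE)
  n <- as.integer(n)
  nominal <- patient_params()
  out <- vector("list", n)
  out[[1]] <- nominal
  if (n == 1L) return(out)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  eps <- 1e-6
  clipped <- FALSE
  for (i in 2:n) {
    f <- 1 + runif(4, -spread, spread)
    p <- c(nominal$p1, nominal$p2, nominal$p3) * f[2:4]
    if (any(p <= 0) || any(p >= 1)) {
      clipped <- TRUE
      p <- pmin(pmax(p, eps), 1 - eps)
    }
    out[[i]] <- patient_params(C0 = nominal$C0 * f[1],
                               p1 = p[1], p2 = p[2], p3 = p[3],
                               Ts = nominal$Ts)
  }
  if (clipped) warning("some sampled poles were clipped into (0, 1)")
  out
}
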