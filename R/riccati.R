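# Algebraic Riccati solvers and LQR synthesis.

sym <- function(M) (M + t(M)) / 2

#' Continuous algebraic Riccati equation
#'
#' Solves `A'P + PA - PBR^-1B'P + Q = 0` for the stabilizing `P` via the
#' invariant subspace of the Hamiltonian matrix associated with its `n`
#' stable eigenvalues.
#'
#' @param A,B system matrices.
#' @param Q state weight (symmetric positive semidefinite).
#' @param R input weight (symmetric positive definite).
#' @return The stabilizing symmetric solution `P`.
#' @export
solve_care <- function(A, B, Q, R) {
  A <- as.matrix(A); B <- as.matrix(B)
  Q <- as.matrix(Q); R <- as.matrix(R)
  n <- nrow(A)
  Rinv <- solve(R)
  H <- rbind(cbind(A, -B %*% Rinv %*% t(B)),
             cbind(-Q, -t(A)))
  ev <- eigen(H)
  idx <- which(Re(ev$values) < 0)
  if (length(idx) != n)
    stop("Hamiltonian matrix does not have ", n, " stable eigenvalues; ",
         "the pair (A, B) may not be stabilizable", call. = FALSE)
  X <- ev$vectors[, idx, drop = FALSE]
  X1 <- X[1:n, , drop = FALSE]
  X2 <- X[(n + 1):(2 * n), , drop = FALSE]
  P <- tryCatch(X2 %*% solve(X1), error = function(e)
    stop("singular invariant-subspace basis; CARE has no stabilizing solution",
         call. = FALSE))
  sym(Re(P))
}

#' Discrete algebraic Riccati equation
#'
#' Solves `P = A'PA - A'PB (R + B'PB)^-1 B'PA + Q` for the stabilizing `P`
#' by fixed-point iteration of the Riccati recursion from `P0 = Q`
#' (convergent for stabilizable/detectable problems).
#'
#' @inheritParams solve_care
#' @param tol relative convergence tolerance.
#' @param max_iter iteration cap.
#' @return The stabilizing symmetric solution `P`.
#' @export
solve_dare <- function(A, B, Q, R, tol = 1e-13, max_iter = 200000L) {
  A <- as.matrix(A); B <- as.matrix(B)
  Q <- as.matrix(Q); R <- as.matrix(R)
  P <- Q
  for (i in seq_len(max_iter)) {
    BtP <- t(B) %*% P
    Pn <- sym(t(A) %*% P %*% A -
                t(A) %*% P %*% B %*% solve(R + BtP %*% B, BtP %*% A) + Q)
    if (max(abs(Pn - P)) <= tol * max(1, max(abs(Pn)))) return(Pn)
    P <- Pn
  }
  stop("DARE iteration did not converge; the pair (A, B) may not be ",
       "stabilizable", call. = FALSE)
}

check_psd <- function(M, name, strict = FALSE) {
  M <- as.matrix(M)
  if (max(abs(M - t(M))) > 1e-8 * max(1, max(abs(M))))
    stop("`", name, "` must be symmetric", call. = FALSE)
  ev <- eigen(sym(M), symmetric = TRUE, only.values = TRUE)$values
  if (strict && min(ev) <= 0)
    stop("`", name, "` must be positive definite", call. = FALSE)
  if (!strict && min(ev) < -1e-10 * max(1, max(abs(ev))))
    stop("`", name, "` must be positive semidefinite", call. = FALSE)
  invisible(TRUE)
}

#' LQR state-feedback design
#'
#' Minimizes the quadratic cost `integral (x'Qx + u'Ru) dt` (or its sum for
#' discrete models) and returns the optimal state-feedback gain. Dispatches
#' on the model's domain tag: the continuous problem solves the CARE and
#' returns `K = R^-1 B'P`; the discrete problem solves the DARE and returns
#' `K = (R + B'PB)^-1 B'PA`. The control law is `u = -K x`.
#'
#' @param model an `ss_model`.
#' @param Q state weight matrix (symmetric positive semidefinite).
#' @param R input weight (positive definite matrix or positive scalar).
#' @return An `lqr_solution` with fields `K` (1 x n gain), `P` (Riccati
#'   solution), `residual` (relative algebraic residual at `P`),
#'   `closed_loop_eigenvalues` and `domain`.
#' @examples
#' sol <- lqr_design(tf_to_state_space(printed_continuous_tf()),
#'                   Q = reference_lqr_weights()$Q, R = 1)
#' sol$K
#' @export
lqr_design <- function(model, Q, R) {
  stopifnot(inherits(model, "ss_model"))
  A <- model$A; B <- model$B
  Q <- as.matrix(Q)
  R <- as.matrix(R)
  check_psd(Q, "Q")
  check_psd(R, "R", strict = TRUE)
  if (model$domain == "continuous") {
    P <- solve_care(A, B, Q, R)
    K <- solve(R, t(B) %*% P)
    res <- t(A) %*% P + P %*% A - P %*% B %*% solve(R, t(B) %*% P) + Q
    cl <- eigen(A - B %*% K, only.values = TRUE)$values
    stable <- max(Re(cl)) < 0
  } else {
    P <- solve_dare(A, B, Q, R)
    BtP <- t(B) %*% P
    K <- solve(R + BtP %*% B, BtP %*% A)
    res <- t(A) %*% P %*% A - P -
      t(A) %*% P %*% B %*% solve(R + BtP %*% B, BtP %*% A) + Q
    cl <- eigen(A - B %*% K, only.values = TRUE)$values
    stable <- max(Mod(cl)) < 1
  }
  relres <- max(abs(res)) / max(1, max(abs(P)))
  if (!stable)
    stop("LQR synthesis produced an unstable closed loop; check that ",
         "(A, B) is stabilizable and (A, Q^{1/2}) detectable", call. = FALSE)
  structure(list(K = matrix(as.numeric(K), nrow = 1),
                 P = P, residual = relres,
                 closed_loop_eigenvalues = cl,
                 domain = model$domain),
            class = "lqr_solution")
}

#' @export
print.lqr_solution <- function(x, ...) {
  cat("LQR solution (", x$domain, " Riccati)\n", sep = "")
  cat("  K =", signif(as.numeric(x$K), 6), "\n")
  cat("  residual =", format(x$residual, digits = 3),
      " closed-loop eigenvalues:", format(x$closed_loop_eigenvalues, digits = 4), "\n")
  invisible(x)
}
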