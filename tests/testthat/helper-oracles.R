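# Independent oracles and generators used across the suite.

# Solve the continuous Lyapunov equation A'X + X A + Q = 0 by Kronecker
# vectorization (independent of the package's Riccati route).
lyap_solve <- function(A, Q) {
  n <- nrow(A)
  M <- kronecker(diag(n), t(A)) + kronecker(t(A), diag(n))
  matrix(solve(M, -as.vector(Q)), n, n)
}

# Newton-Kleinman iteration for the continuous LQR gain, started from K = 0
# (valid when A is stable). Converges quadratically to the stabilizing
# Riccati solution.
nk_lqr_gain <- function(A, B, Q, R, tol = 1e-12, max_iter = 100) {
  A <- as.matrix(A); B <- as.matrix(B); Q <- as.matrix(Q); R <- as.matrix(R)
  K <- matrix(0, ncol(B), nrow(A))
  P_old <- NULL
  for (i in seq_len(max_iter)) {
    Acl <- A - B %*% K
    P <- lyap_solve(Acl, Q + t(K) %*% R %*% K)
    K <- solve(R, t(B) %*% P)
    if (!is.null(P_old) &&
        max(abs(P - P_old)) < tol * max(1, max(abs(P)))) break
    P_old <- P
  }
  list(K = K, P = P)
}

# Random stable continuous system with PSD state weight.
random_stable_system <- function(n) {
  M <- matrix(rnorm(n * n), n, n)
  A <- M - diag(n) * (max(Re(eigen(M, only.values = TRUE)$values)) +
                        0.5 + runif(1))
  B <- matrix(rnorm(n), n, 1)
  W <- matrix(rnorm(n * n), n, n)
  Q <- crossprod(W) / n
  R <- matrix(0.5 + runif(1), 1, 1)
  list(A = A, B = B, Q = Q, R = R)
}

# Synthetic exponential recovery trajectory G(t) = G_ref + dev0 * exp(-t/tau)
exp_trajectory <- function(G_ref = 70, dev0 = 130, tau = 10, dt = 0.05,
                           horizon = 120) {
  t <- seq(0, horizon, by = dt)
  data.frame(time_s = t,
             glucose_mg_dl = G_ref + dev0 * exp(-t / tau),
             control_u = 0, sliding_s = NA_real_, disturbance = 0)
}

ref_plant <- function() tf_to_state_space(printed_continuous_tf())
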