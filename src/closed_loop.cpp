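// Fixed-step closed-loop simulation of the third-order glucose-insulin
// deviation model under PID / state-feedback / sliding-mode control.
//
// The controller is evaluated inside the integrator substages for the
// state-feedback and sliding-mode laws (so the switching term sees the
// substage states), while the PID law is a sampled (zero-order-held)
// discrete realization updated once per step. Matched sinusoidal
// disturbances enter through the input channel.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Plant {
  double A[3][3];
  double B[3];
  double C[3];
};

inline double sgn(double s, double zero) {
  if (s > 0.0) return 1.0;
  if (s < 0.0) return -1.0;
  return zero;
}

// control law for state-dependent controllers (none / state feedback / SMC)
inline double control(int ctrl, const double* cpar, const double* x,
                      double sign_zero) {
  switch (ctrl) {
  case 0:
    return 0.0;
  case 2:  // u = -K x
    return -(cpar[0] * x[0] + cpar[1] * x[1] + cpar[2] * x[2]);
  case 3: {  // u = ueq + udisc
    const double s = cpar[0] * x[0] + cpar[1] * x[1] + cpar[2] * x[2];
    const double ueq =
        -(cpar[5] * x[0] + cpar[6] * x[1] + cpar[7] * x[2]) / cpar[8];
    return ueq - cpar[3] * s - cpar[4] * sgn(s, sign_zero);
  }
  default:
    return 0.0;
  }
}

inline void deriv(const Plant& p, const double* x, double u, double d,
                  double* dx) {
  const double v = u + d;
  for (int i = 0; i < 3; ++i) {
    dx[i] = p.A[i][0] * x[0] + p.A[i][1] * x[1] + p.A[i][2] * x[2] +
            p.B[i] * v;
  }
}

}  // namespace

// ctrl: 0 = none, 1 = PID (cpar = kp, ki, kd), 2 = state feedback
// (cpar = K1..K3), 3 = SMC (cpar = c1..c3, k1, k2, a1..a3, b).
// integrator: 0 = RK4, 1 = Euler, 2 = discrete step x+ = A x + B u.
// Returns (nsteps + 1) x 5: time, output y, control u, sliding s, disturbance.
// [[Rcpp::export]]
NumericMatrix cl_loop_cpp(NumericMatrix A, NumericVector B, NumericVector C,
                          NumericVector x0, int ctrl, NumericVector cpar,
                          double dt, int nsteps, int integrator,
                          double dist_amp, double dist_omega,
                          double dist_phase, double sign_zero) {
  Plant p;
  for (int i = 0; i < 3; ++i) {
    p.B[i] = B[i];
    p.C[i] = C[i];
    for (int j = 0; j < 3; ++j) p.A[i][j] = A(i, j);
  }
  std::vector<double> cp(cpar.begin(), cpar.end());
  cp.resize(9, 0.0);

  double x[3] = {x0[0], x0[1], x0[2]};
  // PID internal state
  double integ = 0.0, eprev = 0.0;
  bool init = false;

  NumericMatrix out(nsteps + 1, 5);
  const bool smc = (ctrl == 3);

  for (int k = 0; k <= nsteps; ++k) {
    const double t = k * dt;
    const double d =
        dist_amp == 0.0 ? 0.0 : dist_amp * std::sin(dist_omega * t + dist_phase);
    const double y = p.C[0] * x[0] + p.C[1] * x[1] + p.C[2] * x[2];

    double u;
    if (ctrl == 1) {
      const double e = -y;  // error = reference - output, in deviation form
      integ += dt * (eprev + e) / 2.0;
      const double dterm = init ? (e - eprev) / dt : 0.0;
      u = cp[0] * e + cp[1] * integ + cp[2] * dterm;
      eprev = e;
      init = true;
    } else {
      u = control(ctrl, cp.data(), x, sign_zero);
    }

    out(k, 0) = t;
    out(k, 1) = y;
    out(k, 2) = u;
    out(k, 3) = smc ? cp[0] * x[0] + cp[1] * x[1] + cp[2] * x[2] : NA_REAL;
    out(k, 4) = d;

    if (!std::isfinite(y) || !std::isfinite(u) || !std::isfinite(x[0]) ||
        !std::isfinite(x[1]) || !std::isfinite(x[2])) {
      stop("closed-loop state diverged (non-finite) at t = %.6g s", t);
    }
    if (k == nsteps) break;

    if (integrator == 2) {  // discrete plant step
      double xn[3];
      const double v = u + d;
      for (int i = 0; i < 3; ++i)
        xn[i] = p.A[i][0] * x[0] + p.A[i][1] * x[1] + p.A[i][2] * x[2] +
                p.B[i] * v;
      x[0] = xn[0]; x[1] = xn[1]; x[2] = xn[2];
      continue;
    }

    if (integrator == 1) {  // Euler
      double dx[3];
      deriv(p, x, u, d, dx);
      for (int i = 0; i < 3; ++i) x[i] += dt * dx[i];
      continue;
    }

    // RK4; state-dependent controllers re-evaluated at substages, PID held
    double k1[3], k2[3], k3[3], k4[3], xs[3];
    const double dmid =
        dist_amp == 0.0
            ? 0.0
            : dist_amp * std::sin(dist_omega * (t + dt / 2.0) + dist_phase);
    const double dend =
        dist_amp == 0.0
            ? 0.0
            : dist_amp * std::sin(dist_omega * (t + dt) + dist_phase);

    deriv(p, x, u, d, k1);
    for (int i = 0; i < 3; ++i) xs[i] = x[i] + dt / 2.0 * k1[i];
    double us = (ctrl == 1) ? u : control(ctrl, cp.data(), xs, sign_zero);
    deriv(p, xs, us, dmid, k2);
    for (int i = 0; i < 3; ++i) xs[i] = x[i] + dt / 2.0 * k2[i];
    us = (ctrl == 1) ? u : control(ctrl, cp.data(), xs, sign_zero);
    deriv(p, xs, us, dmid, k3);
    for (int i = 0; i < 3; ++i) xs[i] = x[i] + dt * k3[i];
    us = (ctrl == 1) ? u : control(ctrl, cp.data(), xs, sign_zero);
    deriv(p, xs, us, dend, k4);
    for (int i = 0; i < 3; ++i)
      x[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
  }

  return out;
}
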