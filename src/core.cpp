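// Fixed-step RK4 integrators for the muscle--load system and its
// Pontryagin (state + costate) extension with sigmoid-smoothed bang-bang
// control. Step sizes are chosen by the R callers so that the RHS is smooth
// within every step (stimulus grids are zero-order-hold aligned).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Pars {
  double A1, B1, C1, D1, l01, tc1, ta1, g1, lo1, hi1;
  double A2, B2, C2, D2, l02, tc2, ta2, g2, lo2, hi2;
  double M, b, k;
};

static Pars unpack(const NumericVector& p) {
  if (p.size() != 23) stop("parameter vector must have length 23");
  Pars q;
  q.A1 = p[0];  q.B1 = p[1];  q.C1 = p[2];  q.D1 = p[3];  q.l01 = p[4];
  q.tc1 = p[5]; q.ta1 = p[6]; q.g1 = p[7];  q.lo1 = p[8]; q.hi1 = p[9];
  q.A2 = p[10]; q.B2 = p[11]; q.C2 = p[12]; q.D2 = p[13]; q.l02 = p[14];
  q.tc2 = p[15]; q.ta2 = p[16]; q.g2 = p[17]; q.lo2 = p[18]; q.hi2 = p[19];
  q.M = p[20];  q.b = p[21];  q.k = p[22];
  return q;
}

// contractile forces in local muscle coordinates (l1 = l01 - x, l2 = l02 + x)
static inline void forces(const Pars& p, double x, double a1, double a2,
                          double& F1, double& F2) {
  const double l1 = p.l01 - x, l2 = p.l02 + x;
  F1 = p.A1 + p.B1 * l1 + (p.C1 + p.D1 * l1) * a1;
  F2 = p.A2 + p.B2 * l2 + (p.C2 + p.D2 * l2) * a2;
}

// six-state RHS (x, v, a1, c1, a2, c2) under given controls; returns net force
static inline double state_rhs(const Pars& p, const double* z,
                               double u1, double u2, double* dz) {
  double F1, F2;
  forces(p, z[0], z[2], z[4], F1, F2);
  const double Fnet = F1 - F2;
  dz[0] = z[1];
  dz[1] = (Fnet - p.k * z[0] - p.b * z[1]) / p.M;
  dz[2] = (z[3] - z[2]) / p.ta1;
  dz[3] = (p.g1 * u1 - z[3]) / p.tc1;
  dz[4] = (z[5] - z[4]) / p.ta2;
  dz[5] = (p.g2 * u2 - z[5]) / p.tc2;
  return Fnet;
}

// smoothed bang-bang control from the switching function s = lambda_c * g/tc;
// u -> hi as beta*s -> -Inf, u -> lo as beta*s -> +Inf, ties (s = 0) give the
// interval midpoint which collapses to lo in the exact (beta -> Inf) law.
static inline double smooth_u(double s, double beta, double lo, double hi) {
  const double e = std::exp(beta * s);
  return lo + (hi - lo) / (1.0 + e);
}

// Pontryagin RHS: z = (x,v,a1,c1,a2,c2, lx,lv,la1,lc1,la2,lc2, W)
// Running cost L = -Fnet*v (power maximisation); W accumulates +Fnet*v.
static void pmp_rhs(const Pars& p, const double* z, double beta, double* dz) {
  const double x = z[0], v = z[1], a1 = z[2], a2 = z[4];
  const double lx = z[6], lv = z[7], la1 = z[8], lc1 = z[9],
               la2 = z[10], lc2 = z[11];
  const double s1 = lc1 * p.g1 / p.tc1;
  const double s2 = lc2 * p.g2 / p.tc2;
  const double u1 = smooth_u(s1, beta, p.lo1, p.hi1);
  const double u2 = smooth_u(s2, beta, p.lo2, p.hi2);
  const double Fnet = state_rhs(p, z, u1, u2, dz);
  const double l1 = p.l01 - x, l2 = p.l02 + x;
  const double K = p.B1 + p.D1 * a1 + p.B2 + p.D2 * a2;
  const double G1 = p.C1 + p.D1 * l1;
  const double G2 = p.C2 + p.D2 * l2;
  dz[6]  = -K * v + lv * (K + p.k) / p.M;
  dz[7]  = Fnet - lx + lv * p.b / p.M;
  dz[8]  = G1 * v - lv * G1 / p.M + la1 / p.ta1;
  dz[9]  = -la1 / p.ta1 + lc1 / p.tc1;
  dz[10] = -G2 * v + lv * G2 / p.M + la2 / p.ta2;
  dz[11] = -la2 / p.ta2 + lc2 / p.tc2;
  dz[12] = Fnet * v;
}

static inline void rk4_step_pmp(const Pars& p, double* z, double h,
                                double beta, double* k1, double* k2,
                                double* k3, double* k4, double* tmp) {
  const int n = 13;
  pmp_rhs(p, z, beta, k1);
  for (int i = 0; i < n; ++i) tmp[i] = z[i] + 0.5 * h * k1[i];
  pmp_rhs(p, tmp, beta, k2);
  for (int i = 0; i < n; ++i) tmp[i] = z[i] + 0.5 * h * k2[i];
  pmp_rhs(p, tmp, beta, k3);
  for (int i = 0; i < n; ++i) tmp[i] = z[i] + h * k3[i];
  pmp_rhs(p, tmp, beta, k4);
  for (int i = 0; i < n; ++i)
    z[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

// [[Rcpp::export]]
NumericVector ml_flow(NumericVector pars, NumericVector z0, double T,
                      int nsteps, double beta) {
  const Pars p = unpack(pars);
  if (z0.size() != 12) stop("z0 must have length 12");
  double z[13], k1[13], k2[13], k3[13], k4[13], tmp[13];
  for (int i = 0; i < 12; ++i) z[i] = z0[i];
  z[12] = 0.0;
  const double h = T / nsteps;
  for (int s = 0; s < nsteps; ++s) rk4_step_pmp(p, z, h, beta, k1, k2, k3, k4, tmp);
  NumericVector out(13);
  for (int i = 0; i < 13; ++i) out[i] = z[i];
  return out;
}

// [[Rcpp::export]]
NumericMatrix ml_flow_traj(NumericVector pars, NumericVector z0, double T,
                           int nsteps, double beta, int thin) {
  const Pars p = unpack(pars);
  if (z0.size() != 12) stop("z0 must have length 12");
  if (thin < 1) thin = 1;
  const int nrec = nsteps / thin + 1;
  NumericMatrix out(nrec, 14);
  double z[13], k1[13], k2[13], k3[13], k4[13], tmp[13];
  for (int i = 0; i < 12; ++i) z[i] = z0[i];
  z[12] = 0.0;
  const double h = T / nsteps;
  int r = 0;
  for (int s = 0; s <= nsteps; ++s) {
    if (s % thin == 0) {
      out(r, 0) = s * h;
      for (int i = 0; i < 13; ++i) out(r, i + 1) = z[i];
      ++r;
    }
    if (s < nsteps) rk4_step_pmp(p, z, h, beta, k1, k2, k3, k4, tmp);
  }
  return out;
}

// Shooting map z(T) and its Jacobian wrt z0 by central differences.
// [[Rcpp::export]]
List ml_shoot(NumericVector pars, NumericVector z0, double T, int nsteps,
              double beta, bool jac, double rel_h) {
  NumericVector zT = ml_flow(pars, z0, T, nsteps, beta);
  if (!jac) return List::create(_["zT"] = zT);
  NumericMatrix J(12, 12);
  NumericVector zp(12), zm(12);
  for (int j = 0; j < 12; ++j) {
    const double hj = rel_h * std::max(std::abs(z0[j]), 1e-4);
    for (int i = 0; i < 12; ++i) { zp[i] = z0[i]; zm[i] = z0[i]; }
    zp[j] += hj; zm[j] -= hj;
    NumericVector fp = ml_flow(pars, zp, T, nsteps, beta);
    NumericVector fm = ml_flow(pars, zm, T, nsteps, beta);
    for (int i = 0; i < 12; ++i) J(i, j) = (fp[i] - fm[i]) / (2.0 * hj);
  }
  return List::create(_["zT"] = zT, _["J"] = J);
}

static inline double lookup_u(const NumericVector& u, double t, double u_dt,
                              bool linear) {
  const int n = u.size();
  double idx = t / u_dt;
  if (idx <= 0) return u[0];
  if (linear) {
    if (idx >= n - 1) return u[n - 1];
    const int i0 = (int)std::floor(idx);
    const double w = idx - i0;
    return (1.0 - w) * u[i0] + w * u[i0 + 1];
  }
  int i0 = (int)std::floor(idx + 1e-9);
  if (i0 > n - 1) i0 = n - 1;
  return u[i0];
}

// Forward simulation of the six-state system under sampled controls.
// Controls are sampled on a uniform grid of spacing u_dt starting at t = 0;
// interp = 0 for zero-order hold, 1 for linear interpolation.
// [[Rcpp::export]]
NumericMatrix ml_sim_states(NumericVector pars, NumericVector z0, double dt,
                            int nsteps, NumericVector u1, NumericVector u2,
                            double u_dt, int interp, int thin,
                            double state_guard) {
  const Pars p = unpack(pars);
  if (z0.size() != 6) stop("z0 must have length 6");
  if (thin < 1) thin = 1;
  const bool lin = interp == 1;
  const int nrec = nsteps / thin + 1;
  // columns: t, x, v, a1, c1, a2, c2, u1, u2, F1, F2, W
  NumericMatrix out(nrec, 12);
  double z[6], k1[6], k2[6], k3[6], k4[6], tmp[6];
  for (int i = 0; i < 6; ++i) z[i] = z0[i];
  double W = 0.0;
  int r = 0;
  for (int s = 0; s <= nsteps; ++s) {
    const double t = s * dt;
    const double cu1 = lookup_u(u1, t, u_dt, lin);
    const double cu2 = lookup_u(u2, t, u_dt, lin);
    if (s % thin == 0) {
      double F1, F2;
      forces(p, z[0], z[2], z[4], F1, F2);
      out(r, 0) = t;
      for (int i = 0; i < 6; ++i) out(r, i + 1) = z[i];
      out(r, 7) = cu1; out(r, 8) = cu2;
      out(r, 9) = F1; out(r, 10) = F2; out(r, 11) = W;
      ++r;
    }
    if (s == nsteps) break;
    // RK4 stage controls: in hold mode the sample at the step start applies
    // to the whole step (the RHS is then smooth within the step); in linear
    // mode stages interpolate.
    const double tm = t + 0.5 * dt, te = t + dt;
    const double u1m = lin ? lookup_u(u1, tm, u_dt, true) : cu1;
    const double u2m = lin ? lookup_u(u2, tm, u_dt, true) : cu2;
    const double u1e = lin ? lookup_u(u1, te, u_dt, true) : cu1;
    const double u2e = lin ? lookup_u(u2, te, u_dt, true) : cu2;
    double Fn = state_rhs(p, z, cu1, cu2, k1);
    double dW1 = Fn * z[1];
    for (int i = 0; i < 6; ++i) tmp[i] = z[i] + 0.5 * dt * k1[i];
    Fn = state_rhs(p, tmp, u1m, u2m, k2);
    double dW2 = Fn * tmp[1];
    for (int i = 0; i < 6; ++i) tmp[i] = z[i] + 0.5 * dt * k2[i];
    Fn = state_rhs(p, tmp, u1m, u2m, k3);
    double dW3 = Fn * tmp[1];
    for (int i = 0; i < 6; ++i) tmp[i] = z[i] + dt * k3[i];
    Fn = state_rhs(p, tmp, u1e, u2e, k4);
    double dW4 = Fn * tmp[1];
    for (int i = 0; i < 6; ++i)
      z[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    W += dt / 6.0 * (dW1 + 2.0 * dW2 + 2.0 * dW3 + dW4);
    if (std::abs(z[0]) > state_guard || !std::isfinite(z[0]))
      stop("state magnitude exceeded guard (%g m) at t = %g s: integration aborted",
           state_guard, t);
  }
  return out;
}

// Backward costate integration along a stored state trajectory. The costate
// RHS -dH/dz depends only on states and costates (the control enters H
// linearly through rows whose state-gradient is control-free), so no control
// trace is needed. states: (nsteps+1) x 6 matrix on a uniform grid of
// spacing dt. Integrates lambda from t = nsteps*dt down to 0 (RK4 with
// midpoint states averaged between nodes). Returns the full costate grid.
// [[Rcpp::export]]
NumericMatrix ml_costate_back(NumericVector pars, NumericMatrix states,
                              double dt, NumericVector lamT) {
  const Pars p = unpack(pars);
  const int n = states.nrow() - 1;
  if (lamT.size() != 6) stop("lamT must have length 6");
  NumericMatrix lam(n + 1, 6);
  double L[6], k1[6], k2[6], k3[6], k4[6], tmp[6];
  for (int i = 0; i < 6; ++i) { L[i] = lamT[i]; lam(n, i) = lamT[i]; }
  double zfull[13], dz[13];
  auto co_rhs = [&](const double* zs, const double* lamv, double* dl) {
    for (int i = 0; i < 6; ++i) zfull[i] = zs[i];
    for (int i = 0; i < 6; ++i) zfull[6 + i] = lamv[i];
    zfull[12] = 0.0;
    pmp_rhs(p, zfull, 0.0, dz);
    for (int i = 0; i < 6; ++i) dl[i] = dz[6 + i];
  };
  double zs0[6], zsm[6], zs1[6];
  for (int s = n; s > 0; --s) {
    for (int i = 0; i < 6; ++i) {
      zs0[i] = states(s, i);
      zs1[i] = states(s - 1, i);
      zsm[i] = 0.5 * (zs0[i] + zs1[i]);
    }
    const double h = -dt;
    co_rhs(zs0, L, k1);
    for (int i = 0; i < 6; ++i) tmp[i] = L[i] + 0.5 * h * k1[i];
    co_rhs(zsm, tmp, k2);
    for (int i = 0; i < 6; ++i) tmp[i] = L[i] + 0.5 * h * k2[i];
    co_rhs(zsm, tmp, k3);
    for (int i = 0; i < 6; ++i) tmp[i] = L[i] + h * k3[i];
    co_rhs(zs1, tmp, k4);
    for (int i = 0; i < 6; ++i)
      L[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    for (int i = 0; i < 6; ++i) lam(s - 1, i) = L[i];
  }
  return lam;
}
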