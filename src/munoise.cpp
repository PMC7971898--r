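// Core integrators for the motor-unit model: the calcium-kinetics /
// cross-bridge activation cascade of single units and the coupled
// population + musculotendon simulation. Fixed-step RK4 throughout; the
// spike release kernel R(t) is maintained through two exponential states
// (algebraically identical to the per-spike sum, O(1) per step).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Hill-type curve primitives (fiber-type constants supplied by R)
// ---------------------------------------------------------------------------

static inline double fl_one(double Lce, double beta, double omega, double rho) {
  return std::exp(-std::pow(std::fabs((std::pow(Lce, beta) - 1.0) / omega), rho));
}

// Shortening branch for Vce <= 0, lengthening branch for Vce > 0.
static inline double fv_one(double Lce, double Vce, double vmax, double cv0,
                            double cv1, double av0, double av1, double av2,
                            double bv) {
  if (Vce <= 0.0) {
    return (vmax - Vce) / (vmax + (cv0 + cv1 * Lce) * Vce);
  }
  return (bv - (av0 + av1 * Lce + av2 * Lce * Lce) * Vce) / (bv + Vce);
}

static inline double fse_one(double Lse, double cT, double kT, double LrT) {
  return cT * kT * std::log(1.0 + std::exp((Lse - LrT) / kT));
}

static inline double fpe1_one(double Lce, double Vce, double c1, double k1,
                              double Lr1, double Lmax, double eta) {
  return c1 * k1 * std::log(1.0 + std::exp((Lce / Lmax - Lr1) / k1)) + eta * Vce;
}

static inline double fpe2_one(double Lce, double c2, double k2, double Lr2) {
  double v = c2 * (std::exp(k2 * (Lce - Lr2)) - 1.0);
  return v < 0.0 ? v : 0.0;
}

// [[Rcpp::export]]
NumericVector fl_cpp(NumericVector Lce, double beta, double omega, double rho) {
  int n = Lce.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = fl_one(Lce[i], beta, omega, rho);
  return out;
}

// [[Rcpp::export]]
NumericVector fv_cpp(NumericVector Lce, NumericVector Vce, double vmax,
                     double cv0, double cv1, double av0, double av1,
                     double av2, double bv) {
  int n = Lce.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = fv_one(Lce[i], Vce[i], vmax, cv0, cv1, av0, av1, av2, bv);
  return out;
}

// [[Rcpp::export]]
NumericVector fse_cpp(NumericVector Lse, double cT, double kT, double LrT) {
  int n = Lse.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = fse_one(Lse[i], cT, kT, LrT);
  return out;
}

// [[Rcpp::export]]
NumericVector fpe1_cpp(NumericVector Lce, NumericVector Vce, double c1,
                       double k1, double Lr1, double Lmax, double eta) {
  int n = Lce.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = fpe1_one(Lce[i], Vce[i], c1, k1, Lr1, Lmax, eta);
  return out;
}

// [[Rcpp::export]]
NumericVector fpe2_cpp(NumericVector Lce, double c2, double k2, double Lr2) {
  int n = Lce.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = fpe2_one(Lce[i], c2, k2, Lr2);
  return out;
}

// ---------------------------------------------------------------------------
// Activation dynamics
// ---------------------------------------------------------------------------

// Parameter vector layout (see R/constants.R): alphaS, alphaC, k1, k2, k3,
// k4i, gamma, N, K, tau1, tau2, tau3, phi_short, phi_long, fiber(0 slow/1 fast)
struct UnitPar {
  double alphaS, alphaC, k1, k2, k3, k4i, gamma, N, K, tau1, tau2, tau3;
  double phiS, phiL;
  int fiber;
  double Kn0;  // cached pow(K, N) for the unscaled case
};

static UnitPar unpack_par(const double *p) {
  UnitPar u;
  u.alphaS = p[0]; u.alphaC = p[1]; u.k1 = p[2]; u.k2 = p[3]; u.k3 = p[4];
  u.k4i = p[5]; u.gamma = p[6]; u.N = p[7]; u.K = p[8]; u.tau1 = p[9];
  u.tau2 = p[10]; u.tau3 = p[11]; u.phiS = p[12]; u.phiL = p[13];
  u.fiber = (int)p[14];
  u.Kn0 = std::pow(u.K, u.N);
  return u;
}

// Length scaling x = phi * x0 * (1 - Lce) + x0 applied to k3, N, K, gamma.
// Scaled values floored at 1e-6 (the affine form can cross zero).
static inline double lscale(double x0, double phi, double Lce) {
  double x = phi * x0 * (1.0 - Lce) + x0;
  return x > 1e-6 ? x : 1e-6;
}

struct ScaledPar {
  double k3, N, K, gamma, Kn;
};

static inline ScaledPar scale_par(const UnitPar &u, double Lce) {
  ScaledPar s;
  double phi = (Lce < 1.0) ? u.phiS : u.phiL;
  if (phi == 0.0 || Lce == 1.0) {
    s.k3 = u.k3; s.N = u.N; s.K = u.K; s.gamma = u.gamma;
    s.Kn = u.Kn0;
  } else {
    s.k3 = lscale(u.k3, phi, Lce);
    s.N = lscale(u.N, phi, Lce);
    s.K = lscale(u.K, phi, Lce);
    s.gamma = lscale(u.gamma, phi, Lce);
    s.Kn = std::pow(s.K, s.N);
  }
  return s;
}

// Time derivatives of one unit's state (c, cf, S, Y, A).
// sag_target: value a_S currently tracks (aS1 below the rate switch, aS2
// above); sag_dyn = false holds S fixed (twitch references).
static inline void unit_derivs(const UnitPar &u, const ScaledPar &sp,
                               double c, double cf, double S, double Y,
                               double A, double Rval, bool sag_dyn,
                               double sag_target, double TS, double absVce,
                               double cY, double VY, double TY, double &dc,
                               double &dcf, double &dS, double &dY,
                               double &dA) {
  const double C = u.alphaC;          // total calcium (F = 1)
  const double Ss = u.alphaS * C;     // total SR binding sites
  double k4 = u.k4i * (1.0 + sp.gamma * A);
  double bind = (sp.k3 * c - k4 * cf) * (1.0 - cf);
  dc = u.k1 * (C - c - cf) * Rval - u.k2 * c * (Ss - C + c + cf) - bind;
  dcf = bind;
  dS = (u.fiber == 1 && sag_dyn) ? (sag_target - S) / TS : 0.0;
  dY = (u.fiber == 0)
           ? (1.0 - cY * (1.0 - std::exp(-absVce / VY)) - Y) / TY
           : 0.0;
  double x = cf;
  if (u.fiber == 1) x *= S;
  if (u.fiber == 0) x *= Y;
  if (x < 0.0) x = 0.0;
  double xn = std::pow(x, sp.N);
  double Atilde = xn / (xn + sp.Kn);
  dA = (Atilde - A) / u.tau3;
}

// Simulate one isolated unit driven by a given spike train at fixed Lce,
// Vce = 0. Returns the activation and bound-myofilament traces.
//
// sag_mode: 0 = hold S at aS2 (non-potentiated twitch reference),
//           1 = dynamic sag toward aS2 from S(0) = aS1 (sustained trains),
//           2 = dynamic sag toward aS1 (discharge below 0.1 * f0.5).
// [[Rcpp::export]]
List simulate_unit_cpp(NumericVector spike_times, NumericVector par,
                       double dt, double duration, double Lce, int sag_mode,
                       double aS1, double aS2, double TS, double cY,
                       double VY, double TY) {
  UnitPar u = unpack_par(REAL(par));
  ScaledPar sp = scale_par(u, Lce);

  int nt = (int)std::round(duration / dt);
  NumericVector A_out(nt + 1), cf_out(nt + 1);

  double c = 0.0, cf = 0.0, A = 0.0, Y = 1.0;
  bool sag_dyn = sag_mode != 0;
  double sag_target = (sag_mode == 2) ? aS1 : aS2;
  double S = sag_dyn ? aS1 : aS2;

  // Release kernel R(t) = E2 - E12 with decay rates 1/tau2 and 1/tau1+1/tau2.
  double E2 = 0.0, E12 = 0.0;
  const double r2 = 1.0 / u.tau2, r12 = 1.0 / u.tau1 + 1.0 / u.tau2;
  const double d2_full = std::exp(-dt * r2), d12_full = std::exp(-dt * r12);
  const double d2_half = std::exp(-0.5 * dt * r2),
               d12_half = std::exp(-0.5 * dt * r12);

  int si = 0, ns = spike_times.size();
  A_out[0] = 0.0; cf_out[0] = 0.0;

  for (int k = 0; k < nt; ++k) {
    double t = k * dt;
    // Incorporate spikes that fell in [t, t + dt) at the start of the step.
    while (si < ns && spike_times[si] < t + dt) {
      E2 += 1.0; E12 += 1.0;
      ++si;
    }
    double R0 = E2 - E12;
    double Rh = E2 * d2_half - E12 * d12_half;
    double R1 = E2 * d2_full - E12 * d12_full;

    double k1c, k1f, k1S, k1Y, k1A, k2c, k2f, k2S, k2Y, k2A;
    double k3c, k3f, k3S, k3Y, k3A, k4c, k4f, k4S, k4Y, k4A;
    unit_derivs(u, sp, c, cf, S, Y, A, R0, sag_dyn, sag_target, TS, 0.0, cY,
                VY, TY, k1c, k1f, k1S, k1Y, k1A);
    unit_derivs(u, sp, c + 0.5 * dt * k1c, cf + 0.5 * dt * k1f,
                S + 0.5 * dt * k1S, Y + 0.5 * dt * k1Y, A + 0.5 * dt * k1A,
                Rh, sag_dyn, sag_target, TS, 0.0, cY, VY, TY, k2c, k2f, k2S,
                k2Y, k2A);
    unit_derivs(u, sp, c + 0.5 * dt * k2c, cf + 0.5 * dt * k2f,
                S + 0.5 * dt * k2S, Y + 0.5 * dt * k2Y, A + 0.5 * dt * k2A,
                Rh, sag_dyn, sag_target, TS, 0.0, cY, VY, TY, k3c, k3f, k3S,
                k3Y, k3A);
    unit_derivs(u, sp, c + dt * k3c, cf + dt * k3f, S + dt * k3S,
                Y + dt * k3Y, A + dt * k3A, R1, sag_dyn, sag_target, TS, 0.0,
                cY, VY, TY, k4c, k4f, k4S, k4Y, k4A);

    c += dt / 6.0 * (k1c + 2 * k2c + 2 * k3c + k4c);
    cf += dt / 6.0 * (k1f + 2 * k2f + 2 * k3f + k4f);
    S += dt / 6.0 * (k1S + 2 * k2S + 2 * k3S + k4S);
    Y += dt / 6.0 * (k1Y + 2 * k2Y + 2 * k3Y + k4Y);
    A += dt / 6.0 * (k1A + 2 * k2A + 2 * k3A + k4A);
    if (cf < 0.0) cf = 0.0;
    if (cf > 1.0) cf = 1.0;
    if (c < 0.0) c = 0.0;

    E2 *= d2_full; E12 *= d12_full;

    if (!std::isfinite(c) || !std::isfinite(cf) || !std::isfinite(A))
      stop("activation integration became unstable (dt = %f)", dt);

    A_out[k + 1] = A;
    cf_out[k + 1] = cf;
  }
  return List::create(_["A"] = A_out, _["cf"] = cf_out);
}

// ---------------------------------------------------------------------------
// Population simulation: spikes -> activation -> musculotendon force
// ---------------------------------------------------------------------------

// Discharge rate of one unit given precomputed rate-coding constants.
// scheme: 0 = linear (Eq 2-3 form), 1 = bilinear low-threshold form.
static inline double dr_one(double ueff, double RT, double MDR, double PDR,
                            int scheme, double ge, double lamke, double ke,
                            double Ut) {
  if (ueff < RT) return 0.0;
  double dr;
  if (scheme == 1) {
    dr = (ueff <= Ut) ? lamke * (ueff - RT) + MDR : PDR - ke * (1.0 - ueff);
  } else {
    dr = ge * (ueff - RT) + MDR;
  }
  if (dr > PDR) dr = PDR;
  if (dr < 0.0) dr = 0.0;
  return dr;
}

static inline double draw_truncnorm() {
  double z;
  do { z = norm_rand(); } while (std::fabs(z) > 3.9);
  return z;
}

// Full trial simulation of a motor-unit pool, optionally coupled to the
// musculotendon mechanics (use_see). U_eff is sampled on the dt grid.
//
// pars: n x 15 activation-parameter matrix (columns as in simulate_unit_cpp)
// rc:   n x 9 rate-coding matrix: RT, MDR, PDR, f05, scheme, ge, lamke, ke, Ut
// PT:   peak tetanic forces (N)
// cv_mode: 0 constant cv (cv_const, %ISI), 1 input-dependent law
// mech: named list of muscle constants (SI units) + curve constants
// keep_units: 1-based indices of units whose force traces are returned
// [[Rcpp::export]]
List simulate_trial_cpp(NumericVector ueff, double dt, NumericMatrix pars,
                        NumericMatrix rc, NumericVector PT, int cv_mode,
                        double cv_const, bool use_see, List mech,
                        double Lce_init, IntegerVector keep_units,
                        int out_every, double aS1, double aS2, double TS,
                        double cY, double VY, double TY, int mech_substeps) {
  const int n = pars.nrow();
  const int nt = ueff.size();

  std::vector<UnitPar> U(n);
  for (int i = 0; i < n; ++i) {
    NumericVector row = pars(i, _);
    U[i] = unpack_par(REAL(row));
  }

  // muscle constants
  const double F0 = as<double>(mech["F0"]);
  const double Mm = as<double>(mech["Mm_kg"]);
  const double Lce0 = as<double>(mech["Lce0_m"]);
  const double Lse0 = as<double>(mech["Lse0_m"]);
  const double ca = std::cos(as<double>(mech["alpha_rad"]));
  const double ta2 = std::pow(std::tan(as<double>(mech["alpha_rad"])), 2.0);
  const double Lmt = as<double>(mech["Lmt_m"]);
  const double cT = as<double>(mech["se_c"]), kT = as<double>(mech["se_k"]),
               LrT = as<double>(mech["se_Lr"]);
  const double p1c = as<double>(mech["pe1_c"]), p1k = as<double>(mech["pe1_k"]),
               p1Lr = as<double>(mech["pe1_Lr"]),
               p1Lmax = as<double>(mech["pe1_Lmax"]),
               p1eta = as<double>(mech["pe1_eta"]);
  const double p2c = as<double>(mech["pe2_c"]), p2k = as<double>(mech["pe2_k"]),
               p2Lr = as<double>(mech["pe2_Lr"]);
  NumericVector flc_s = mech["fl_slow"], flc_f = mech["fl_fast"];
  NumericVector fvc_s = mech["fv_slow"], fvc_f = mech["fv_fast"];

  // unit state arrays
  std::vector<double> c(n, 0.0), cf(n, 0.0), S(n, aS1), Y(n, 1.0), A(n, 0.0);
  std::vector<double> E2(n, 0.0), E12(n, 0.0);
  std::vector<double> next_spike(n, 0.0);
  std::vector<int> active(n, 0);
  std::vector<long> nspike(n, 0);

  std::vector<double> d2f(n), d12f(n), d2h(n), d12h(n);
  for (int i = 0; i < n; ++i) {
    double r2 = 1.0 / U[i].tau2, r12 = 1.0 / U[i].tau1 + 1.0 / U[i].tau2;
    d2f[i] = std::exp(-dt * r2); d12f[i] = std::exp(-dt * r12);
    d2h[i] = std::exp(-0.5 * dt * r2); d12h[i] = std::exp(-0.5 * dt * r12);
  }

  double Lce = use_see ? Lce_init : 1.0, Vce = 0.0;

  const int nkeep = keep_units.size();
  const int nout = nt / out_every + ((nt % out_every) ? 1 : 0);
  NumericVector t_out(nout), F_out(nout), Lce_out(nout), Vce_out(nout),
      Fce_out(nout);
  NumericVector spikes_out(nout);  // pool spike count per output bin
  NumericMatrix unitF_out(nout, nkeep);
  int oi = 0;
  double spike_accum = 0.0;

  // scratch for RK4 stage derivatives
  std::vector<double> kc(4 * n), kf(4 * n), kS(4 * n), kY(4 * n), kA(4 * n);
  std::vector<double> sag_target(n, aS2);
  std::vector<int> sag_dyn(n, 1);

  for (int k = 0; k <= nt - 1; ++k) {
    double t = k * dt;
    double ue = ueff[k];

    // --- spike generation (renewal process, event times quantized to dt) ---
    for (int i = 0; i < n; ++i) {
      double RT = rc(i, 0);
      if (!active[i]) {
        if (ue >= RT) {  // recruitment: first spike at threshold crossing
          active[i] = 1;
          next_spike[i] = t;
        }
      } else if (ue < RT) {
        active[i] = 0;  // de-recruitment, pending spike cancelled
      }
      if (active[i]) {
        while (next_spike[i] < t + dt) {
          E2[i] += 1.0; E12[i] += 1.0;
          ++nspike[i];
          spike_accum += 1.0;
          double dr = dr_one(ue, RT, rc(i, 1), rc(i, 2), (int)rc(i, 4),
                             rc(i, 5), rc(i, 6), rc(i, 7), rc(i, 8));
          if (dr <= 0.0) { active[i] = 0; break; }
          double mu = 1.0 / dr;
          double cv = (cv_mode == 1)
                          ? 10.0 + 20.0 * std::exp(-(ue - RT) * 100.0 / 2.5)
                          : cv_const;
          double isi;
          do { isi = mu * (1.0 + cv * draw_truncnorm() / 100.0); } while (isi <= 0.0);
          next_spike[i] += isi;
        }
      }
      // sag drive: discharge rate relative to f0.5 (0 while silent)
      double dr_now = active[i]
                          ? dr_one(ue, RT, rc(i, 1), rc(i, 2), (int)rc(i, 4),
                                   rc(i, 5), rc(i, 6), rc(i, 7), rc(i, 8))
                          : 0.0;
      sag_target[i] = (dr_now / rc(i, 3) < 0.1) ? aS1 : aS2;
    }

    // --- RK4 step of the unit states (muscle state held over the step) ---
    double absV = use_see ? std::fabs(Vce) : 0.0;
    double Ws0 = 0.0, Wf0 = 0.0;   // activation-weighted tetanic force sums
    for (int i = 0; i < n; ++i)
      (U[i].fiber == 1 ? Wf0 : Ws0) += PT[i] * A[i];
    for (int stage = 0; stage < 4; ++stage) {
      double h = (stage == 0) ? 0.0 : (stage == 3 ? dt : 0.5 * dt);
      for (int i = 0; i < n; ++i) {
        double sc = c[i], scf = cf[i], sS = S[i], sY = Y[i], sA = A[i];
        if (stage > 0) {
          int pr = (stage - 1) * n + i;
          sc += h * kc[pr]; scf += h * kf[pr]; sS += h * kS[pr];
          sY += h * kY[pr]; sA += h * kA[pr];
        }
        double Rv;
        if (stage == 0) Rv = E2[i] - E12[i];
        else if (stage == 3) Rv = E2[i] * d2f[i] - E12[i] * d12f[i];
        else Rv = E2[i] * d2h[i] - E12[i] * d12h[i];

        ScaledPar sp = scale_par(U[i], Lce);
        int ix = stage * n + i;
        unit_derivs(U[i], sp, sc, scf, sS, sY, sA, Rv, sag_dyn[i],
                    sag_target[i], TS, absV, cY, VY, TY, kc[ix], kf[ix],
                    kS[ix], kY[ix], kA[ix]);
      }
    }
    for (int i = 0; i < n; ++i) {
      c[i] += dt / 6.0 * (kc[i] + 2 * kc[n + i] + 2 * kc[2 * n + i] + kc[3 * n + i]);
      cf[i] += dt / 6.0 * (kf[i] + 2 * kf[n + i] + 2 * kf[2 * n + i] + kf[3 * n + i]);
      S[i] += dt / 6.0 * (kS[i] + 2 * kS[n + i] + 2 * kS[2 * n + i] + kS[3 * n + i]);
      Y[i] += dt / 6.0 * (kY[i] + 2 * kY[n + i] + 2 * kY[2 * n + i] + kY[3 * n + i]);
      A[i] += dt / 6.0 * (kA[i] + 2 * kA[n + i] + 2 * kA[2 * n + i] + kA[3 * n + i]);
      if (cf[i] < 0.0) cf[i] = 0.0;
      if (cf[i] > 1.0) cf[i] = 1.0;
      if (c[i] < 0.0) c[i] = 0.0;
      E2[i] *= d2f[i]; E12[i] *= d12f[i];
    }

    // --- mechanics substeps with the force weights interpolated in time ---
    if (use_see) {
      double Ws1 = 0.0, Wf1 = 0.0;
      for (int i = 0; i < n; ++i)
        (U[i].fiber == 1 ? Wf1 : Ws1) += PT[i] * A[i];
      const int M = mech_substeps;
      const double hs = dt / M;
      for (int m = 0; m < M; ++m) {
        // one RK4 substep of (Lce, Vce); weights linear in time
        double dL[4], dV[4];
        for (int stage = 0; stage < 4; ++stage) {
          double hh = (stage == 0) ? 0.0 : (stage == 3 ? hs : 0.5 * hs);
          double th = (m * hs + hh) / dt;
          double Ws = Ws0 + (Ws1 - Ws0) * th, Wf = Wf0 + (Wf1 - Wf0) * th;
          double sL = Lce, sV = Vce;
          if (stage > 0) { sL += hh * dL[stage - 1]; sV += hh * dV[stage - 1]; }
          double FLs = fl_one(sL, flc_s[0], flc_s[1], flc_s[2]);
          double FLf = fl_one(sL, flc_f[0], flc_f[1], flc_f[2]);
          double FVs = fv_one(sL, sV, fvc_s[0], fvc_s[1], fvc_s[2], fvc_s[3],
                              fvc_s[4], fvc_s[5], fvc_s[6]);
          double FVf = fv_one(sL, sV, fvc_f[0], fvc_f[1], fvc_f[2], fvc_f[3],
                              fvc_f[4], fvc_f[5], fvc_f[6]);
          double Fp2 = fpe2_one(sL, p2c, p2k, p2Lr);
          double Fce = (FLs * FVs + Fp2) * Ws + (FLf * FVf + Fp2) * Wf;
          double Lse = (Lmt - sL * Lce0 * ca) / Lse0;
          double Fse = fse_one(Lse, cT, kT, LrT);
          double Fp1 = fpe1_one(sL, sV, p1c, p1k, p1Lr, p1Lmax, p1eta);
          double acc =
              (1.0 / Mm) * (F0 * Fse * ca - (Fce + F0 * Fp1) * ca * ca) +
              (sV * Lce0) * (sV * Lce0) * ta2 / (sL * Lce0);
          dL[stage] = sV;
          dV[stage] = acc / Lce0;
        }
        Lce += hs / 6.0 * (dL[0] + 2 * dL[1] + 2 * dL[2] + dL[3]);
        Vce += hs / 6.0 * (dV[0] + 2 * dV[1] + 2 * dV[2] + dV[3]);
        if (!std::isfinite(Lce) || Lce <= 0.0)
          stop("musculotendon integration became unstable (dt = %f)", dt);
      }
    }

    // --- output (decimated) ---
    if ((k + 1) % out_every == 0 || k == nt - 1) {
      if (oi < nout) {
        double FLs = fl_one(Lce, flc_s[0], flc_s[1], flc_s[2]);
        double FLf = fl_one(Lce, flc_f[0], flc_f[1], flc_f[2]);
        double FVs = fv_one(Lce, Vce, fvc_s[0], fvc_s[1], fvc_s[2], fvc_s[3],
                            fvc_s[4], fvc_s[5], fvc_s[6]);
        double FVf = fv_one(Lce, Vce, fvc_f[0], fvc_f[1], fvc_f[2], fvc_f[3],
                            fvc_f[4], fvc_f[5], fvc_f[6]);
        double Fp2 = fpe2_one(Lce, p2c, p2k, p2Lr);
        double gain_s = FLs * FVs + Fp2, gain_f = FLf * FVf + Fp2;
        double Fce = 0.0;
        for (int i = 0; i < n; ++i)
          Fce += PT[i] * A[i] * (U[i].fiber == 1 ? gain_f : gain_s);
        double Fout;
        if (use_see) {
          double Lse = (Lmt - Lce * Lce0 * ca) / Lse0;
          Fout = F0 * fse_one(Lse, cT, kT, LrT);
        } else {
          Fout = Fce;
        }
        t_out[oi] = (k + 1) * dt;
        F_out[oi] = Fout;
        Fce_out[oi] = Fce;
        Lce_out[oi] = Lce;
        Vce_out[oi] = Vce;
        spikes_out[oi] = spike_accum;
        spike_accum = 0.0;
        for (int j = 0; j < nkeep; ++j) {
          int i = keep_units[j] - 1;
          unitF_out(oi, j) =
              PT[i] * A[i] *
              ((U[i].fiber == 1)
                   ? (fl_one(Lce, flc_f[0], flc_f[1], flc_f[2]) *
                          fv_one(Lce, Vce, fvc_f[0], fvc_f[1], fvc_f[2],
                                 fvc_f[3], fvc_f[4], fvc_f[5], fvc_f[6]) +
                      fpe2_one(Lce, p2c, p2k, p2Lr))
                   : (fl_one(Lce, flc_s[0], flc_s[1], flc_s[2]) *
                          fv_one(Lce, Vce, fvc_s[0], fvc_s[1], fvc_s[2],
                                 fvc_s[3], fvc_s[4], fvc_s[5], fvc_s[6]) +
                      fpe2_one(Lce, p2c, p2k, p2Lr)));
        }
        ++oi;
      }
    }
  }

  IntegerVector ns_out(n);
  for (int i = 0; i < n; ++i) ns_out[i] = (int)nspike[i];

  return List::create(_["time"] = t_out, _["Fout"] = F_out,
                      _["Fce"] = Fce_out, _["Lce"] = Lce_out,
                      _["Vce"] = Vce_out, _["pool_spikes"] = spikes_out,
                      _["unit_force"] = unitF_out, _["n_spikes"] = ns_out);
}
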