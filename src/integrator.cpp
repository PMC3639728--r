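#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Flat parameter vector layout shared with R (see R/params-internal.R,
// param_engine_vector). Synapse order everywhere: ee, ei, ie, ii.
enum {
  P_HREST_E = 0, P_HREST_I, P_TAU_E, P_TAU_I,
  P_HEQ    = 4,   // 4..7
  P_GAMMA  = 8,   // 8..11
  P_GAMMA0 = 12,  // 12..15
  P_EPS    = 16,  // 16..19
  P_NALPHA = 20,  // 20..21 (ee, ei)
  P_NBETA  = 22,  // 22..25
  P_V      = 26,  // 26..27
  P_LAMBDA = 28,  // 28..29
  P_SMAX   = 30, P_MUBAR = 32, P_SIGMA = 34,
  P_P      = 36,  // 36..39
  P_SLOPE  = 40,
  P_LAW    = 41,  // 0 none, 1 SS1, 2 SS2
  P_NSLOW  = 42,
  P_SLOT   = 43,  // 43..46: 0 (unmodulated) or 1..n_slow per synapse
  P_MU     = 47,  // 47..48 (source e, i)
  P_AB     = 49,  // 49..52 SS1: theta_e, theta_i, k_e, k_i
                  //        SS2: kappa_e, kappa_i, xi_e, xi_i
  P_G0     = 53,  // 53..56 SS2 resting amplitudes
  P_FLOOR  = 57,  // SS1: clamp Gamma at 0 when 1
  NPAR     = 58
};

static inline double sigmoid_rate(const double *p, int pop, double h) {
  return p[P_SMAX + pop] /
         (1.0 + exp(-p[P_SLOPE] * (h - p[P_MUBAR + pop]) / p[P_SIGMA + pop]));
}

// Right-hand side of the coupled fast-slow system.  y has 14 fast components
// (h_e, h_i, I_lk x4, J_lk x4, phi_ek x2, psi_ek x2) followed by n_slow
// dynamic synaptic amplitudes.  p_ee_extra is an additive perturbation of the
// excitatory extra-cortical drive (noise injection).
static void model_rhs(const double *p, const double *y, double *dy,
                      double p_extra, int p_slot) {
  const double Se = sigmoid_rate(p, 0, y[0]);
  const double Si = sigmoid_rate(p, 1, y[1]);

  double A[4];
  A[0] = p[P_NBETA + 0] * Se + y[10] + p[P_P + 0];
  A[1] = p[P_NBETA + 1] * Se + y[11] + p[P_P + 1];
  A[2] = p[P_NBETA + 2] * Si + p[P_P + 2];
  A[3] = p[P_NBETA + 3] * Si + p[P_P + 3];
  if (p_slot >= 0 && p_slot < 4) A[p_slot] += p_extra;

  for (int s = 0; s < 4; ++s) {
    const double eps = p[P_EPS + s], g0 = p[P_GAMMA0 + s];
    double g, gt;
    if (eps <= 0.0) {
      g = gt = g0;
    } else {
      g  = eps * g0 / expm1(eps);
      gt = g * exp(eps);
    }
    double G = p[P_GAMMA + s];
    const int slot = (int)p[P_SLOT + s];
    if (slot > 0) G = y[14 + slot - 1];
    const double drive = gt * exp(g / g0) * G * A[s];
    dy[2 + s] = y[6 + s] - gt * y[2 + s];
    dy[6 + s] = drive - g * y[6 + s];
  }

  // membrane equations with ionic weighting (h_eq - h)/|h_eq - h_rest|
  const double wee = (p[P_HEQ + 0] - y[0]) / fabs(p[P_HEQ + 0] - p[P_HREST_E]);
  const double wie = (p[P_HEQ + 2] - y[0]) / fabs(p[P_HEQ + 2] - p[P_HREST_E]);
  const double wei = (p[P_HEQ + 1] - y[1]) / fabs(p[P_HEQ + 1] - p[P_HREST_I]);
  const double wii = (p[P_HEQ + 3] - y[1]) / fabs(p[P_HEQ + 3] - p[P_HREST_I]);
  dy[0] = (p[P_HREST_E] - y[0] + wee * y[2] + wie * y[4]) / p[P_TAU_E];
  dy[1] = (p[P_HREST_I] - y[1] + wei * y[3] + wii * y[5]) / p[P_TAU_I];

  // homogeneous telegraph dynamics for the cortico-cortical flux
  for (int c = 0; c < 2; ++c) {
    const double a = p[P_V + c] * p[P_LAMBDA + c];
    dy[10 + c] = y[12 + c] - a * y[10 + c];
    dy[12 + c] = a * a * p[P_NALPHA + c] * Se - a * y[12 + c];
  }

  // slow synaptic-amplitude dynamics
  const int law = (int)p[P_LAW];
  const int nslow = (int)p[P_NSLOW];
  if (law == 0 || nslow == 0) return;
  for (int s = 0; s < 4; ++s) {
    const int slot = (int)p[P_SLOT + s];
    if (slot <= 0) continue;
    const int src = (s < 2) ? 0 : 1;  // ee, ei from e; ie, ii from i
    const double hl = y[src];
    const double Sl = (src == 0) ? Se : Si;
    const double mu = p[P_MU + src];
    double d;
    if (law == 1) {
      d = mu * (p[P_AB + src] - p[P_AB + 2 + src] * Sl);
      if (p[P_FLOOR] > 0.5 && y[14 + slot - 1] <= 0.0 && d < 0.0) d = 0.0;
    } else {
      const double kappa = p[P_AB + src], xi = p[P_AB + 2 + src];
      const double target = p[P_G0 + s] / (1.0 + exp(kappa * (hl - xi)));
      d = mu * (target - y[14 + slot - 1]);
    }
    dy[14 + slot - 1] = d;
  }
}

// [[Rcpp::export(name = ".engine_rhs")]]
NumericVector engine_rhs(NumericVector y, NumericVector parms,
                         double p_extra = 0.0, int p_slot = -1) {
  if (parms.size() != NPAR) stop("parameter vector has wrong length");
  NumericVector dy(y.size());
  model_rhs(REAL(parms), REAL(y), REAL(dy), p_extra, p_slot);
  return dy;
}

// Classical fixed-step RK4.  `noise` (possibly empty) holds one additive
// perturbation of p_ee per step, held constant across the step's stages.
// Recording: state at t = 0 and then every `record_every` steps.
// [[Rcpp::export(name = ".engine_rk4")]]
List engine_rk4(NumericVector y0, NumericVector parms, double dt, int nstep,
                int record_every, NumericVector noise, int noise_slot,
                double h_limit) {
  if (parms.size() != NPAR) stop("parameter vector has wrong length");
  const int n = y0.size();
  const bool has_noise = noise.size() > 0;
  if (has_noise && noise.size() < nstep) stop("noise vector shorter than nstep");

  const int nrec = nstep / record_every + 1;
  NumericMatrix out(nrec, n + 1);
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(n), k2(n), k3(n), k4(n), tmp(n);
  const double *p = REAL(parms);

  out(0, 0) = 0.0;
  for (int j = 0; j < n; ++j) out(0, j + 1) = y[j];

  int irec = 1;
  double bad_time = -1.0;
  for (int s = 0; s < nstep; ++s) {
    const double pn = has_noise ? noise[s] : 0.0;
    model_rhs(p, y.data(), k1.data(), pn, noise_slot);
    for (int j = 0; j < n; ++j) tmp[j] = y[j] + 0.5 * dt * k1[j];
    model_rhs(p, tmp.data(), k2.data(), pn, noise_slot);
    for (int j = 0; j < n; ++j) tmp[j] = y[j] + 0.5 * dt * k2[j];
    model_rhs(p, tmp.data(), k3.data(), pn, noise_slot);
    for (int j = 0; j < n; ++j) tmp[j] = y[j] + dt * k3[j];
    model_rhs(p, tmp.data(), k4.data(), pn, noise_slot);
    for (int j = 0; j < n; ++j)
      y[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);

    bool bad = false;
    for (int j = 0; j < n; ++j)
      if (!std::isfinite(y[j])) { bad = true; break; }
    if (!bad && (fabs(y[0]) > h_limit || fabs(y[1]) > h_limit)) bad = true;
    if (bad) { bad_time = (s + 1) * dt; break; }

    if ((s + 1) % record_every == 0 && irec < nrec) {
      out(irec, 0) = (s + 1) * dt;
      for (int j = 0; j < n; ++j) out(irec, j + 1) = y[j];
      ++irec;
    }
  }

  return List::create(_["trace"] = out, _["n_recorded"] = irec,
                      _["bad_time"] = bad_time);
}

// deSolve-compatible entry points so the stiff (lsoda) path integrates the
// same compiled right-hand side.
static double desolve_parms[NPAR];

extern "C" {
void mesoburst_initmod(void (*odeparms)(int *, double *)) {
  int n = NPAR;
  odeparms(&n, desolve_parms);
}

void mesoburst_derivs(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip) {
  (void)neq; (void)t; (void)yout; (void)ip;
  model_rhs(desolve_parms, y, ydot, 0.0, -1);
}
}

// keep name-based lookup available: deSolve resolves the entry points above
// by symbol name at run time
// [[Rcpp::init]]
void mesoburst_enable_dynamic_lookup(DllInfo *dll) {
  R_useDynamicSymbols(dll, TRUE);
}
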