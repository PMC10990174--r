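// Fixed-step RK4 core for the 5D neuron model and its 3D slow-fast
// subsystem.  The reference integration scheme is 4th-order Runge-Kutta at
// dt = 0.001 ms; trajectories of up to a few seconds of model time require
// ~1e6 steps, hence the compiled loop.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Parameter vector layout (kept in sync with as_par_vector() on the R side).
enum ParIdx {
  P_gNaF = 0, P_gNaP, P_gKS, P_gL, P_gHCN, P_gM, P_dgHCN, P_dgM,
  P_ENa, P_EK, P_EL, P_EHCN, P_Cm, P_IApp, P_cAMP,
  P_T, P_Tref1, P_Tref2, P_Qm, P_Qn, P_Qh, P_Qs, P_Qr, P_NPAR
};

struct Pars {
  double gNaF, gNaP, gKS, gL, gHCNeff, gMeff, gHCN, gM;
  double ENa, EK, EL, EHCN, Cm, IApp;
  double phih, phis, phir, nu;
};

static Pars unpack(const NumericVector& p) {
  if (p.size() != P_NPAR) stop("parameter vector has wrong length");
  Pars q;
  q.gNaF = p[P_gNaF]; q.gNaP = p[P_gNaP]; q.gKS = p[P_gKS]; q.gL = p[P_gL];
  q.gHCN = p[P_gHCN]; q.gM = p[P_gM];
  const double camp = p[P_cAMP];
  q.gHCNeff = p[P_gHCN] + camp * p[P_dgHCN];
  q.gMeff   = p[P_gM]   + camp * p[P_dgM];
  q.ENa = p[P_ENa]; q.EK = p[P_EK]; q.EL = p[P_EL]; q.EHCN = p[P_EHCN];
  q.Cm = p[P_Cm]; q.IApp = p[P_IApp];
  q.phih = std::pow(p[P_Qh], (p[P_T] - p[P_Tref1]) / 10.0);
  q.phis = std::pow(p[P_Qs], (p[P_T] - p[P_Tref1]) / 10.0);
  q.phir = std::pow(p[P_Qr], (p[P_T] - p[P_Tref2]) / 10.0);
  q.nu = 95.0 * camp + 103.5 * (1.0 - camp);
  return q;
}

// a*(V+th)/(1 - exp(-(V+th)/k)); removable singularity at V = -th handled
// by the series limit a*k*(1 + u/2), u = (V+th)/k.
static inline double ratexp(double V, double a, double th, double k) {
  const double u = (V + th) / k;
  if (std::fabs(u) < 1e-7) return a * k * (1.0 + 0.5 * u);
  return a * (V + th) / (1.0 - std::exp(-u));
}

struct Gates {
  double minf, ninf, hinf, sinf, rinf, winf;
  double tauh, taus, taur, tauw;
};

static Gates gates_at(double V, const Pars& q) {
  Gates g;
  const double am = ratexp(V, 1.86,     25.4,  10.3);
  const double bm = ratexp(V, -0.086,   29.7,  -9.16);
  const double an = ratexp(V, 0.186,    48.4,  10.3);
  const double bn = ratexp(V, -0.0086,  42.7,  -9.16);
  const double ah = ratexp(V, -0.0336, 118.0, -11.0);
  const double bh = 2.3 / (1.0 + std::exp(-(V + 35.8) / 13.4));
  const double as = ratexp(V, 0.00122,  19.5,  23.6);
  const double bs = ratexp(V, -0.000739, 87.1, -21.8);
  const double ar = 0.007 * std::exp(-(V + q.nu) / 19.0);
  const double br = 0.007 * std::exp((V + q.nu) / 22.0);
  g.minf = am / (am + bm);
  g.ninf = an / (an + bn);
  g.hinf = ah / (ah + bh);
  g.sinf = as / (as + bs);
  g.rinf = ar / (ar + br);
  g.tauh = 1.0 / (q.phih * (ah + bh));
  g.taus = 1.0 / (q.phis * (as + bs));
  g.taur = 1.0 / (q.phir * (ar + br));
  g.winf = 1.0 / (1.0 + std::exp(-(V + 35.0) / 10.0));
  g.tauw = 400.0 / (3.3 * std::exp((V + 35.0) / 20.0) + std::exp(-(V + 35.0) / 20.0));
  return g;
}

static inline void rhs5(const double* y, double* dy, const Pars& q) {
  const double V = y[0], h = y[1], s = y[2], r = y[3], w = y[4];
  const Gates g = gates_at(V, q);
  const double m3 = g.minf * g.minf * g.minf;
  const double n3 = g.ninf * g.ninf * g.ninf;
  const double INaF = q.gNaF * m3 * h * (V - q.ENa);
  const double INaP = q.gNaP * n3 * (V - q.ENa);
  const double IKS  = q.gKS * s * (V - q.EK);
  const double IL   = q.gL * (V - q.EL);
  const double IHCN = q.gHCNeff * r * (V - q.EHCN);
  const double IM   = q.gMeff * w * (V - q.EK);
  dy[0] = (-INaF - INaP - IKS - IL - IHCN - IM + q.IApp) / q.Cm;
  dy[1] = (g.hinf - h) / g.tauh;
  dy[2] = (g.sinf - s) / g.taus;
  dy[3] = (g.rinf - r) / g.taur;
  dy[4] = (g.winf - w) / g.tauw;
}

// 3D slow-fast subsystem: frozen scaled gates wt, rt multiply the base
// conductances gM, gHCN; independent of the cAMP flag by construction.
static inline void rhs3(const double* y, double* dy, const Pars& q,
                        double wt, double rt) {
  const double V = y[0], h = y[1], s = y[2];
  const Gates g = gates_at(V, q);
  const double m3 = g.minf * g.minf * g.minf;
  const double n3 = g.ninf * g.ninf * g.ninf;
  const double INaF = q.gNaF * m3 * h * (V - q.ENa);
  const double INaP = q.gNaP * n3 * (V - q.ENa);
  const double IKS  = q.gKS * s * (V - q.EK);
  const double IL   = q.gL * (V - q.EL);
  const double IHCN = q.gHCN * rt * (V - q.EHCN);
  const double IM   = q.gM * wt * (V - q.EK);
  dy[0] = (-INaF - INaP - IKS - IL - IHCN - IM + q.IApp) / q.Cm;
  dy[1] = (g.hinf - h) / g.tauh;
  dy[2] = (g.sinf - s) / g.taus;
}

// [[Rcpp::export]]
NumericVector cpp_rhs5(NumericVector state, NumericVector par) {
  if (state.size() != 5) stop("5D state must have length 5");
  Pars q = unpack(par);
  double dy[5];
  rhs5(REAL(state), dy, q);
  return NumericVector(dy, dy + 5);
}

// [[Rcpp::export]]
NumericVector cpp_rhs3(NumericVector state, NumericVector par,
                       double wt, double rt) {
  if (state.size() != 3) stop("3D state must have length 3");
  Pars q = unpack(par);
  double dy[3];
  rhs3(REAL(state), dy, q, wt, rt);
  return NumericVector(dy, dy + 3);
}

// [[Rcpp::export]]
List cpp_gate_kinetics(double V, NumericVector par) {
  Pars q = unpack(par);
  Gates g = gates_at(V, q);
  return List::create(
    _["m_inf"] = g.minf, _["n_inf"] = g.ninf, _["h_inf"] = g.hinf,
    _["s_inf"] = g.sinf, _["r_inf"] = g.rinf, _["w_inf"] = g.winf,
    _["tau_h"] = g.tauh, _["tau_s"] = g.taus, _["tau_r"] = g.taur,
    _["tau_w"] = g.tauw, _["nu"] = q.nu);
}

template <int N>
static List run_rk4(const Pars& q, double wt, double rt,
                    NumericVector ic, double t_end, double dt, int thin,
                    int stop_var, double stop_val, int stop_dir) {
  const long nstep = (long)std::llround(t_end / dt);
  if (nstep <= 0) stop("t_end/dt must be a positive number of steps");
  const long nout = nstep / thin + 2;  // +1 for t=0, +1 for a final partial row
  NumericVector tout(nout);
  NumericMatrix yout(nout, N);
  double y[N], k1[N], k2[N], k3[N], k4[N], tmp[N], yprev[N];
  for (int i = 0; i < N; ++i) y[i] = ic[i];
  auto deriv = [&](const double* a, double* d) {
    if (N == 5) rhs5(a, d, q); else rhs3(a, d, q, wt, rt);
  };
  long row = 0;
  tout[0] = 0.0;
  for (int i = 0; i < N; ++i) yout(0, i) = y[i];
  ++row;
  bool stopped = false;
  double t_stop = NA_REAL;
  NumericVector y_stop(N, NA_REAL);
  for (long step = 1; step <= nstep; ++step) {
    for (int i = 0; i < N; ++i) yprev[i] = y[i];
    deriv(y, k1);
    for (int i = 0; i < N; ++i) tmp[i] = y[i] + 0.5 * dt * k1[i];
    deriv(tmp, k2);
    for (int i = 0; i < N; ++i) tmp[i] = y[i] + 0.5 * dt * k2[i];
    deriv(tmp, k3);
    for (int i = 0; i < N; ++i) tmp[i] = y[i] + dt * k3[i];
    deriv(tmp, k4);
    for (int i = 0; i < N; ++i)
      y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    const double t = step * dt;
    for (int i = 0; i < N; ++i) {
      if (!std::isfinite(y[i]))
        stop("non-finite state at t = %f ms (component %d)", t, i + 1);
    }
    if (stop_var >= 0) {
      const double a = yprev[stop_var] - stop_val;
      const double b = y[stop_var] - stop_val;
      const bool crossed = (a <= 0.0 && b > 0.0) || (a >= 0.0 && b < 0.0);
      const int dir = (b > a) ? 1 : -1;
      if (crossed && (stop_dir == 0 || dir == stop_dir)) {
        const double frac = (b - a) != 0.0 ? (0.0 - a) / (b - a) : 0.0;
        t_stop = (step - 1) * dt + frac * dt;
        for (int i = 0; i < N; ++i)
          y_stop[i] = yprev[i] + frac * (y[i] - yprev[i]);
        stopped = true;
      }
    }
    if ((step % thin == 0 || step == nstep) && row < nout) {
      tout[row] = t;
      for (int i = 0; i < N; ++i) yout(row, i) = y[i];
      ++row;
    }
    if (stopped) break;
  }
  if (row < nout) {
    tout = head(tout, row);
    yout = yout(Range(0, row - 1), _);
  }
  return List::create(_["t"] = tout, _["y"] = yout, _["stopped"] = stopped,
                      _["t_stop"] = t_stop, _["y_stop"] = y_stop);
}

// [[Rcpp::export]]
List cpp_sim5(NumericVector par, NumericVector ic, double t_end, double dt,
              int thin) {
  if (ic.size() != 5) stop("5D initial condition must have length 5");
  Pars q = unpack(par);
  return run_rk4<5>(q, 0.0, 0.0, ic, t_end, dt, thin, -1, 0.0, 0);
}

// [[Rcpp::export]]
List cpp_sim3(NumericVector par, double wt, double rt, NumericVector ic,
              double t_end, double dt, int thin,
              int stop_var = -1, double stop_val = 0.0, int stop_dir = 0) {
  if (ic.size() != 3) stop("3D initial condition must have length 3");
  Pars q = unpack(par);
  return run_rk4<3>(q, wt, rt, ic, t_end, dt, thin, stop_var, stop_val,
                    stop_dir);
}
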