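// Compiled core for the thalamocortical conductance neural-mass model:
// a fixed-step RK4 integrator with frozen-history conduction delays and a
// damped-Newton steady-state solver.  The pure-R state_derivative() in
// R/model_core.R is the readable reference for the same dynamics.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int NK = 6; // channel order: AMPA NMDA GABA_A GABA_B M H
static const int K_AMPA = 0, K_NMDA = 1;

struct Edge {
  int i;     // target population
  int j;     // source population
  int k;     // channel kind (0..3, synaptic kinds only)
  double w;  // coupling gain
};

struct Pack {
  int np;
  std::vector<double> delays;            // one per delay group (ms); delays[0] == 0
  std::vector<std::vector<Edge>> edges;  // sparse gains per delay group
  std::vector<double> gM, gH;            // intrinsic M/H gains per population
  std::vector<double> C, Sigma;
  double kappa[NK], Vrev[NK];
  double alphaN, VR, VL, gL;
};

static Pack unpack(const List& m) {
  Pack P;
  P.np = as<int>(m["np"]);
  P.delays = as<std::vector<double>>(m["delays"]);
  const int np = P.np, ndel = (int)P.delays.size();
  NumericVector G = m["gains"]; // np x np x 4 x ndel
  P.edges.resize(ndel);
  for (int d = 0; d < ndel; ++d)
    for (int k = 0; k < 4; ++k)
      for (int j = 0; j < np; ++j)
        for (int i = 0; i < np; ++i) {
          double w = G[i + np * (j + np * (k + 4 * d))];
          if (w != 0.0) P.edges[d].push_back(Edge{i, j, k, w});
        }
  P.gM = as<std::vector<double>>(m["gM"]);
  P.gH = as<std::vector<double>>(m["gH"]);
  P.C = as<std::vector<double>>(m["C"]);
  P.Sigma = as<std::vector<double>>(m["Sigma"]);
  NumericVector kap = m["kappa"], vr = m["Vrev"];
  for (int k = 0; k < NK; ++k) { P.kappa[k] = kap[k]; P.Vrev[k] = vr[k]; }
  P.alphaN = as<double>(m["alpha_NMDA"]);
  P.VR = as<double>(m["V_R"]);
  P.VL = as<double>(m["V_L"]);
  P.gL = as<double>(m["g_L"]);
  return P;
}

// Gaussian CDF firing sigmoid
static inline double phi(double z) { return 0.5 * erfc(-z * M_SQRT1_2); }

static inline double fmg(double V, double a) {
  return 1.0 / (1.0 + 0.2 * exp(-a * V));
}

static void firing(const Pack& P, const double* V, double* f) {
  for (int j = 0; j < P.np; ++j) f[j] = phi((V[j] - P.VR) / P.Sigma[j]);
}

// add synaptic drive of one delay group, given that group's firing vector
static void add_group(const Pack& P, int d, const double* f, double* S /* np x 4 */) {
  const std::vector<Edge>& E = P.edges[d];
  for (size_t e = 0; e < E.size(); ++e)
    S[E[e].i + P.np * E[e].k] += E[e].w * f[E[e].j];
}

// voltage + conductance derivatives.  Sdel holds the frozen delayed synaptic
// drive; instantaneous (group 0) drive and intrinsic M/H drive are added here.
static void deriv(const Pack& P, const double* V, const double* g,
                  const double* Sdel, const double* u,
                  double* dV, double* dg) {
  const int np = P.np;
  std::vector<double> f(np), S(np * 4);
  firing(P, V, f.data());
  for (int x = 0; x < np * 4; ++x) S[x] = Sdel[x];
  add_group(P, 0, f.data(), S.data());
  for (int i = 0; i < np; ++i) {
    double dv = P.gL * (P.VL - V[i]) + u[i];
    for (int k = 0; k < 4; ++k) {
      double drive = (k == K_NMDA)
        ? fmg(V[i], P.alphaN) * (P.Vrev[K_NMDA] - V[i])
        : (P.Vrev[k] - V[i]);
      dv += g[i + np * k] * drive;
    }
    dv += g[i + np * 4] * (P.Vrev[4] - V[i]); // M
    dv += g[i + np * 5] * (P.Vrev[5] - V[i]); // H
    dV[i] = dv / P.C[i];
    for (int k = 0; k < 4; ++k)
      dg[i + np * k] = P.kappa[k] * (S[i + np * k] - g[i + np * k]);
    dg[i + np * 4] = P.kappa[4] * (P.gM[i] * f[i] - g[i + np * 4]);
    dg[i + np * 5] = P.kappa[5] * (P.gH[i] * (1.0 - f[i]) - g[i + np * 5]);
  }
}

// steady-state conductances implied by a voltage vector (all delays collapse)
static void steady_g(const Pack& P, const double* V, double* g) {
  const int np = P.np;
  std::vector<double> f(np), S(np * 4, 0.0);
  firing(P, V, f.data());
  for (size_t d = 0; d < P.delays.size(); ++d) add_group(P, (int)d, f.data(), S.data());
  for (int x = 0; x < np * 4; ++x) g[x] = S[x];
  for (int i = 0; i < np; ++i) {
    g[i + np * 4] = P.gM[i] * f[i];
    g[i + np * 5] = P.gH[i] * (1.0 - f[i]);
  }
}

// voltage residual at the conductance nullcline
static void vresid(const Pack& P, const double* V, const double* u0, double* R) {
  const int np = P.np;
  std::vector<double> g(np * NK), dg(np * NK), Sdel(np * 4, 0.0), dV(np);
  steady_g(P, V, g.data());
  // deriv() adds group-0 drive itself; pre-load the other groups into Sdel
  std::vector<double> f(np);
  firing(P, V, f.data());
  for (size_t d = 1; d < P.delays.size(); ++d) add_group(P, (int)d, f.data(), Sdel.data());
  deriv(P, V, g.data(), Sdel.data(), u0, dV.data(), dg.data());
  for (int i = 0; i < np; ++i) R[i] = dV[i];
}

static double maxabs(const double* x, int n) {
  double m = 0.0;
  for (int i = 0; i < n; ++i) m = std::max(m, std::fabs(x[i]));
  return m;
}

// solve A x = b in place, partial pivoting; n <= 8
static bool lusolve(std::vector<double>& A, std::vector<double>& b, int n) {
  for (int c = 0; c < n; ++c) {
    int p = c;
    for (int r = c + 1; r < n; ++r)
      if (std::fabs(A[r + n * c]) > std::fabs(A[p + n * c])) p = r;
    if (std::fabs(A[p + n * c]) < 1e-14) return false;
    if (p != c) {
      for (int cc = 0; cc < n; ++cc) std::swap(A[c + n * cc], A[p + n * cc]);
      std::swap(b[c], b[p]);
    }
    for (int r = c + 1; r < n; ++r) {
      double m = A[r + n * c] / A[c + n * c];
      for (int cc = c; cc < n; ++cc) A[r + n * cc] -= m * A[c + n * cc];
      b[r] -= m * b[c];
    }
  }
  for (int r = n - 1; r >= 0; --r) {
    double s = b[r];
    for (int cc = r + 1; cc < n; ++cc) s -= A[r + n * cc] * b[cc];
    b[r] = s / A[r + n * r];
  }
  return true;
}

// [[Rcpp::export(name = ".tc_steady_cpp")]]
List tc_steady_cpp(List pack, NumericVector u0, double tol = 1e-12,
                   int max_iter = 200, Nullable<NumericVector> Vstart = R_NilValue) {
  Pack P = unpack(pack);
  const int np = P.np;
  std::vector<double> V(np, P.VL), R(np), Rn(np), u(np);
  if (Vstart.isNotNull()) {
    NumericVector vs(Vstart);
    for (int i = 0; i < np; ++i) V[i] = vs[i];
  }
  for (int i = 0; i < np; ++i) u[i] = u0[i % u0.size()];
  vresid(P, V.data(), u.data(), R.data());
  double rn = maxabs(R.data(), np);
  int it = 0;
  bool ok = true;
  for (; it < max_iter && rn > tol; ++it) {
    // finite-difference Jacobian of the voltage residual
    std::vector<double> J(np * np), Vp(V), Rp(np);
    const double h = 1e-6;
    for (int c = 0; c < np; ++c) {
      Vp[c] = V[c] + h;
      vresid(P, Vp.data(), u.data(), Rp.data());
      for (int r = 0; r < np; ++r) J[r + np * c] = (Rp[r] - R[r]) / h;
      Vp[c] = V[c];
    }
    std::vector<double> step(R);
    std::vector<double> Jc(J);
    if (!lusolve(Jc, step, np)) { ok = false; break; }
    double t = 1.0;
    bool moved = false;
    for (int half = 0; half < 40; ++half) {
      std::vector<double> Vn(np);
      for (int i = 0; i < np; ++i) Vn[i] = V[i] - t * step[i];
      vresid(P, Vn.data(), u.data(), Rn.data());
      double rnn = maxabs(Rn.data(), np);
      if (rnn < rn) {
        V = Vn; R = Rn; rn = rnn; moved = true;
        break;
      }
      t *= 0.5;
    }
    if (!moved) break;
  }
  std::vector<double> g(np * NK);
  steady_g(P, V.data(), g.data());
  return List::create(
    _["V"] = NumericVector(V.begin(), V.end()),
    _["g"] = NumericVector(g.begin(), g.end()),
    _["residual"] = rn,
    _["converged"] = (rn <= tol) && ok,
    _["iterations"] = it);
}

// [[Rcpp::export(name = ".tc_integrate_cpp")]]
List tc_integrate_cpp(List pack, NumericMatrix u, double dt, int nsteps,
                      int out_every, NumericVector Vinit, NumericVector ginit) {
  Pack P = unpack(pack);
  const int np = P.np, ndel = (int)P.delays.size();
  std::vector<double> V(Vinit.begin(), Vinit.end());
  std::vector<double> g(ginit.begin(), ginit.end());

  // firing history on the step grid; pre-integration history = initial firing
  std::vector<double> fh((nsteps + 1) * np);
  firing(P, V.data(), &fh[0]);

  const int nout = nsteps / out_every + 1;
  NumericMatrix Vout(nout, np), gout(nout, np * NK);
  NumericVector tout(nout);
  for (int i = 0; i < np; ++i) Vout(0, i) = V[i];
  for (int x = 0; x < np * NK; ++x) gout(0, x) = g[x];
  tout[0] = 0.0;

  std::vector<double> Sdel(np * 4), fdel(np);
  std::vector<double> k1V(np), k2V(np), k3V(np), k4V(np);
  std::vector<double> k1g(np * NK), k2g(np * NK), k3g(np * NK), k4g(np * NK);
  std::vector<double> Vs(np), gs(np * NK), urow(np);
  int bad_step = -1;

  // delayed synaptic drive at fractional step position q (linear
  // interpolation of the stored firing history; delays exceed dt, so the
  // required history always predates the current step)
  std::vector<double> Sdel0(np * 4), Sdel1(np * 4), Sdel2(np * 4);
  auto delayed_drive = [&](double qpos, int s, std::vector<double>& S) {
    std::fill(S.begin(), S.end(), 0.0);
    for (int d = 1; d < ndel; ++d) {
      double q = qpos - P.delays[d] / dt;
      if (q <= 0.0) {
        for (int j = 0; j < np; ++j) fdel[j] = fh[j];
      } else {
        int lo = (int)std::floor(q);
        int hi = lo + 1 > s ? s : lo + 1;
        double w = q - lo;
        for (int j = 0; j < np; ++j)
          fdel[j] = (1.0 - w) * fh[j + np * lo] + w * fh[j + np * hi];
      }
      add_group(P, d, fdel.data(), S.data());
    }
  };

  for (int s = 0; s < nsteps; ++s) {
    delayed_drive(s, s, Sdel0);
    delayed_drive(s + 0.5, s, Sdel1);
    delayed_drive(s + 1.0, s, Sdel2);

    // RK4 stages; exogenous drive sampled on the half-step grid
    std::vector<double> ua(np), ub(np), uc(np);
    for (int i = 0; i < np; ++i) {
      ua[i] = u(2 * s, i); ub[i] = u(2 * s + 1, i); uc[i] = u(2 * s + 2, i);
    }
    deriv(P, V.data(), g.data(), Sdel0.data(), ua.data(), k1V.data(), k1g.data());
    for (int i = 0; i < np; ++i) Vs[i] = V[i] + 0.5 * dt * k1V[i];
    for (int x = 0; x < np * NK; ++x) gs[x] = g[x] + 0.5 * dt * k1g[x];
    deriv(P, Vs.data(), gs.data(), Sdel1.data(), ub.data(), k2V.data(), k2g.data());
    for (int i = 0; i < np; ++i) Vs[i] = V[i] + 0.5 * dt * k2V[i];
    for (int x = 0; x < np * NK; ++x) gs[x] = g[x] + 0.5 * dt * k2g[x];
    deriv(P, Vs.data(), gs.data(), Sdel1.data(), ub.data(), k3V.data(), k3g.data());
    for (int i = 0; i < np; ++i) Vs[i] = V[i] + dt * k3V[i];
    for (int x = 0; x < np * NK; ++x) gs[x] = g[x] + dt * k3g[x];
    deriv(P, Vs.data(), gs.data(), Sdel2.data(), uc.data(), k4V.data(), k4g.data());

    bool finite = true;
    for (int i = 0; i < np; ++i) {
      V[i] += dt / 6.0 * (k1V[i] + 2.0 * k2V[i] + 2.0 * k3V[i] + k4V[i]);
      if (!std::isfinite(V[i])) finite = false;
    }
    for (int x = 0; x < np * NK; ++x) {
      g[x] += dt / 6.0 * (k1g[x] + 2.0 * k2g[x] + 2.0 * k3g[x] + k4g[x]);
      if (!std::isfinite(g[x])) finite = false;
    }
    if (!finite) { bad_step = s + 1; break; }

    firing(P, V.data(), &fh[(s + 1) * np]);
    if ((s + 1) % out_every == 0) {
      int r = (s + 1) / out_every;
      for (int i = 0; i < np; ++i) Vout(r, i) = V[i];
      for (int x = 0; x < np * NK; ++x) gout(r, x) = g[x];
      tout[r] = (s + 1) * dt;
    }
  }

  return List::create(
    _["t"] = tout, _["V"] = Vout, _["g"] = gout,
    _["diverged_at"] = bad_step < 0 ? R_NilValue
                                    : (SEXP)NumericVector::create(bad_step * dt));
}
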