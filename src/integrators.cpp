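#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step RK4 integrators for the dynamic models (logistic, constrained
// logistic system, generalized Lotka-Volterra). States are clamped at zero so
// the invariant manifold x_i = 0 is exact, and trajectories that exceed
// X_BLOWUP abort early (possible for unconstrained interaction parameters
// during optimization).

static const double X_CLAMP = 10.0;

// dx_i/dt = (mu_i + sum_j a_ij x_j) x_i
// species at exactly zero stay zero (invariant manifold), so they are
// skipped — monoculture conditions then cost O(1) per step instead of O(S^2)
static inline void glv_rhs(const std::vector<double>& x,
                           const NumericVector& mu, const NumericMatrix& A,
                           std::vector<double>& dx) {
  int S = x.size();
  for (int i = 0; i < S; ++i) {
    if (x[i] == 0.0) { dx[i] = 0.0; continue; }
    double g = mu[i];
    for (int j = 0; j < S; ++j) if (x[j] != 0.0) g += A(i, j) * x[j];
    dx[i] = g * x[i];
  }
}

// dx_i/dt = mu_i (1 - x_i/K_i) (1 - sum_j x_j / K_comm) x_i
static inline void csle_rhs(const std::vector<double>& x,
                            const NumericVector& mu, const NumericVector& K,
                            double Kcomm, std::vector<double>& dx) {
  int S = x.size();
  double tot = 0.0;
  for (int j = 0; j < S; ++j) tot += x[j];
  double comm = 1.0 - tot / Kcomm;
  for (int i = 0; i < S; ++i)
    dx[i] = mu[i] * (1.0 - x[i] / K[i]) * comm * x[i];
}

enum Model { GLV, CSLE };

struct Params {
  const NumericVector* mu;
  const NumericMatrix* A;
  const NumericVector* K;
  double Kcomm;
};

static inline void rhs(Model m, const std::vector<double>& x, const Params& p,
                       std::vector<double>& dx) {
  if (m == GLV) glv_rhs(x, *p.mu, *p.A, dx);
  else          csle_rhs(x, *p.mu, *p.K, p.Kcomm, dx);
}

// one RK4 step of size h. Unbounded growth (possible for trial parameter
// sets during optimization) is handled by saturating the state at X_CLAMP
// rather than aborting: the objective then stays finite and decreasing away
// from the divergent region, instead of presenting the optimizer with a
// flat cliff. Returns false when saturation (or a non-finite value) occurred.
static bool rk4_step(Model m, std::vector<double>& x, double h, const Params& p,
                     std::vector<double>& k1, std::vector<double>& k2,
                     std::vector<double>& k3, std::vector<double>& k4,
                     std::vector<double>& tmp) {
  int S = x.size();
  bool ok = true;
  rhs(m, x, p, k1);
  for (int i = 0; i < S; ++i) tmp[i] = x[i] + 0.5 * h * k1[i];
  rhs(m, tmp, p, k2);
  for (int i = 0; i < S; ++i) tmp[i] = x[i] + 0.5 * h * k2[i];
  rhs(m, tmp, p, k3);
  for (int i = 0; i < S; ++i) tmp[i] = x[i] + h * k3[i];
  rhs(m, tmp, p, k4);
  for (int i = 0; i < S; ++i) {
    x[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    if (x[i] < 0.0) x[i] = 0.0;
    if (!std::isfinite(x[i]) || x[i] > X_CLAMP) { x[i] = X_CLAMP; ok = false; }
  }
  return ok;
}

// integrate from t=0 recording the state at `times` (ascending, >= 0)
static NumericMatrix integrate_record(Model m, const NumericVector& x0,
                                      const NumericVector& times, double dt,
                                      const Params& p, bool* diverged) {
  int S = x0.size(), nt = times.size();
  NumericMatrix out(nt, S);
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> k1(S), k2(S), k3(S), k4(S), tmp(S);
  double t = 0.0;
  *diverged = false;
  for (int r = 0; r < nt; ++r) {
    double target = times[r];
    while (t < target - 1e-12) {
      double h = std::min(dt, target - t);
      if (!rk4_step(m, x, h, p, k1, k2, k3, k4, tmp)) *diverged = true;
      t += h;
    }
    for (int i = 0; i < S; ++i) out(r, i) = x[i];
  }
  return out;
}

// [[Rcpp::export]]
List cpp_glv_simulate(NumericVector mu, NumericMatrix A, NumericVector x0,
                      NumericVector times, double dt = 0.05) {
  Params p; p.mu = &mu; p.A = &A;
  bool div;
  NumericMatrix st = integrate_record(GLV, x0, times, dt, p, &div);
  return List::create(_["states"] = st, _["diverged"] = div);
}

// [[Rcpp::export]]
List cpp_csle_simulate(NumericVector mu, NumericVector K, double Kcomm,
                       NumericVector x0, NumericVector times, double dt = 0.05) {
  Params p; p.mu = &mu; p.K = &K; p.Kcomm = Kcomm;
  bool div;
  NumericMatrix st = integrate_record(CSLE, x0, times, dt, p, &div);
  return List::create(_["states"] = st, _["diverged"] = div);
}

// integrate until max |dx/dt| < dtol or t >= t_max; returns endpoint
static List steady(Model m, const NumericVector& x0, const Params& p,
                   double dt, double t_max, double dtol) {
  int S = x0.size();
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> k1(S), k2(S), k3(S), k4(S), tmp(S);
  double t = 0.0;
  bool converged = false, diverged = false;
  while (t < t_max) {
    if (!rk4_step(m, x, dt, p, k1, k2, k3, k4, tmp)) { diverged = true; break; }
    t += dt;
    rhs(m, x, p, k1);
    double mx = 0.0;
    for (int i = 0; i < S; ++i) mx = std::max(mx, std::fabs(k1[i]));
    if (mx < dtol) { converged = true; break; }
  }
  NumericVector xf(S);
  for (int i = 0; i < S; ++i) xf[i] = diverged ? NA_REAL : x[i];
  return List::create(_["x"] = xf, _["t"] = t, _["converged"] = converged,
                      _["diverged"] = diverged);
}

// [[Rcpp::export]]
List cpp_glv_steady(NumericVector mu, NumericMatrix A, NumericVector x0,
                    double dt = 0.05, double t_max = 200.0, double dtol = 1e-9) {
  Params p; p.mu = &mu; p.A = &A;
  return steady(GLV, x0, p, dt, t_max, dtol);
}

// [[Rcpp::export]]
List cpp_csle_steady(NumericVector mu, NumericVector K, double Kcomm,
                     NumericVector x0, double dt = 0.05, double t_max = 200.0,
                     double dtol = 1e-9) {
  Params p; p.mu = &mu; p.K = &K; p.Kcomm = Kcomm;
  return steady(CSLE, x0, p, dt, t_max, dtol);
}

// Sum of squared errors between gLV predictions and observations over a set of
// training conditions, plus an L1 penalty on interaction terms. `par` packs
// c(mu, vec(A)) column-major. Each condition c has initial state x0[c, ],
// observation times times[[c]] and an observation matrix obs[[c]]
// (length(times) x S, NA entries skipped). Used as the inference objective,
// so it must be cheap: everything stays in C++.
static double glv_obj_impl(const NumericVector& par, int S,
                           const NumericMatrix& x0s, const List& times,
                           const List& obs, double lambda,
                           bool penalize_diag, double dt) {
  NumericVector mu(S);
  NumericMatrix A(S, S);
  for (int i = 0; i < S; ++i) mu[i] = par[i];
  for (int j = 0; j < S; ++j)
    for (int i = 0; i < S; ++i) A(i, j) = par[S + j * S + i];
  Params p; p.mu = &mu; p.A = &A;
  double sse = 0.0;
  int nc = x0s.nrow();
  for (int c = 0; c < nc; ++c) {
    NumericVector tc = times[c];
    NumericMatrix oc = obs[c];
    NumericVector x0 = x0s(c, _);
    bool div;
    NumericMatrix pred = integrate_record(GLV, x0, tc, dt, p, &div);
    for (int r = 0; r < oc.nrow(); ++r)
      for (int i = 0; i < S; ++i)
        if (!NumericVector::is_na(oc(r, i))) {
          double e = pred(r, i) - oc(r, i);
          sse += e * e;
        }
  }
  // smoothed absolute value: |a| ~= sqrt(a^2 + eps^2) - eps. The kink of the
  // exact L1 norm at zero makes quasi-Newton line searches fail; the
  // smoothing is two orders below the parameter scale, so the penalty is L1 in all
  // but an eps-neighborhood of zero.
  const double eps = 1e-4;
  double pen = 0.0;
  for (int i = 0; i < S; ++i)
    for (int j = 0; j < S; ++j)
      if (i != j || penalize_diag)
        pen += std::sqrt(A(i, j) * A(i, j) + eps * eps) - eps;
  return sse + lambda * pen;
}

// [[Rcpp::export]]
double cpp_glv_objective(NumericVector par, int S, NumericMatrix x0s,
                         List times, List obs, double lambda,
                         bool penalize_diag = false, double dt = 0.1) {
  return glv_obj_impl(par, S, x0s, times, obs, lambda, penalize_diag, dt);
}

// Forward-difference gradient of the objective, computed entirely in C++ so
// the optimizer's per-iteration cost is (n+1) integr. sweeps with no R
// round-trips. A parameter sitting at zero is stepped forward, which yields
// the right one-sided subgradient of the L1 term.
// [[Rcpp::export]]
NumericVector cpp_glv_gradient(NumericVector par, int S, NumericMatrix x0s,
                               List times, List obs, double lambda,
                               bool penalize_diag = false, double dt = 0.1,
                               double h = 1e-7,
                               IntegerVector idx = IntegerVector::create()) {
  int n = par.size();
  NumericVector g(n);
  double f0 = glv_obj_impl(par, S, x0s, times, obs, lambda, penalize_diag, dt);
  NumericVector p = clone(par);
  std::vector<int> ks;
  if (idx.size() == 0) for (int k = 0; k < n; ++k) ks.push_back(k);
  else for (int k = 0; k < idx.size(); ++k) ks.push_back(idx[k]);
  for (int k : ks) {
    double hk = h * std::max(1.0, std::fabs(par[k]));
    p[k] = par[k] + hk;
    double f1 = glv_obj_impl(p, S, x0s, times, obs, lambda, penalize_diag, dt);
    g[k] = (f1 - f0) / hk;
    p[k] = par[k];
  }
  return g;
}

// Serial-passage chain: each passage integrates t_per hours from the previous
// endpoint divided by `dilution`; returns endpoint abundances per passage.
// [[Rcpp::export]]
List cpp_glv_passages(NumericVector mu, NumericMatrix A, NumericVector x0,
                      int n_passages, double dilution, double t_per,
                      double dt = 0.05) {
  int S = x0.size();
  NumericMatrix out(n_passages, S);
  NumericVector start = clone(x0);
  Params p; p.mu = &mu; p.A = &A;
  NumericVector tt = NumericVector::create(t_per);
  bool div = false;
  for (int pa = 0; pa < n_passages; ++pa) {
    bool d1 = false;
    NumericMatrix st = integrate_record(GLV, start, tt, dt, p, &d1);
    if (d1) div = true;
    for (int i = 0; i < S; ++i) {
      out(pa, i) = st(0, i);
      start[i] = st(0, i) / dilution;
    }
  }
  return List::create(_["endpoints"] = out, _["diverged"] = div);
}
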