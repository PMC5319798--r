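// Logic-based ODE core: normalized Hill transfer, multivariate polynomial
// interpolation of Boolean gates, adaptive Dormand-Prince RK45 integration,
// and the sum-of-squares training objective evaluated over a whole dataset.
//
// The model is passed as a flat "compiled" representation built in R
// (see compile_model() in R/calibration.R): per node, the active regulator
// indices and, for every tunable slot, an index into a single parameter
// vector `par`. This lets the optimizer re-evaluate the objective for a new
// parameter vector without rebuilding any R structures.
//
// Experiments may carry a "forcing" block (time grid + per-node values):
// forced nodes are clamped to the linear interpolation of those values --
// used for data-driven (teacher-forced) node-wise pre-fits.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct NodeSpec {
  bool is_stim;
  std::vector<int> reg;    // 0-based parent node indices (active edges only)
  std::vector<int> n_idx;  // par index of Hill exponent per edge
  std::vector<int> k_idx;  // par index of Hill half-saturation per edge
  std::vector<int> w_idx;  // par indices, length 2^N, corner j: x_k = bit (k-1) of j
  int tau_idx;             // par index of lifetime; -1 for stimulus nodes
};

struct CompiledModel {
  int n_nodes;
  std::vector<NodeSpec> nodes;
};

struct Forcing {
  bool any = false;
  const int* forced = nullptr;   // 0/1 per node
  const double* times = nullptr; // shared grid, length nt
  const double* vals = nullptr;  // matrix nt x n_nodes (column-major)
  int nt = 0;

  double interp(double t, int node) const {
    const double* col = vals + (size_t)nt * node;
    if (t <= times[0]) return col[0];
    if (t >= times[nt - 1]) return col[nt - 1];
    int lo = 0, hi = nt - 1;
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (times[mid] <= t) lo = mid; else hi = mid;
    }
    double f = (t - times[lo]) / (times[hi] - times[lo]);
    return col[lo] + f * (col[hi] - col[lo]);
  }
};

CompiledModel unpack_model(const List& cm) {
  CompiledModel m;
  m.n_nodes = as<int>(cm["n_nodes"]);
  IntegerVector is_stim = cm["is_stim"];
  List reg = cm["reg"], n_idx = cm["n_idx"], k_idx = cm["k_idx"], w_idx = cm["w_idx"];
  IntegerVector tau_idx = cm["tau_idx"];
  m.nodes.resize(m.n_nodes);
  for (int i = 0; i < m.n_nodes; ++i) {
    NodeSpec& nd = m.nodes[i];
    nd.is_stim = is_stim[i] != 0;
    nd.reg = as<std::vector<int>>(reg[i]);
    nd.n_idx = as<std::vector<int>>(n_idx[i]);
    nd.k_idx = as<std::vector<int>>(k_idx[i]);
    nd.w_idx = as<std::vector<int>>(w_idx[i]);
    nd.tau_idx = tau_idx[i];
  }
  return m;
}

inline double clamp01(double x) { return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x); }

// Normalized Hill with optional inhibition of the regulator species:
// H = x^n (1-inh) / (x^n (1-inh) + k^n) * (1 + k^n), so H(1,inh=0)=1, H(0)=0.
inline double hill_tf(double x, double n, double kn, double inh) {
  x = clamp01(x);
  if (x <= 0.0) return 0.0;
  double xn = std::pow(x, n) * (1.0 - inh);
  return xn / (xn + kn) * (1.0 + kn);
}

// Right-hand side of the logic ODE system at time t.
// mode: 0 = node-level inhibition (derivative damped by 1-inh_i),
//       1 = downstream inhibition (inhibited species' Hill terms damped).
// kn holds precomputed k^n per parameter slot (indexed like par).
void rhs(const CompiledModel& m, const double* par, const double* kn,
         const double* inh, int mode, const Forcing& fc, double t,
         const double* x, double* dx, double* xs) {
  const int n = m.n_nodes;
  for (int i = 0; i < n; ++i) {
    xs[i] = (fc.any && fc.forced[i]) ? fc.interp(t, i) : x[i];
  }
  for (int i = 0; i < n; ++i) {
    const NodeSpec& nd = m.nodes[i];
    if (nd.is_stim || (fc.any && fc.forced[i])) { dx[i] = 0.0; continue; }
    const int N = (int)nd.reg.size();
    double h[32];
    for (int k = 0; k < N; ++k) {
      double inh_k = (mode == 1) ? inh[nd.reg[k]] : 0.0;
      h[k] = hill_tf(xs[nd.reg[k]], par[nd.n_idx[k]], kn[nd.n_idx[k]], inh_k);
    }
    // B = sum over Boolean corners of w * prod(x_k ? h_k : 1-h_k)
    double B = 0.0;
    const int ncorner = 1 << N;
    for (int j = 0; j < ncorner; ++j) {
      double w = par[nd.w_idx[j]];
      if (w == 0.0) continue;
      double prod = w;
      for (int k = 0; k < N; ++k)
        prod *= ((j >> k) & 1) ? h[k] : (1.0 - h[k]);
      B += prod;
    }
    double d = (B - x[i]) / par[nd.tau_idx];
    if (mode == 0) d *= (1.0 - inh[i]);
    dx[i] = d;
  }
}

// Dormand-Prince RK45 coefficients
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
                    a64 = 49.0 / 176, a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
static const double e1 = 35.0 / 384 - 5179.0 / 57600,
                    e3 = 500.0 / 1113 - 7571.0 / 16695,
                    e4 = 125.0 / 192 - 393.0 / 640,
                    e5 = -2187.0 / 6784 + 92097.0 / 339200,
                    e6 = 11.0 / 84 - 187.0 / 2100, e7 = -1.0 / 40;

struct Workspace {
  std::vector<double> k1, k2, k3, k4, k5, k6, k7, xt, xs;
  void resize(int n) {
    k1.resize(n); k2.resize(n); k3.resize(n); k4.resize(n); k5.resize(n);
    k6.resize(n); k7.resize(n); xt.resize(n); xs.resize(n);
  }
};

// Integrate from t0 with state x, writing the solution at each requested
// output time into out (row t, col node). Returns false on step failure.
bool integrate(const CompiledModel& m, const double* par, const double* kn,
               const double* inh, int mode, const Forcing& fc,
               std::vector<double>& x, double t0,
               const double* times, int ntimes, double rtol, double atol,
               int max_steps, double* out, int nt_stride, Workspace& W) {
  const int n = m.n_nodes;
  W.resize(n);
  double* k1 = W.k1.data(); double* k2 = W.k2.data(); double* k3 = W.k3.data();
  double* k4 = W.k4.data(); double* k5 = W.k5.data(); double* k6 = W.k6.data();
  double* k7 = W.k7.data(); double* xt = W.xt.data(); double* xs = W.xs.data();
  double t = t0;
  double h = 1e-3;
  int steps = 0;
  int it = 0;
  auto emit = [&](double tt) {
    for (int i = 0; i < n; ++i) {
      double v = (fc.any && fc.forced[i]) ? fc.interp(tt, i) : x[i];
      out[it + nt_stride * i] = clamp01(v);
    }
    ++it;
  };
  while (it < ntimes && times[it] <= t0 + 1e-12) emit(times[it]);
  if (it >= ntimes) return true;
  rhs(m, par, kn, inh, mode, fc, t, x.data(), k1, xs);  // FSAL seed
  while (it < ntimes) {
    if (++steps > max_steps) return false;
    double t_target = times[it];
    if (t + h > t_target) h = t_target - t;
    if (h <= 0) h = 1e-12;
    for (int i = 0; i < n; ++i) xt[i] = x[i] + h * a21 * k1[i];
    rhs(m, par, kn, inh, mode, fc, t + c2 * h, xt, k2, xs);
    for (int i = 0; i < n; ++i) xt[i] = x[i] + h * (a31 * k1[i] + a32 * k2[i]);
    rhs(m, par, kn, inh, mode, fc, t + c3 * h, xt, k3, xs);
    for (int i = 0; i < n; ++i)
      xt[i] = x[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    rhs(m, par, kn, inh, mode, fc, t + c4 * h, xt, k4, xs);
    for (int i = 0; i < n; ++i)
      xt[i] = x[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
    rhs(m, par, kn, inh, mode, fc, t + c5 * h, xt, k5, xs);
    for (int i = 0; i < n; ++i)
      xt[i] = x[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] + a64 * k4[i] +
                          a65 * k5[i]);
    rhs(m, par, kn, inh, mode, fc, t + h, xt, k6, xs);
    for (int i = 0; i < n; ++i)
      xt[i] = x[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] + b5 * k5[i] +
                          b6 * k6[i]);
    rhs(m, par, kn, inh, mode, fc, t + h, xt, k7, xs);
    double err = 0.0;
    for (int i = 0; i < n; ++i) {
      double e = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                      e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(x[i]), std::fabs(xt[i]));
      double r = e / sc;
      err += r * r;
    }
    err = std::sqrt(err / n);
    if (!std::isfinite(err)) return false;
    if (err <= 1.0) {  // accept
      t += h;
      for (int i = 0; i < n; ++i) x[i] = xt[i];
      std::swap(W.k1, W.k7);  // FSAL
      k1 = W.k1.data(); k7 = W.k7.data();
      while (it < ntimes && times[it] <= t + 1e-12) emit(times[it]);
    }
    double fac = (err > 0) ? 0.9 * std::pow(err, -0.2) : 5.0;
    if (fac < 0.2) fac = 0.2;
    if (fac > 5.0) fac = 5.0;
    h *= fac;
    if (h < 1e-12) return false;
  }
  return true;
}

// k^n cache, indexed like par (only k-slots meaningful).
void fill_kn(const CompiledModel& m, const double* par, std::vector<double>& kn) {
  for (const NodeSpec& nd : m.nodes) {
    for (size_t e = 0; e < nd.reg.size(); ++e) {
      kn[nd.n_idx[e]] = std::pow(par[nd.k_idx[e]], par[nd.n_idx[e]]);
    }
  }
}

Forcing read_forcing(const List& ex) {
  Forcing fc;
  if (ex.containsElementNamed("forced")) {
    IntegerVector forced = ex["forced"];
    if (Rf_isNull(ex["ftimes"])) return fc;
    NumericVector ftimes = ex["ftimes"];
    NumericMatrix fvals = ex["fvals"];
    fc.any = true;
    fc.forced = INTEGER(forced);
    fc.times = REAL(ftimes);
    fc.vals = REAL(fvals);
    fc.nt = ftimes.size();
  }
  return fc;
}

}  // namespace

// Simulate one experiment; returns matrix [time x node] clipped to [0,1].
// [[Rcpp::export]]
NumericMatrix sim_experiment_cpp(List cmodel, NumericVector par, NumericVector x0,
                                 NumericVector inh, int mode, NumericVector times,
                                 double t0, double rtol, double atol,
                                 int max_steps) {
  CompiledModel m = unpack_model(cmodel);
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> kn(par.size(), 0.0);
  fill_kn(m, REAL(par), kn);
  NumericMatrix out(times.size(), m.n_nodes);
  Forcing fc;
  Workspace W;
  bool ok = integrate(m, REAL(par), kn.data(), REAL(inh), mode, fc, x, t0,
                      REAL(times), times.size(), rtol, atol, max_steps,
                      REAL(out), times.size(), W);
  if (!ok) stop("integration failed");
  return out;
}

// Sum of squared residuals over a list of experiments (the training
// objective). Each experiment: x0, inh, times, obs (matrix time x n_obs,
// NA = missing), obs_cols (0-based node index per observed column), and an
// optional forcing block (forced, ftimes, fvals). A failed integration
// returns `penalty` immediately.
// [[Rcpp::export]]
double objective_cpp(List cmodel, NumericVector par, List experiments, int mode,
                     double rtol, double atol, int max_steps, double penalty) {
  CompiledModel m = unpack_model(cmodel);
  std::vector<double> kn(par.size(), 0.0);
  fill_kn(m, REAL(par), kn);
  double F = 0.0;
  int nexp = experiments.size();
  std::vector<double> traj;
  Workspace W;
  for (int e = 0; e < nexp; ++e) {
    List ex = experiments[e];
    NumericVector x0 = ex["x0"], inh = ex["inh"], times = ex["times"];
    NumericMatrix obs = ex["obs"];
    IntegerVector obs_cols = ex["obs_cols"];
    Forcing fc = read_forcing(ex);
    std::vector<double> x(x0.begin(), x0.end());
    const int nt = times.size();
    traj.assign((size_t)nt * m.n_nodes, 0.0);
    bool ok = integrate(m, REAL(par), kn.data(), REAL(inh), mode, fc, x, 0.0,
                        REAL(times), nt, rtol, atol, max_steps, traj.data(),
                        nt, W);
    if (!ok) return penalty;
    for (int j = 0; j < obs_cols.size(); ++j) {
      const int node = obs_cols[j];
      for (int s = 0; s < nt; ++s) {
        double y = obs(s, j);
        if (ISNAN(y)) continue;
        double r = y - traj[s + (size_t)nt * node];
        F += r * r;
      }
    }
  }
  return F;
}
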