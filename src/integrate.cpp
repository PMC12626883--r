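// Fixed-step Langevin integrator for multiscale unit networks.
//
// The R wrapper precomputes, per unit, the three step matrices of a
// linear-implicit update
//     x_u <- M1 x_u + M2 (sum_c g_c phi_c(x_source)) + L xi,
// which covers both Euler-Maruyama (M1 = I - A dt/tau, M2 = (dt/tau) I,
// L = sqrt(2 dt/tau) sigma) and the exponential splitting (M1 = expm,
// M2 = A^{-1}(I - expm), L = factor of the exact step covariance). The
// nonlinear inter-unit drive is evaluated from the current state each
// step.
//
// The step loop runs over raw arrays with a dedicated, explicitly
// seeded std::mt19937_64 normal stream: unit sizes are tiny (tens of
// dofs) while stiff timescale ladders need ~1e8 steps, so per-step
// call overhead, not linear algebra, is the budget.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct DenseMat {               // row-major dense matrix
  int nr = 0, nc = 0;
  std::vector<double> a;
  void from(const NumericMatrix& m) {
    nr = m.nrow(); nc = m.ncol();
    a.resize((size_t)nr * nc);
    for (int i = 0; i < nr; ++i)
      for (int j = 0; j < nc; ++j) a[(size_t)i * nc + j] = m(i, j);
  }
  // y += s * A x
  void accum(const double* x, double* y, double s = 1.0) const {
    for (int i = 0; i < nr; ++i) {
      const double* row = &a[(size_t)i * nc];
      double acc = 0;
      for (int j = 0; j < nc; ++j) acc += row[j] * x[j];
      y[i] += s * acc;
    }
  }
};

struct Unit {
  int M = 0;
  DenseMat M1, M2, L;
};

struct Coupling {
  int target, source, scheme, act;  // scheme: 0 sum, 1 int; act: 0 tanh
  double g;
  DenseMat Wn;
  std::vector<double> theta;
};

}  // namespace

// [[Rcpp::export]]
List cpp_integrate(List units, List couplings, IntegerVector Ms,
                   NumericVector x0, int n_keep, int thin, int burn_in,
                   double guard, int seed) {
  const int n_units = units.size();
  std::vector<Unit> U(n_units);
  std::vector<int> off(n_units);
  int total = 0, maxM = 1;
  for (int u = 0; u < n_units; ++u) {
    List uu = units[u];
    U[u].M = Ms[u];
    U[u].M1.from(as<NumericMatrix>(uu["M1"]));
    U[u].M2.from(as<NumericMatrix>(uu["M2"]));
    U[u].L.from(as<NumericMatrix>(uu["L"]));
    off[u] = total;
    total += Ms[u];
    maxM = std::max(maxM, (int)Ms[u]);
  }
  std::vector<Coupling> C(couplings.size());
  for (int c = 0; c < (int)couplings.size(); ++c) {
    List cc = couplings[c];
    C[c].target = as<int>(cc["target"]);
    C[c].source = as<int>(cc["source"]);
    C[c].g = as<double>(cc["g"]);
    C[c].scheme = as<int>(cc["scheme"]);
    C[c].act = as<int>(cc["act"]);
    C[c].Wn.from(as<NumericMatrix>(cc["Wn"]));
    NumericVector th = cc["theta"];
    C[c].theta.assign(th.begin(), th.end());
  }

  std::mt19937_64 rng((uint64_t)(uint32_t)seed * 0x9E3779B97F4A7C15ULL + 1);
  std::normal_distribution<double> N01(0.0, 1.0);

  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> xnew(total), drive(total), xi(maxM), z(maxM), y(maxM);
  std::vector<NumericMatrix> out;
  out.reserve(n_units);
  for (int u = 0; u < n_units; ++u) out.emplace_back(n_keep, (int)Ms[u]);

  const long long n_total = (long long)burn_in + (long long)thin * n_keep;
  long long kept = 0;
  for (long long step = 1; step <= n_total; ++step) {
    std::fill(drive.begin(), drive.end(), 0.0);
    for (const Coupling& cp : C) {
      const double* xs = &x[off[cp.source]];
      double* d = &drive[off[cp.target]];
      const int nsrc = cp.Wn.nc, ntgt = cp.Wn.nr;
      for (int j = 0; j < nsrc; ++j) z[j] = xs[j] - cp.theta[j];
      if (cp.scheme == 0) {            // summation: activation first
        if (cp.act == 0)
          for (int j = 0; j < nsrc; ++j) z[j] = std::tanh(z[j]);
        std::fill(y.begin(), y.begin() + ntgt, 0.0);
        cp.Wn.accum(z.data(), y.data());
        for (int i = 0; i < ntgt; ++i) d[i] += cp.g * y[i];
      } else {                         // integration: combine first
        std::fill(y.begin(), y.begin() + ntgt, 0.0);
        cp.Wn.accum(z.data(), y.data());
        if (cp.act == 0)
          for (int i = 0; i < ntgt; ++i) y[i] = std::tanh(y[i]);
        for (int i = 0; i < ntgt; ++i) d[i] += cp.g * y[i];
      }
    }
    for (int u = 0; u < n_units; ++u) {
      const int M = U[u].M, o = off[u];
      for (int j = 0; j < M; ++j) xi[j] = N01(rng);
      double* xn = &xnew[o];
      std::fill(xn, xn + M, 0.0);
      U[u].M1.accum(&x[o], xn);
      U[u].M2.accum(&drive[o], xn);
      U[u].L.accum(xi.data(), xn);
    }
    std::copy(xnew.begin(), xnew.end(), x.begin());
    if ((step & 255) == 0) {
      double mx = 0;
      for (double v : x) mx = std::max(mx, std::fabs(v));
      if (mx > guard)
        stop("trajectory diverged: |x| exceeded the guard at step " +
             std::to_string(step));
      Rcpp::checkUserInterrupt();
    }
    if (step > burn_in && (step - burn_in) % thin == 0) {
      for (int u = 0; u < n_units; ++u)
        for (int j = 0; j < U[u].M; ++j) out[u]((int)kept, j) = x[off[u] + j];
      ++kept;
      if (kept == n_keep) break;
    }
  }
  List res(n_units);
  for (int u = 0; u < n_units; ++u) res[u] = out[u];
  return res;
}
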