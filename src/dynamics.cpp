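#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// integer power for Hill exponents (n <= 6 in practice)
static inline double ipow(double b, int n) {
  double r = 1.0;
  while (n-- > 0) r *= b;
  return r;
}

// Batch asynchronous Boolean simulation under the majority rule.
// inits: n_runs x n_nodes matrix of 0/1 initial states.
// act, inh: per-node 0-based regulator index vectors.
// A state is declared converged when no single-node update changes it; one
// uniformly random node is updated per step otherwise. Uses the R RNG.
// [[Rcpp::export]]
List boolean_runs_cpp(IntegerMatrix inits, List act, List inh, int max_steps) {
  const int n_runs = inits.nrow(), n = inits.ncol();
  std::vector< std::vector<int> > A(n), I(n);
  for (int v = 0; v < n; ++v) {
    A[v] = as< std::vector<int> >(act[v]);
    I[v] = as< std::vector<int> >(inh[v]);
  }
  IntegerMatrix finals(n_runs, n);
  LogicalVector converged(n_runs);
  IntegerVector steps_taken(n_runs);
  std::vector<int> x(n);
  for (int r = 0; r < n_runs; ++r) {
    for (int v = 0; v < n; ++v) x[v] = inits(r, v);
    int steps = 0;
    bool fixed = false;
    while (true) {
      // fixed-point test: would any single-node update change the state?
      fixed = true;
      for (int v = 0; v < n && fixed; ++v) {
        int a = 0, i = 0;
        for (size_t j = 0; j < A[v].size(); ++j) a += x[A[v][j]];
        for (size_t j = 0; j < I[v].size(); ++j) i += x[I[v][j]];
        int nv = (a > i) ? 1 : ((i > a) ? 0 : x[v]);
        if (nv != x[v]) fixed = false;
      }
      if (fixed || steps >= max_steps) break;
      int v = (int)(unif_rand() * n);
      if (v == n) v = n - 1;
      int a = 0, i = 0;
      for (size_t j = 0; j < A[v].size(); ++j) a += x[A[v][j]];
      for (size_t j = 0; j < I[v].size(); ++j) i += x[I[v][j]];
      if (a > i) x[v] = 1; else if (i > a) x[v] = 0;
      ++steps;
    }
    for (int v = 0; v < n; ++v) finals(r, v) = x[v];
    converged[r] = fixed;
    steps_taken[r] = steps;
  }
  return List::create(_["finals"] = finals, _["converged"] = converged,
                      _["steps"] = steps_taken);
}

// Forward-Euler integration of the shifted-Hill ODE system from a batch of
// initial conditions.
//   dT/dt = G_T * prod_act[H+(P)/lambda] * prod_inh[H-(N)] - k_T * T
// with H(B) = (B0^n + lam_num * B^n) / (B0^n + B^n), where for activating
// edges the multiplier is pre-divided by lambda (numerator constants below).
// x0: n_ic x n_nodes. Each trajectory stops when max|dx/dt| < tol, and is
// flagged non-converged at t_max otherwise.
//
// Trajectories are advanced in lockstep with node-major, IC-contiguous
// arrays so the per-edge inner loops vectorize; converged ICs are compacted
// out of the active set.
// [[Rcpp::export]]
List racipe_integrate_cpp(NumericMatrix x0, NumericVector G, NumericVector k,
                          IntegerVector esrc, IntegerVector etgt,
                          IntegerVector is_act, NumericVector B0,
                          IntegerVector hilln, NumericVector lambda,
                          double dt, double t_max, double tol) {
  const int n_ic = x0.nrow(), n = x0.ncol(), m = esrc.size();
  const int max_steps = (int)std::ceil(t_max / dt);
  // per-edge constants: multiplier = (c0 + c1 * B^n) / (b0n + B^n)
  std::vector<double> b0n(m), c0(m), c1(m);
  for (int e = 0; e < m; ++e) {
    b0n[e] = ipow(B0[e], hilln[e]);
    if (is_act[e]) { c0[e] = b0n[e] / lambda[e]; c1[e] = 1.0; }
    else           { c0[e] = b0n[e];             c1[e] = lambda[e]; }
  }
  std::vector<double> X((size_t)n * n_ic);     // X[v * n_ic + ic]
  std::vector<int> id(n_ic);                   // original IC index per column
  for (int r = 0; r < n_ic; ++r) {
    id[r] = r;
    for (int v = 0; v < n; ++v) X[(size_t)v * n_ic + r] = x0(r, v);
  }
  NumericMatrix endpoints(n_ic, n);
  LogicalVector converged(n_ic);
  std::vector<double> P((size_t)n * n_ic), maxd(n_ic);
  int active = n_ic;
  for (int s = 0; s < max_steps && active > 0; ++s) {
    std::fill(P.begin(), P.begin() + (size_t)n * active, 1.0);
    for (int e = 0; e < m; ++e) {
      const double *xs = &X[(size_t)esrc[e] * n_ic];
      double *pt = &P[(size_t)etgt[e] * active];
      const double ce0 = c0[e], ce1 = c1[e], be = b0n[e];
      const int ne = hilln[e];
      // P rows are indexed over the active prefix; X rows over full n_ic
      switch (ne) {
      case 1:
        for (int ic = 0; ic < active; ++ic) {
          double bn = xs[ic];
          pt[ic] *= (ce0 + ce1 * bn) / (be + bn);
        }
        break;
      case 2:
        for (int ic = 0; ic < active; ++ic) {
          double b = xs[ic], bn = b * b;
          pt[ic] *= (ce0 + ce1 * bn) / (be + bn);
        }
        break;
      case 3:
        for (int ic = 0; ic < active; ++ic) {
          double b = xs[ic], bn = b * b * b;
          pt[ic] *= (ce0 + ce1 * bn) / (be + bn);
        }
        break;
      case 4:
        for (int ic = 0; ic < active; ++ic) {
          double b2 = xs[ic] * xs[ic], bn = b2 * b2;
          pt[ic] *= (ce0 + ce1 * bn) / (be + bn);
        }
        break;
      case 5:
        for (int ic = 0; ic < active; ++ic) {
          double b = xs[ic], b2 = b * b, bn = b2 * b2 * b;
          pt[ic] *= (ce0 + ce1 * bn) / (be + bn);
        }
        break;
      default:
        for (int ic = 0; ic < active; ++ic) {
          double b2 = xs[ic] * xs[ic], bn = b2 * b2 * b2;
          pt[ic] *= (ce0 + ce1 * bn) / (be + bn);
        }
      }
    }
    std::fill(maxd.begin(), maxd.begin() + active, 0.0);
    for (int v = 0; v < n; ++v) {
      double *xv = &X[(size_t)v * n_ic];
      const double *pv = &P[(size_t)v * active];
      const double gv = G[v], kv = k[v];
      for (int ic = 0; ic < active; ++ic) {
        double d = gv * pv[ic] - kv * xv[ic];
        double a = std::fabs(d);
        if (a > maxd[ic]) maxd[ic] = a;
        xv[ic] += dt * d;
      }
    }
    // retire converged / blown-up trajectories (swap with last active)
    for (int ic = active - 1; ic >= 0; --ic) {
      const double md = maxd[ic];
      const bool blown = !(md < 1e300);  // inf or nan derivative
      if (!(md < tol) && !blown) continue;
      bool fin = !blown;
      for (int v = 0; v < n && fin; ++v)
        if (!std::isfinite(X[(size_t)v * n_ic + ic])) fin = false;
      int r = id[ic];
      for (int v = 0; v < n; ++v) endpoints(r, v) = X[(size_t)v * n_ic + ic];
      converged[r] = fin;
      int last = active - 1;
      if (ic != last) {
        for (int v = 0; v < n; ++v)
          X[(size_t)v * n_ic + ic] = X[(size_t)v * n_ic + last];
        id[ic] = id[last];
      }
      --active;
    }
  }
  // anything still active hit the horizon: non-converged
  for (int ic = 0; ic < active; ++ic) {
    int r = id[ic];
    for (int v = 0; v < n; ++v) endpoints(r, v) = X[(size_t)v * n_ic + ic];
    converged[r] = false;
  }
  return List::create(_["endpoints"] = endpoints, _["converged"] = converged);
}
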