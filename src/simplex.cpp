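#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

// Dense bounded-variable two-phase primal simplex.
//
// Solves   maximize c'x   s.t.  A x = b,  l <= x <= u
// with finite bounds (callers clamp "unbounded" to a large finite value).
// Explicit basis-inverse updates (O(m^2) per pivot); Dantzig pricing with a
// Bland's-rule fallback to escape degenerate cycling. FBA problems (S v = 0)
// are heavily degenerate, so the anti-cycling fallback is load-bearing.

namespace {

const double kPivTol  = 1e-9;   // minimum admissible pivot magnitude
const double kDualTol = 1e-7;   // reduced-cost optimality tolerance
const double kFeasTol = 1e-7;   // phase-1 infeasibility tolerance

struct Simplex {
  int m, n, ntot;               // rows, structural cols, cols incl. artificials
  std::vector<double> A;        // column-major m x ntot
  std::vector<double> b, l, u, c;
  std::vector<double> Binv;     // column-major m x m
  std::vector<int> basis;       // basis[i] = column basic in row i
  std::vector<int> stat;        // nonbasic status: 0 basic, -1 at lower, +1 at upper
  std::vector<double> x;

  double colA(int i, int j) const { return A[(size_t)j * m + i]; }

  void computeBasicValues() {
    // x_B = Binv (b - A_N x_N)
    std::vector<double> r(m);
    for (int i = 0; i < m; ++i) r[i] = b[i];
    for (int j = 0; j < ntot; ++j) {
      if (stat[j] == 0 || x[j] == 0.0) continue;
      const double xj = x[j];
      const double* col = &A[(size_t)j * m];
      for (int i = 0; i < m; ++i) r[i] -= col[i] * xj;
    }
    for (int i = 0; i < m; ++i) {
      double s = 0.0;
      for (int k = 0; k < m; ++k) s += Binv[(size_t)k * m + i] * r[k];
      x[basis[i]] = s;
    }
  }

  // one simplex phase on objective coefficients obj; returns 0 ok, 1 unbounded, 2 iteration limit
  int iterate(const std::vector<double>& obj, int maxit) {
    std::vector<double> y(m), w(m);
    int it = 0, blandAfter = maxit / 2;
    while (it++ < maxit) {
      bool bland = it > blandAfter;
      // duals y' = c_B' Binv
      for (int i = 0; i < m; ++i) {
        double s = 0.0;
        for (int k = 0; k < m; ++k) s += obj[basis[k]] * Binv[(size_t)i * m + k];
        y[i] = s;
      }
      // pricing
      int enter = -1; double best = 0.0; int dir = 0;
      for (int j = 0; j < ntot; ++j) {
        if (stat[j] == 0) continue;
        if (l[j] == u[j]) continue;           // fixed variable can never improve
        const double* col = &A[(size_t)j * m];
        double d = obj[j];
        for (int i = 0; i < m; ++i) d -= y[i] * col[i];
        double viol = 0.0; int dj = 0;
        if (stat[j] < 0 && d > kDualTol)      { viol = d;  dj = +1; }
        else if (stat[j] > 0 && d < -kDualTol){ viol = -d; dj = -1; }
        else continue;
        if (bland) { enter = j; dir = dj; break; }
        if (viol > best) { best = viol; enter = j; dir = dj; }
      }
      if (enter < 0) return 0;                // optimal
      // w = Binv A_enter
      {
        const double* col = &A[(size_t)enter * m];
        for (int i = 0; i < m; ++i) {
          double s = 0.0;
          for (int k = 0; k < m; ++k) s += Binv[(size_t)k * m + i] * col[k];
          w[i] = s;
        }
      }
      // ratio test: entering moves by t >= 0 in direction dir
      double tmax = u[enter] - l[enter];      // bound-flip limit
      int leave = -1; double leaveBound = 0.0;
      for (int i = 0; i < m; ++i) {
        double delta = dir * w[i];            // x_{B_i} changes by -delta * t
        double t;
        int bi = basis[i];
        if (delta > kPivTol)       t = (x[bi] - l[bi]) / delta;
        else if (delta < -kPivTol) t = (u[bi] - x[bi]) / (-delta);
        else continue;
        if (t < 0) t = 0;                     // roundoff below a bound
        if (t < tmax - 1e-12) {
          tmax = t; leave = i;
          leaveBound = (delta > 0) ? l[bi] : u[bi];
        }
      }
      if (tmax > 1e30) return 1;              // unbounded
      if (tmax < 0) tmax = 0;
      if (leave < 0) {
        // bound flip
        for (int i = 0; i < m; ++i) x[basis[i]] -= dir * w[i] * tmax;
        x[enter] = (dir > 0) ? u[enter] : l[enter];
        stat[enter] = (dir > 0) ? +1 : -1;
        continue;
      }
      // pivot
      for (int i = 0; i < m; ++i) x[basis[i]] -= dir * w[i] * tmax;
      x[enter] += dir * tmax;
      int out = basis[leave];
      x[out] = leaveBound;
      stat[out] = (std::fabs(leaveBound - l[out]) <= std::fabs(leaveBound - u[out])) ? -1 : +1;
      stat[enter] = 0;
      basis[leave] = enter;
      // Binv update: eliminate column 'enter' from all rows but 'leave'
      double piv = w[leave];
      for (int cc = 0; cc < m; ++cc) {
        double* col = &Binv[(size_t)cc * m];
        double pr = col[leave] / piv;
        col[leave] = pr;
        for (int i = 0; i < m; ++i) {
          if (i == leave) continue;
          col[i] -= w[i] * pr;
        }
      }
      if (it % 64 == 0) computeBasicValues(); // periodic refresh against drift
    }
    return 2;
  }
};

} // namespace

// [[Rcpp::export(name = ".simplex_lp")]]
Rcpp::List simplex_lp(Rcpp::NumericMatrix Amat, Rcpp::NumericVector bvec,
                      Rcpp::NumericVector cvec, Rcpp::NumericVector lb,
                      Rcpp::NumericVector ub, int maxit = 20000) {
  int m = Amat.nrow(), n = Amat.ncol();
  Simplex sx;
  sx.m = m; sx.n = n; sx.ntot = n + m;
  sx.A.assign((size_t)sx.ntot * m, 0.0);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < m; ++i) sx.A[(size_t)j * m + i] = Amat(i, j);
  sx.b.assign(bvec.begin(), bvec.end());
  sx.l.assign(lb.begin(), lb.end());
  sx.u.assign(ub.begin(), ub.end());
  sx.c.assign(cvec.begin(), cvec.end());
  sx.l.resize(sx.ntot); sx.u.resize(sx.ntot); sx.c.resize(sx.ntot);
  sx.x.assign(sx.ntot, 0.0);
  sx.stat.assign(sx.ntot, -1);
  sx.basis.resize(m);
  sx.Binv.assign((size_t)m * m, 0.0);

  for (int j = 0; j < n; ++j) {
    if (sx.l[j] > sx.u[j] + 1e-12)
      return Rcpp::List::create(Rcpp::Named("status") = "infeasible",
                                Rcpp::Named("objective") = 0.0,
                                Rcpp::Named("x") = Rcpp::NumericVector(n));
    // start at the bound closest to zero
    double v = (std::fabs(sx.l[j]) <= std::fabs(sx.u[j])) ? sx.l[j] : sx.u[j];
    sx.x[j] = v;
    sx.stat[j] = (v == sx.l[j]) ? -1 : +1;
  }
  // residual and artificial columns
  std::vector<double> r(m);
  for (int i = 0; i < m; ++i) {
    double s = sx.b[i];
    for (int j = 0; j < n; ++j) s -= sx.colA(i, j) * sx.x[j];
    r[i] = s;
  }
  std::vector<double> phase1(sx.ntot, 0.0);
  for (int i = 0; i < m; ++i) {
    int j = n + i;
    sx.A[(size_t)j * m + i] = (r[i] >= 0) ? 1.0 : -1.0;
    sx.l[j] = 0.0; sx.u[j] = std::numeric_limits<double>::infinity();
    sx.c[j] = 0.0; phase1[j] = -1.0;          // maximize -sum(artificials)
    sx.x[j] = std::fabs(r[i]);
    sx.stat[j] = 0;
    sx.basis[i] = j;
    sx.Binv[(size_t)i * m + i] = (r[i] >= 0) ? 1.0 : -1.0;
  }

  bool needPhase1 = false;
  for (int i = 0; i < m; ++i) if (std::fabs(r[i]) > kFeasTol) { needPhase1 = true; break; }
  if (needPhase1) {
    int rc = sx.iterate(phase1, maxit);
    double infeas = 0.0;
    for (int i = 0; i < m; ++i) { int bi = sx.basis[i]; if (bi >= n) infeas += sx.x[bi]; }
    if (rc == 2 || infeas > 1e-6)
      return Rcpp::List::create(Rcpp::Named("status") = "infeasible",
                                Rcpp::Named("objective") = 0.0,
                                Rcpp::Named("x") = Rcpp::NumericVector(n));
  }
  // freeze artificials at zero for phase 2
  for (int i = 0; i < m; ++i) { sx.l[n + i] = 0.0; sx.u[n + i] = 0.0; }
  for (int j = n; j < sx.ntot; ++j) if (sx.stat[j] != 0) sx.x[j] = 0.0;
  sx.computeBasicValues();

  int rc = sx.iterate(sx.c, maxit);
  if (rc == 1)
    return Rcpp::List::create(Rcpp::Named("status") = "unbounded",
                              Rcpp::Named("objective") = R_PosInf,
                              Rcpp::Named("x") = Rcpp::NumericVector(n));
  if (rc == 2)
    return Rcpp::List::create(Rcpp::Named("status") = "maxit",
                              Rcpp::Named("objective") = R_NegInf,
                              Rcpp::Named("x") = Rcpp::NumericVector(n));
  double obj = 0.0;
  Rcpp::NumericVector xout(n);
  for (int j = 0; j < n; ++j) { xout[j] = sx.x[j]; obj += sx.c[j] * sx.x[j]; }
  return Rcpp::List::create(Rcpp::Named("status") = "optimal",
                            Rcpp::Named("objective") = obj,
                            Rcpp::Named("x") = xout);
}
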