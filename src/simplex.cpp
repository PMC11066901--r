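#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// Bounded-variable primal simplex for
//   maximize c'x  subject to  A x = b,  lb <= x <= ub
// Two phases with explicit artificial variables; dense basis inverse kept
// up to date by pivoting. Dantzig pricing with a Bland's-rule fallback once
// degenerate pivots accumulate, so the method cannot cycle. Variables may
// have one infinite bound (or be free, held nonbasic at zero).
//
// Problem sizes here are small (metabolic toy networks, a few hundred
// variables at most), so dense O(m^2) updates are the right trade-off.

static const double INF = std::numeric_limits<double>::infinity();

enum VStatus { AT_LOWER = 0, AT_UPPER = 1, BASIC = 2, FREE_NB = 3 };

struct SimplexProblem {
  int m, n, N;              // rows, structural cols, total cols (n + m artificials)
  std::vector<double> A;    // column-major m x n structural matrix
  std::vector<double> b;
  std::vector<double> lo, up, x;
  std::vector<int> status;
  std::vector<int> basis;           // basis[i] = column index basic in row i
  std::vector<double> Binv;         // m x m row-major
  std::vector<int> art_sign;        // +1/-1 sign of artificial column i
  double tol;

  double Acol(int j, int i) const { // entry (i, j) of the full column set
    if (j < n) return A[(size_t)j * m + i];
    return (j - n == i) ? (double)art_sign[i] : 0.0;
  }
};

// alpha = Binv * A_j
static void ftran(const SimplexProblem &P, int j, std::vector<double> &alpha) {
  const int m = P.m;
  if (j >= P.n) { // artificial: Binv column times sign
    int i0 = j - P.n;
    for (int i = 0; i < m; ++i)
      alpha[i] = P.Binv[(size_t)i * m + i0] * P.art_sign[i0];
    return;
  }
  for (int i = 0; i < m; ++i) {
    double s = 0.0;
    const double *Bi = &P.Binv[(size_t)i * m];
    const double *Aj = &P.A[(size_t)j * m];
    for (int k = 0; k < m; ++k) s += Bi[k] * Aj[k];
    alpha[i] = s;
  }
}

// y = c_B' * Binv
static void btran(const SimplexProblem &P, const std::vector<double> &c,
                  std::vector<double> &y) {
  const int m = P.m;
  for (int k = 0; k < m; ++k) {
    double s = 0.0;
    for (int i = 0; i < m; ++i) {
      double cb = c[P.basis[i]];
      if (cb != 0.0) s += cb * P.Binv[(size_t)i * m + k];
    }
    y[k] = s;
  }
}

static double reduced_cost(const SimplexProblem &P, const std::vector<double> &c,
                           const std::vector<double> &y, int j) {
  double d = c[j];
  if (j >= P.n) {
    d -= y[j - P.n] * P.art_sign[j - P.n];
  } else {
    const double *col = &P.A[(size_t)j * P.m];
    for (int i = 0; i < P.m; ++i) d -= y[i] * col[i];
  }
  return d;
}

// One simplex run with objective c over current basis/x. Returns:
// 0 optimal, 2 unbounded, 3 iteration limit.
static int simplex_iterate(SimplexProblem &P, const std::vector<double> &c,
                           long maxit) {
  const int m = P.m, N = P.N;
  std::vector<double> y(m), alpha(m);
  long it = 0;
  int degen = 0;
  bool bland = false;

  while (it++ < maxit) {
    btran(P, c, y);

    // --- pricing ---
    int q = -1, dir = 0;
    double best = P.tol;
    for (int j = 0; j < N; ++j) {
      int st = P.status[j];
      if (st == BASIC) continue;
      if (P.up[j] - P.lo[j] <= 0.0) continue;   // fixed, cannot move
      double d = reduced_cost(P, c, y, j);
      int dj = 0;
      double viol = 0.0;
      if (st == AT_LOWER && d > P.tol) { dj = +1; viol = d; }
      else if (st == AT_UPPER && d < -P.tol) { dj = -1; viol = -d; }
      else if (st == FREE_NB && std::fabs(d) > P.tol) {
        dj = d > 0 ? +1 : -1; viol = std::fabs(d);
      }
      if (dj != 0) {
        if (bland) { q = j; dir = dj; break; }      // first index
        if (viol > best) { best = viol; q = j; dir = dj; }
      }
    }
    if (q < 0) return 0; // optimal

    ftran(P, q, alpha);

    // --- ratio test ---
    double tmax = (P.lo[q] > -INF && P.up[q] < INF) ? (P.up[q] - P.lo[q]) : INF;
    int rmin = -1;            // blocking row, -1 = entering variable's own bound
    int leave_to = AT_LOWER;  // where the leaving variable goes
    for (int i = 0; i < m; ++i) {
      double delta = -dir * alpha[i];  // change of x_basis[i] per unit t
      int bj = P.basis[i];
      double t; int to;
      if (delta < -P.tol) {
        if (P.lo[bj] <= -INF) continue;
        t = (P.x[bj] - P.lo[bj]) / (-delta);
        to = AT_LOWER;
      } else if (delta > P.tol) {
        if (P.up[bj] >= INF) continue;
        t = (P.up[bj] - P.x[bj]) / delta;
        to = AT_UPPER;
      } else continue;
      if (t < 0) t = 0;
      bool take = (t < tmax - P.tol) ||
                  (t < tmax + P.tol && rmin >= 0 && bj < P.basis[rmin]);
      if (take) {
        tmax = std::min(t, tmax); rmin = i; leave_to = to;
      }
    }
    if (tmax >= INF) return 2; // unbounded
    if (tmax < 0) tmax = 0;

    // --- update primal values ---
    P.x[q] += dir * tmax;
    for (int i = 0; i < m; ++i) P.x[P.basis[i]] -= dir * tmax * alpha[i];

    if (tmax <= P.tol) { if (++degen > 40) bland = true; }
    else { degen = 0; bland = false; }

    if (rmin < 0) {
      // entering variable ran to its other bound: bound flip, basis unchanged
      P.status[q] = (dir > 0) ? AT_UPPER : AT_LOWER;
      continue;
    }

    // --- pivot: q enters, basis[rmin] leaves ---
    int lv = P.basis[rmin];
    P.status[lv] = leave_to;
    P.x[lv] = (leave_to == AT_LOWER) ? P.lo[lv] : P.up[lv];
    P.status[q] = BASIC;
    P.basis[rmin] = q;

    double piv = alpha[rmin];
    double *Br = &P.Binv[(size_t)rmin * m];
    for (int k = 0; k < m; ++k) Br[k] /= piv;
    for (int i = 0; i < m; ++i) {
      if (i == rmin) continue;
      double f = alpha[i];
      if (f == 0.0) continue;
      double *Bi = &P.Binv[(size_t)i * m];
      for (int k = 0; k < m; ++k) Bi[k] -= f * Br[k];
    }
  }
  return 3;
}

// [[Rcpp::export(name = ".simplex_solve")]]
List simplex_solve(NumericMatrix Amat, NumericVector bvec, NumericVector cvec,
                   NumericVector lbv, NumericVector ubv,
                   double tol = 1e-9, double maxit = 0) {
  int m = Amat.nrow(), n = Amat.ncol();
  if (bvec.size() != m || cvec.size() != n || lbv.size() != n || ubv.size() != n)
    stop("inconsistent LP dimensions");

  SimplexProblem P;
  P.m = m; P.n = n; P.N = n + m; P.tol = tol;
  P.A.assign(Amat.begin(), Amat.end()); // column-major, matches layout used above
  P.b.assign(bvec.begin(), bvec.end());
  P.lo.assign(P.N, 0.0); P.up.assign(P.N, 0.0);
  P.x.assign(P.N, 0.0);
  P.status.assign(P.N, AT_LOWER);
  for (int j = 0; j < n; ++j) {
    double l = lbv[j], u = ubv[j];
    if (!(l <= u)) stop("lb > ub for variable %d", j + 1);
    P.lo[j] = l; P.up[j] = u;
    if (l > -INF && u < INF) {
      if (std::fabs(l) <= std::fabs(u)) { P.status[j] = AT_LOWER; P.x[j] = l; }
      else { P.status[j] = AT_UPPER; P.x[j] = u; }
    } else if (l > -INF) { P.status[j] = AT_LOWER; P.x[j] = l; }
    else if (u < INF)    { P.status[j] = AT_UPPER; P.x[j] = u; }
    else                 { P.status[j] = FREE_NB;  P.x[j] = 0.0; }
  }

  // residual -> artificial variables form the initial basis
  P.art_sign.assign(m, 1);
  P.basis.resize(m);
  P.Binv.assign((size_t)m * m, 0.0);
  for (int i = 0; i < m; ++i) {
    double r = P.b[i];
    for (int j = 0; j < n; ++j) r -= P.A[(size_t)j * m + i] * P.x[j];
    P.art_sign[i] = (r >= 0) ? 1 : -1;
    int aj = n + i;
    P.lo[aj] = 0.0; P.up[aj] = INF;
    P.x[aj] = std::fabs(r);
    P.status[aj] = BASIC;
    P.basis[i] = aj;
    // basis column of artificial i is e_i * sign, so Binv = diag(sign)
    P.Binv[(size_t)i * m + i] = (double)P.art_sign[i];
  }

  long itmax = (maxit > 0) ? (long)maxit : 2000 + 200L * (long)P.N;

  // Phase 1: maximize -(sum of artificials)
  std::vector<double> c1(P.N, 0.0);
  for (int i = 0; i < m; ++i) c1[n + i] = -1.0;
  int st1 = simplex_iterate(P, c1, itmax);
  double infeas = 0.0;
  for (int i = 0; i < m; ++i) infeas += P.x[n + i];
  if (st1 == 3)
    return List::create(_["status"] = "maxiter", _["x"] = R_NilValue,
                        _["objval"] = R_NilValue);
  if (infeas > std::max(1e-7, tol * 100))
    return List::create(_["status"] = "infeasible", _["x"] = R_NilValue,
                        _["objval"] = R_NilValue);

  // pin artificials to zero so they never re-enter; drive basic ones out
  std::vector<double> alpha(m);
  for (int i = 0; i < m; ++i) { P.lo[n + i] = 0.0; P.up[n + i] = 0.0; }
  for (int i = 0; i < m; ++i) {
    if (P.basis[i] < n) continue;
    int found = -1;
    for (int j = 0; j < n; ++j) {
      if (P.status[j] == BASIC) continue;
      ftran(P, j, alpha);
      if (std::fabs(alpha[i]) > 1e-7) { found = j; break; }
    }
    if (found >= 0) {
      ftran(P, found, alpha);
      int lv = P.basis[i];
      P.status[lv] = AT_LOWER; P.x[lv] = 0.0;
      P.status[found] = BASIC; P.basis[i] = found;
      // x unchanged: pivoting a zero-valued artificial out is degenerate
      double piv = alpha[i];
      double *Br = &P.Binv[(size_t)i * m];
      for (int k = 0; k < m; ++k) Br[k] /= piv;
      for (int r = 0; r < m; ++r) {
        if (r == i) continue;
        double f = alpha[r];
        if (f == 0.0) continue;
        double *Bi = &P.Binv[(size_t)r * m];
        for (int k = 0; k < m; ++k) Bi[k] -= f * Br[k];
      }
    }
    // else: redundant row; artificial stays basic, pinned at 0
  }

  // Phase 2
  std::vector<double> c2(P.N, 0.0);
  for (int j = 0; j < n; ++j) c2[j] = cvec[j];
  int st2 = simplex_iterate(P, c2, itmax);
  if (st2 == 3)
    return List::create(_["status"] = "maxiter", _["x"] = R_NilValue,
                        _["objval"] = R_NilValue);
  if (st2 == 2)
    return List::create(_["status"] = "unbounded", _["x"] = R_NilValue,
                        _["objval"] = R_NilValue);

  NumericVector x(n);
  double z = 0.0;
  for (int j = 0; j < n; ++j) { x[j] = P.x[j]; z += cvec[j] * P.x[j]; }
  return List::create(_["status"] = "optimal", _["x"] = x, _["objval"] = z);
}
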