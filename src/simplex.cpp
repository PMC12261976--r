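#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Dense tableau simplex for the weighted-hinge + L1 linear program
//
//   min  sum_i v_i xi_i + sum_j lam_j (u_j + w_j)
//   s.t. xi_i + Z_i (u - w) - s_i = 1,   xi, u, w, s >= 0
//
// (theta = u - w; Z_i is the i-th label-adjusted feature row).  The slack
// point xi = 1, u = w = 0 is an immediate basic feasible solution, and all
// costs are nonnegative so the program is bounded below by 0 and can never
// be unbounded.  Entering rule: Dantzig (most negative reduced cost) with a
// switch to Bland's rule after a fixed number of pivots to rule out cycling
// on this highly degenerate problem class.
//
// [[Rcpp::export]]
List hinge_l1_lp_cpp(NumericMatrix Z, NumericVector v, NumericVector lam,
                     int maxit = 0, double tol = 1e-9) {
  const int m = Z.nrow(), d = Z.ncol();
  const int N = 2 * m + 2 * d;          // xi | u | w | s
  if (maxit <= 0) maxit = 200 * (m + d);
  const int bland_after = 20 * (m + d);

  std::vector<std::vector<double> > tab(m, std::vector<double>(N + 1, 0.0));
  for (int i = 0; i < m; ++i) {
    tab[i][i] = 1.0;                                   // xi_i
    for (int j = 0; j < d; ++j) {
      tab[i][m + j] = Z(i, j);                         // u_j
      tab[i][m + d + j] = -Z(i, j);                    // w_j
    }
    tab[i][m + 2 * d + i] = -1.0;                      // surplus s_i
    tab[i][N] = 1.0;                                   // rhs
  }
  std::vector<double> cost(N, 0.0);
  for (int i = 0; i < m; ++i) cost[i] = v[i];
  for (int j = 0; j < d; ++j) cost[m + j] = cost[m + d + j] = lam[j];

  // reduced costs relative to the initial xi basis
  std::vector<double> cbar(N + 1, 0.0);
  for (int j = 0; j <= N; ++j) {
    double acc = 0.0;
    for (int i = 0; i < m; ++i) acc += v[i] * tab[i][j];
    cbar[j] = (j < N ? cost[j] : 0.0) - acc;           // cbar[N] = -objective
  }
  std::vector<int> basis(m);
  for (int i = 0; i < m; ++i) basis[i] = i;

  int status = 2;  // 0 optimal, 1 unbounded, 2 iteration limit
  int it = 0;
  for (it = 0; it < maxit; ++it) {
    // entering column
    int q = -1;
    if (it < bland_after) {
      double best = -tol;
      for (int j = 0; j < N; ++j)
        if (cbar[j] < best) { best = cbar[j]; q = j; }
    } else {
      for (int j = 0; j < N; ++j)
        if (cbar[j] < -tol) { q = j; break; }
    }
    if (q < 0) { status = 0; break; }

    // ratio test; ties resolved toward the smallest basis index
    int r = -1;
    double bestratio = 0.0;
    for (int i = 0; i < m; ++i) {
      const double piv = tab[i][q];
      if (piv > tol) {
        const double ratio = tab[i][N] / piv;
        if (r < 0 || ratio < bestratio - tol ||
            (ratio < bestratio + tol && basis[i] < basis[r])) {
          r = i; bestratio = ratio;
        }
      }
    }
    if (r < 0) { status = 1; break; }   // unbounded (cannot occur here)

    // pivot
    const double piv = tab[r][q];
    for (int j = 0; j <= N; ++j) tab[r][j] /= piv;
    for (int i = 0; i < m; ++i) {
      if (i == r) continue;
      const double f = tab[i][q];
      if (f != 0.0)
        for (int j = 0; j <= N; ++j) tab[i][j] -= f * tab[r][j];
    }
    const double f = cbar[q];
    if (f != 0.0)
      for (int j = 0; j <= N; ++j) cbar[j] -= f * tab[r][j];
    basis[r] = q;
  }

  NumericVector theta(d);
  for (int i = 0; i < m; ++i) {
    const int b = basis[i];
    if (b >= m && b < m + d) theta[b - m] += tab[i][N];
    else if (b >= m + d && b < m + 2 * d) theta[b - m - d] -= tab[i][N];
  }
  return List::create(_["theta"] = theta,
                      _["objective"] = -cbar[N],
                      _["status"] = status,
                      _["iterations"] = it);
}
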