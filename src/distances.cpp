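#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double euclid(double x1, double y1, double x2, double y2) {
  double dx = x1 - x2, dy = y1 - y2;
  return std::sqrt(dx * dx + dy * dy);
}

// Directed average distance: mean over rows of A of the Euclidean distance
// to the nearest row of B.  A and B are (birth, death) matrices.
static double dir_avg(const NumericMatrix& A, const NumericMatrix& B) {
  double s = 0.0;
  for (int i = 0; i < A.nrow(); ++i) {
    double best = R_PosInf;
    for (int j = 0; j < B.nrow(); ++j) {
      double d = euclid(A(i, 0), A(i, 1), B(j, 0), B(j, 1));
      if (d < best) best = d;
    }
    s += best;
  }
  return s / A.nrow();
}

static double dir_sup(const NumericMatrix& A, const NumericMatrix& B) {
  double worst = 0.0;
  for (int i = 0; i < A.nrow(); ++i) {
    double best = R_PosInf;
    for (int j = 0; j < B.nrow(); ++j) {
      double d = euclid(A(i, 0), A(i, 1), B(j, 0), B(j, 1));
      if (d < best) best = d;
    }
    if (best > worst) worst = best;
  }
  return worst;
}

// Euclidean distance from a diagram point to the diagonal y = x, used when
// exactly one diagram is empty (the diagonal is the "nothing happened"
// reference).
static inline double diag_euclid(double b, double d) {
  return std::fabs(d - b) / std::sqrt(2.0);
}

// [[Rcpp::export]]
double cpp_dmh(NumericMatrix A, NumericMatrix B) {
  if (A.nrow() == 0 && B.nrow() == 0) return 0.0;
  if (A.nrow() == 0 || B.nrow() == 0) {
    const NumericMatrix& P = A.nrow() == 0 ? B : A;
    double s = 0.0;
    for (int i = 0; i < P.nrow(); ++i) s += diag_euclid(P(i, 0), P(i, 1));
    return s / P.nrow();
  }
  return std::max(dir_avg(A, B), dir_avg(B, A));
}

// [[Rcpp::export]]
double cpp_hausdorff(NumericMatrix A, NumericMatrix B) {
  if (A.nrow() == 0 && B.nrow() == 0) return 0.0;
  if (A.nrow() == 0 || B.nrow() == 0) {
    const NumericMatrix& P = A.nrow() == 0 ? B : A;
    double worst = 0.0;
    for (int i = 0; i < P.nrow(); ++i)
      worst = std::max(worst, diag_euclid(P(i, 0), P(i, 1)));
    return worst;
  }
  return std::max(dir_sup(A, B), dir_sup(B, A));
}

// Exact O(n^3) rectangular Hungarian algorithm (potentials / shortest
// augmenting paths) on a square cost matrix stored row-major.
static double hungarian(const std::vector<double>& a, int n) {
  if (n == 0) return 0.0;
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0), minv(n + 1);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::fill(minv.begin(), minv.end(), R_PosInf);
    std::vector<char> used(n + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      double delta = R_PosInf;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double cur = a[(i0 - 1) * n + (j - 1)] - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  double cost = 0.0;
  for (int j = 1; j <= n; ++j) cost += a[(p[j] - 1) * n + (j - 1)];
  return cost;
}

// q-Wasserstein distance between diagrams with the L-infinity ground metric
// and diagonal augmentation: every point of either diagram may instead be
// matched to its nearest diagonal point at cost (death - birth)/2.  The
// (nA+nB) x (nA+nB) augmented cost matrix carries cost^q; the optimal
// assignment cost is returned as (sum cost^q)^(1/q).
// [[Rcpp::export]]
double cpp_wasserstein(NumericMatrix A, NumericMatrix B, double q) {
  if (q < 1) stop("Wasserstein order q must be >= 1");
  const int na = A.nrow(), nb = B.nrow(), n = na + nb;
  if (n == 0) return 0.0;
  std::vector<double> cost((size_t)n * n, 0.0);
  for (int i = 0; i < na; ++i) {
    double pa = std::fabs(A(i, 1) - A(i, 0)) / 2.0;  // L-inf distance to diagonal
    for (int j = 0; j < nb; ++j) {
      double d = std::max(std::fabs(A(i, 0) - B(j, 0)), std::fabs(A(i, 1) - B(j, 1)));
      cost[(size_t)i * n + j] = std::pow(d, q);
    }
    for (int j = nb; j < n; ++j) cost[(size_t)i * n + j] = std::pow(pa, q);
  }
  for (int i = na; i < n; ++i) {
    for (int j = 0; j < nb; ++j) {
      double pb = std::fabs(B(j, 1) - B(j, 0)) / 2.0;
      cost[(size_t)i * n + j] = std::pow(pb, q);
    }
    // diagonal-to-diagonal matches cost nothing (already zero)
  }
  return std::pow(hungarian(cost, n), 1.0 / q);
}

// Window-by-window distance between two equally long diagram sequences.
// metric: 0 = modified Hausdorff, 1 = Hausdorff, 2 = q-Wasserstein.
// [[Rcpp::export]]
NumericVector cpp_distance_signal(List A, List B, int metric, double q) {
  const R_xlen_t n = A.size();
  if (B.size() != n) stop("diagram sequences have different lengths");
  NumericVector out(n);
  for (R_xlen_t k = 0; k < n; ++k) {
    NumericMatrix a = A[k], b = B[k];
    if (metric == 0) out[k] = cpp_dmh(a, b);
    else if (metric == 1) out[k] = cpp_hausdorff(a, b);
    else out[k] = cpp_wasserstein(a, b, q);
  }
  return out;
}
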