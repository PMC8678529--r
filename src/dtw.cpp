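#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Dynamic-time-warping core. Symmetric step pattern (weights 1,1,1), no
// warping window, no path-length normalization: all compared slots have equal
// length, so normalization would only rescale distances.
//
// Two multivariate modes:
//   dependent   - one DP over time, local cost = Euclidean norm across columns
//   independent - univariate DP per column, distances summed
// Ties in the DP step choice are broken preferring the diagonal step; this
// affects only the reported warp path, never the distance.

static double dtw_uni(const double* a, int n, const double* b, int m) {
  std::vector<double> prev(m), cur(m);
  prev[0] = std::fabs(a[0] - b[0]);
  for (int j = 1; j < m; ++j) prev[j] = prev[j - 1] + std::fabs(a[0] - b[j]);
  for (int i = 1; i < n; ++i) {
    const double ai = a[i];
    cur[0] = prev[0] + std::fabs(ai - b[0]);
    for (int j = 1; j < m; ++j) {
      double best = prev[j - 1];                 // diagonal
      if (prev[j] < best) best = prev[j];        // insertion
      if (cur[j - 1] < best) best = cur[j - 1];  // deletion
      cur[j] = best + std::fabs(ai - b[j]);
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}

static double local_cost_dep(const NumericMatrix& A, const NumericMatrix& B,
                             int i, int j) {
  double s = 0.0;
  const int p = A.ncol();
  for (int v = 0; v < p; ++v) {
    const double d = A(i, v) - B(j, v);
    s += d * d;
  }
  return std::sqrt(s);
}

static double dtw_dep(const NumericMatrix& A, const NumericMatrix& B) {
  const int n = A.nrow(), m = B.nrow();
  std::vector<double> prev(m), cur(m);
  prev[0] = local_cost_dep(A, B, 0, 0);
  for (int j = 1; j < m; ++j) prev[j] = prev[j - 1] + local_cost_dep(A, B, 0, j);
  for (int i = 1; i < n; ++i) {
    cur[0] = prev[0] + local_cost_dep(A, B, i, 0);
    for (int j = 1; j < m; ++j) {
      double best = prev[j - 1];
      if (prev[j] < best) best = prev[j];
      if (cur[j - 1] < best) best = cur[j - 1];
      cur[j] = best + local_cost_dep(A, B, i, j);
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}

// [[Rcpp::export]]
double cpp_dtw_distance(NumericMatrix A, NumericMatrix B, bool dependent) {
  if (A.ncol() != B.ncol())
    stop("variable-count mismatch: %d vs %d", A.ncol(), B.ncol());
  if (A.nrow() == 0 || B.nrow() == 0) stop("empty sequence");
  if (dependent) return dtw_dep(A, B);
  double total = 0.0;
  for (int v = 0; v < A.ncol(); ++v)
    total += dtw_uni(&A(0, v), A.nrow(), &B(0, v), B.nrow());
  return total;
}

// [[Rcpp::export]]
NumericMatrix cpp_dtw_matrix(List slots, bool dependent) {
  const int n = slots.size();
  NumericMatrix D(n, n);
  std::vector<NumericMatrix> mats;
  mats.reserve(n);
  for (int i = 0; i < n; ++i) mats.push_back(as<NumericMatrix>(slots[i]));
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double d = cpp_dtw_distance(mats[i], mats[j], dependent);
      D(i, j) = d;
      D(j, i) = d;
    }
    Rcpp::checkUserInterrupt();
  }
  return D;
}

// Full DP with backtracking; returns the optimal warp path as 1-based (i, j)
// pairs, ordered from (1, 1) to (n, m). Diagonal preferred on ties.
// [[Rcpp::export]]
IntegerMatrix cpp_dtw_path(NumericMatrix A, NumericMatrix B, bool dependent) {
  if (A.ncol() != B.ncol()) stop("variable-count mismatch");
  const int n = A.nrow(), m = B.nrow();
  if (n == 0 || m == 0) stop("empty sequence");
  if (!dependent && A.ncol() > 1)
    stop("a single warp path is only defined for dependent alignment or one variable");
  std::vector<double> C((size_t)n * m);
  auto cost = [&](int i, int j) { return local_cost_dep(A, B, i, j); };
  C[0] = cost(0, 0);
  for (int j = 1; j < m; ++j) C[(size_t)j] = C[(size_t)j - 1] + cost(0, j);
  for (int i = 1; i < n; ++i) {
    C[(size_t)i * m] = C[(size_t)(i - 1) * m] + cost(i, 0);
    for (int j = 1; j < m; ++j) {
      double best = C[(size_t)(i - 1) * m + j - 1];
      const double up = C[(size_t)(i - 1) * m + j];
      const double left = C[(size_t)i * m + j - 1];
      if (up < best) best = up;
      if (left < best) best = left;
      C[(size_t)i * m + j] = best + cost(i, j);
    }
  }
  std::vector<std::pair<int, int>> rev;
  int i = n - 1, j = m - 1;
  rev.emplace_back(i, j);
  while (i > 0 || j > 0) {
    if (i == 0) { --j; }
    else if (j == 0) { --i; }
    else {
      const double diag = C[(size_t)(i - 1) * m + j - 1];
      const double up = C[(size_t)(i - 1) * m + j];
      const double left = C[(size_t)i * m + j - 1];
      if (diag <= up && diag <= left) { --i; --j; }
      else if (up <= left) { --i; }
      else { --j; }
    }
    rev.emplace_back(i, j);
  }
  IntegerMatrix P(rev.size(), 2);
  for (size_t k = 0; k < rev.size(); ++k) {
    P(k, 0) = rev[rev.size() - 1 - k].first + 1;
    P(k, 1) = rev[rev.size() - 1 - k].second + 1;
  }
  return P;
}
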