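#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Dynamic time warping by the standard cumulative-cost recursion.
// Local cost is |x_i - y_j|; admissible moves are (i-1,j-1), (i-1,j),
// (i,j-1); boundary conditions pin the path to (1,1) and (n,m).
// `window` < 0 means no Sakoe-Chiba band. When `normalize` is true the
// cumulative cost is divided by the length (number of lattice points) of
// one optimal path, recovered by backtracking with a fixed tie order
// (diagonal, then vertical, then horizontal) so results are deterministic.
// Fast path: rolling two-row DP, used when only the cumulative cost is
// needed (no path backtracking).
static double dtw_cost_only(const double* x, int n, const double* y, int m,
                            int window) {
  const double inf = std::numeric_limits<double>::infinity();
  std::vector<double> prev(m, inf), curr(m, inf);

  for (int i = 0; i < n; ++i) {
    int jlo = 0, jhi = m - 1;
    if (window >= 0) {
      jlo = std::max(0, i - window);
      jhi = std::min(m - 1, i + window);
    }
    if (window >= 0) std::fill(curr.begin(), curr.end(), inf);
    const double xi = x[i];
    // register-carried left (horizontal) and diag (prev[j-1]) values
    double left = inf;
    double diag = (jlo > 0) ? prev[jlo - 1] : inf;
    for (int j = jlo; j <= jhi; ++j) {
      double up = prev[j];
      double best;
      if (i == 0) {
        best = (j == 0) ? 0.0 : left;
      } else {
        best = std::min(std::min(diag, up), left);
      }
      left = std::fabs(xi - y[j]) + best;
      curr[j] = left;
      diag = up;
    }
    prev.swap(curr);
  }
  return prev[m - 1];
}

// Path-length-normalized DTW: minimizes the MEAN local cost over all
// admissible paths (the ratio objective). Exact DP indexed by path length L:
// G[j][L] = minimal total cost of a path from (1,1) to (i,j) of L points.
// O(n * m * (n+m)) time, O(m * (n+m)) memory; used only behind the
// `normalize_by_path` flag.
static double dtw_normalized(const double* x, int n, const double* y, int m,
                             int window) {
  const double inf = std::numeric_limits<double>::infinity();
  const int Lmax = n + m - 1;               // longest admissible path
  std::vector<double> prev((size_t)m * (Lmax + 1), inf);
  std::vector<double> curr((size_t)m * (Lmax + 1), inf);

  for (int i = 0; i < n; ++i) {
    int jlo = 0, jhi = m - 1;
    if (window >= 0) {
      jlo = std::max(0, i - window);
      jhi = std::min(m - 1, i + window);
    }
    std::fill(curr.begin(), curr.end(), inf);
    for (int j = jlo; j <= jhi; ++j) {
      const double c = std::fabs(x[i] - y[j]);
      double* cj = &curr[(size_t)j * (Lmax + 1)];
      if (i == 0 && j == 0) {
        cj[1] = c;
        continue;
      }
      const double* dj = (i > 0 && j > 0) ? &prev[(size_t)(j - 1) * (Lmax + 1)] : NULL;
      const double* vj = (i > 0) ? &prev[(size_t)j * (Lmax + 1)] : NULL;
      const double* hj = (j > 0) ? &curr[(size_t)(j - 1) * (Lmax + 1)] : NULL;
      for (int L = 2; L <= Lmax; ++L) {
        double best = inf;
        if (dj && dj[L - 1] < best) best = dj[L - 1];
        if (vj && vj[L - 1] < best) best = vj[L - 1];
        if (hj && hj[L - 1] < best) best = hj[L - 1];
        if (best < inf) cj[L] = c + best;
      }
    }
    prev.swap(curr);
  }
  const double* last = &prev[(size_t)(m - 1) * (Lmax + 1)];
  double best = inf;
  for (int L = 1; L <= Lmax; ++L) {
    if (last[L] < inf) best = std::min(best, last[L] / (double)L);
  }
  return best;
}

static double dtw_one(const double* x, int n, const double* y, int m,
                      int window, bool normalize) {
  if (!normalize) return dtw_cost_only(x, n, y, m, window);
  return dtw_normalized(x, n, y, m, window);
}

// [[Rcpp::export]]
double dtw_cpp(NumericVector x, NumericVector y, int window, bool normalize) {
  return dtw_one(x.begin(), x.size(), y.begin(), y.size(), window, normalize);
}

// Full symmetric DTW distance matrix over the rows of X.
// [[Rcpp::export]]
NumericMatrix dtw_pairwise_cpp(NumericMatrix X, int window, bool normalize) {
  int N = X.nrow(), n = X.ncol();
  NumericMatrix out(N, N);
  // copy rows into contiguous buffers once
  std::vector<double> buf((size_t)N * n);
  for (int i = 0; i < N; ++i)
    for (int t = 0; t < n; ++t)
      buf[(size_t)i * n + t] = X(i, t);
  for (int i = 0; i < N; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double d = dtw_one(&buf[(size_t)i * n], n, &buf[(size_t)j * n], n,
                         window, normalize);
      out(i, j) = d;
      out(j, i) = d;
    }
  }
  return out;
}
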