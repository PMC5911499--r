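#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdlib>
using namespace Rcpp;

// Template match counts for sample entropy, all embedding dimensions
// m_min..m_max in one O(N^2) pass.
//
// Convention (Richman & Moorman): for embedding dimension m, templates of
// length m start at i = 0..N-m-1 (0-based), i.e. N-m templates, the same
// number as the (m+1)-length templates used for A. B[m] counts unordered
// pairs of m-templates within Chebyshev distance r, A[m] counts pairs of
// (m+1)-templates. Pairs with |i-j| < w (Theiler window) are excluded;
// w = 1 excludes only self-matches.
//
// Returns a (m_max-m_min+1) x 2 matrix with columns (B, A).
// [[Rcpp::export(name = ".sampen_counts_cpp")]]
NumericMatrix sampen_counts_cpp(NumericVector x, int m_min, int m_max,
                                double r, int w) {
  const int N = x.size();
  const int M = m_max - m_min + 1;
  if (M < 1) stop("m_max must be >= m_min");
  if (w < 1) w = 1;
  NumericMatrix out(M, 2);
  std::vector<double> B(M, 0.0), A(M, 0.0);
  std::vector<int> run;
  for (int d = w; d <= N - 1; ++d) {
    const int lim = N - d;          // scalar pairs (i, i+d), i = 0..lim-1
    run.assign(lim, 0);
    int nxt = 0;
    for (int i = lim - 1; i >= 0; --i) {
      nxt = (std::abs(x[i] - x[i + d]) <= r) ? nxt + 1 : 0;
      run[i] = nxt;
    }
    for (int i = 0; i < lim; ++i) {
      const int ri = run[i];
      if (ri < m_min) continue;
      // start constraint: both template starts <= N-m-1  =>  m <= N-1-d-i
      const int bound = N - 1 - d - i;
      int mb = std::min(ri, bound); if (mb > m_max) mb = m_max;
      for (int m = m_min; m <= mb; ++m) B[m - m_min] += 1.0;
      int ma = std::min(ri - 1, bound); if (ma > m_max) ma = m_max;
      for (int m = m_min; m <= ma; ++m) A[m - m_min] += 1.0;
    }
  }
  for (int k = 0; k < M; ++k) { out(k, 0) = B[k]; out(k, 1) = A[k]; }
  return out;
}
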