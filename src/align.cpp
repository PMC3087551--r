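#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Global affine-gap alignment (Gotoh) of two profiles. A profile is a
// 20 x L matrix of per-column residue frequencies (columns with internal
// gaps sum to < 1). Column score = fA' S fB; gap of length k costs
// open + k * ext. For two single sequences this reduces to plain
// Needleman-Wunsch with affine gaps.
// Tie-break order on traceback: diagonal, then gap-in-B (consume A column),
// then gap-in-A (consume B column).

// [[Rcpp::export(name = ".profile_align_cpp")]]
List profile_align_cpp(NumericMatrix A, NumericMatrix B, NumericMatrix smat,
                       double gap_open, double gap_ext) {
  const int n = A.ncol(), m = B.ncol();
  const double NEG = -1e30;
  // precompute column scores
  NumericMatrix S(n, m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int a = 0; a < 20; ++a) {
        if (A(a, i) == 0.0) continue;
        double sa = 0.0;
        for (int b = 0; b < 20; ++b) sa += smat(a, b) * B(b, j);
        s += A(a, i) * sa;
      }
      S(i, j) = s;
    }
  std::vector<std::vector<double> > H(n + 1, std::vector<double>(m + 1, NEG));
  std::vector<std::vector<double> > E(n + 1, std::vector<double>(m + 1, NEG));
  std::vector<std::vector<double> > F(n + 1, std::vector<double>(m + 1, NEG));
  H[0][0] = 0.0;
  for (int j = 1; j <= m; ++j) {
    E[0][j] = -(gap_open + j * gap_ext);
    H[0][j] = E[0][j];
  }
  for (int i = 1; i <= n; ++i) {
    F[i][0] = -(gap_open + i * gap_ext);
    H[i][0] = F[i][0];
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      E[i][j] = std::max(H[i][j - 1] - gap_open - gap_ext, E[i][j - 1] - gap_ext);
      F[i][j] = std::max(H[i - 1][j] - gap_open - gap_ext, F[i - 1][j] - gap_ext);
      double diag = H[i - 1][j - 1] + S(i - 1, j - 1);
      H[i][j] = std::max(diag, std::max(E[i][j], F[i][j]));
    }
  }
  // traceback
  std::vector<int> ai, bi;
  int i = n, j = m;
  char state = 'H';
  const double tol = 1e-9;
  while (i > 0 || j > 0) {
    if (state == 'H') {
      if (i > 0 && j > 0 &&
          std::abs(H[i][j] - (H[i - 1][j - 1] + S(i - 1, j - 1))) <= tol) {
        ai.push_back(i); bi.push_back(j); --i; --j; continue;
      }
      if (i > 0 && std::abs(H[i][j] - F[i][j]) <= tol) { state = 'F'; continue; }
      if (j > 0 && std::abs(H[i][j] - E[i][j]) <= tol) { state = 'E'; continue; }
      // boundary rows/cols
      if (i > 0) { state = 'F'; continue; }
      state = 'E'; continue;
    } else if (state == 'F') { // gap in B, consume A column
      bool open_here = (i == 1) ||
        std::abs(F[i][j] - (H[i - 1][j] - gap_open - gap_ext)) <= tol;
      ai.push_back(i); bi.push_back(0); --i;
      if (open_here) state = 'H';
    } else { // 'E': gap in A, consume B column
      bool open_here = (j == 1) ||
        std::abs(E[i][j] - (H[i][j - 1] - gap_open - gap_ext)) <= tol;
      ai.push_back(0); bi.push_back(j); --j;
      if (open_here) state = 'H';
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["a_cols"] = wrap(ai), _["b_cols"] = wrap(bi),
                      _["score"] = H[n][m]);
}
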