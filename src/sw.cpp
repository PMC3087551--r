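#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Affine-gap local alignment (Gotoh). Sequences arrive as 0-based integer
// residue codes; `smat` is the square substitution matrix over those codes.
// A gap of length k costs open + k * ext.

struct SwResult {
  double score;
  int qstart, qend, tstart, tend; // 0-based half-open
};

static SwResult sw_core(const std::vector<int>& a, const std::vector<int>& b,
                        const NumericMatrix& smat, double open, double ext,
                        bool traceback) {
  const int n = (int)a.size(), m = (int)b.size();
  const double NEG = -1e30;
  const int na = smat.nrow();
  // flattened row-major copy of the scoring matrix for fast access
  std::vector<double> S((size_t)na * na);
  for (int r = 0; r < na; ++r)
    for (int c = 0; c < na; ++c) S[(size_t)r * na + c] = smat(r, c);
  std::vector<double> Hm1(m + 1, 0.0), H(m + 1, 0.0);
  std::vector<double> Fcol(m + 1, NEG);
  double best = 0.0;
  std::vector<std::pair<int,int> > ends; // end cells achieving best score
  std::vector<std::vector<double> > Hfull, Efull, Ffull;
  if (traceback) {
    Hfull.assign(n + 1, std::vector<double>(m + 1, 0.0));
    Efull.assign(n + 1, std::vector<double>(m + 1, NEG));
    Ffull.assign(n + 1, std::vector<double>(m + 1, NEG));
  }
  const double oe = open + ext;
  for (int i = 1; i <= n; ++i) {
    std::swap(H, Hm1);
    H[0] = 0.0;
    const double* srow = &S[(size_t)a[i - 1] * na];
    const double* hm1 = Hm1.data();
    double* h_ = H.data();
    double* fc = Fcol.data();
    double Ecur = NEG; // E[i][j]: horizontal, within current row
    for (int j = 1; j <= m; ++j) {
      double e_cand = h_[j - 1] - oe;
      Ecur -= ext;
      if (e_cand > Ecur) Ecur = e_cand;
      double f_cand = hm1[j] - oe;
      double Fcur = fc[j] - ext;
      if (f_cand > Fcur) Fcur = f_cand;
      fc[j] = Fcur;
      double h = hm1[j - 1] + srow[b[j - 1]];
      if (Ecur > h) h = Ecur;
      if (Fcur > h) h = Fcur;
      if (h < 0.0) h = 0.0;
      h_[j] = h;
      if (traceback) { Hfull[i][j] = h; Efull[i][j] = Ecur; Ffull[i][j] = Fcur; }
      if (h > best + 1e-12) {
        best = h; ends.clear(); ends.push_back(std::make_pair(i, j));
      } else if (traceback && h > 0 && std::abs(h - best) <= 1e-12) {
        ends.push_back(std::make_pair(i, j));
      }
    }
  }
  SwResult res; res.score = best;
  res.qstart = res.qend = res.tstart = res.tend = 0;
  if (!traceback || best <= 0.0 || ends.empty()) return res;
  // Trace each candidate end back to its start; report the alignment with
  // the smallest (qstart, tstart), then smallest (qend, tend).
  int bq0 = -1, bt0 = -1, bq1 = -1, bt1 = -1;
  for (size_t k = 0; k < ends.size(); ++k) {
    int i = ends[k].first, j = ends[k].second;
    const int ei = i, ej = j;
    char state = 'H';
    while (i > 0 && j > 0) {
      if (state == 'H') {
        double h = Hfull[i][j];
        if (h <= 0.0) break;
        double diag = Hfull[i - 1][j - 1] + smat(a[i - 1], b[j - 1]);
        if (std::abs(h - diag) <= 1e-9) { --i; --j; continue; }
        if (std::abs(h - Efull[i][j]) <= 1e-9) { state = 'E'; continue; }
        state = 'F'; continue;
      } else if (state == 'E') {
        if (std::abs(Efull[i][j] - (Hfull[i][j - 1] - open - ext)) <= 1e-9) {
          --j; state = 'H';
        } else { --j; }
      } else { // 'F'
        if (std::abs(Ffull[i][j] - (Hfull[i - 1][j] - open - ext)) <= 1e-9) {
          --i; state = 'H';
        } else { --i; }
      }
    }
    bool better;
    if (bq0 < 0) better = true;
    else if (i != bq0) better = i < bq0;
    else if (j != bt0) better = j < bt0;
    else if (ei != bq1) better = ei < bq1;
    else better = ej < bt1;
    if (better) { bq0 = i; bt0 = j; bq1 = ei; bt1 = ej; }
  }
  res.qstart = bq0; res.qend = bq1; res.tstart = bt0; res.tend = bt1;
  return res;
}

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix smat,
                  double gap_open, double gap_ext) {
  std::vector<int> av(a.begin(), a.end()), bv(b.begin(), b.end());
  SwResult r = sw_core(av, bv, smat, gap_open, gap_ext, true);
  return List::create(_["score"] = r.score,
                      _["qstart"] = r.qstart, _["qend"] = r.qend,
                      _["tstart"] = r.tstart, _["tend"] = r.tend);
}

// Score-only batch mode: one query against many targets.
// [[Rcpp::export(name = ".sw_scores_cpp")]]
NumericVector sw_scores_cpp(IntegerVector a, List targets, NumericMatrix smat,
                            double gap_open, double gap_ext) {
  std::vector<int> av(a.begin(), a.end());
  const int nt = targets.size();
  NumericVector out(nt);
  for (int t = 0; t < nt; ++t) {
    IntegerVector b = targets[t];
    std::vector<int> bv(b.begin(), b.end());
    out[t] = sw_core(av, bv, smat, gap_open, gap_ext, false).score;
  }
  return out;
}
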