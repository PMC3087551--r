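#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Profile HMM with local (uniform entry/exit) topology:
//   B -> M_k with prob entry[k]; M_k -> E with prob exit_[k];
//   core transitions M->M/I/D, I->M/I, D->M/D; D_m -> E with prob 1.
// Emissions are stored as odds ratios (match emission / background), so the
// forward value is directly P(seq | model) / P(seq | background) for the
// aligned region, with free background flanks. Scores are log2 odds (bits).

struct HmmPar {
  int m;
  std::vector<double> oe; // m x 20 match emission odds, row-major by state
  std::vector<double> entry, exit_, t_mm, t_mi, t_md, t_im, t_ii, t_dm, t_dd;
};

static HmmPar unpack(const List& hmm) {
  HmmPar p;
  NumericMatrix oe = as<NumericMatrix>(hmm["match_odds"]);
  p.m = oe.nrow();
  p.oe.resize((size_t)p.m * 20);
  for (int k = 0; k < p.m; ++k)
    for (int a = 0; a < 20; ++a) p.oe[(size_t)k * 20 + a] = oe(k, a);
  const char* nm[9] = {"entry", "exit", "t_mm", "t_mi", "t_md",
                       "t_im", "t_ii", "t_dm", "t_dd"};
  std::vector<double>* dst[9] = {&p.entry, &p.exit_, &p.t_mm, &p.t_mi,
                                 &p.t_md, &p.t_im, &p.t_ii, &p.t_dm, &p.t_dd};
  for (int i = 0; i < 9; ++i) {
    NumericVector v = hmm[nm[i]];
    dst[i]->assign(v.begin(), v.end());
  }
  return p;
}

static double logsumexp(const std::vector<double>& v) {
  double mx = -INFINITY;
  for (size_t i = 0; i < v.size(); ++i) if (v[i] > mx) mx = v[i];
  if (!std::isfinite(mx)) return -INFINITY;
  double s = 0.0;
  for (size_t i = 0; i < v.size(); ++i) s += std::exp(v[i] - mx);
  return mx + std::log(s);
}

// seq: 0-based residue codes (0..19). Returns log2 odds.
static double forward_bits(const HmmPar& p, const int* seq, int L) {
  const int m = p.m;
  std::vector<double> M(m + 1, 0.0), I(m + 1, 0.0), D(m + 1, 0.0);
  std::vector<double> Mp(m + 1, 0.0), Ip(m + 1, 0.0), Dp(m + 1, 0.0);
  std::vector<double> log_end;
  log_end.reserve(L);
  double cumlog = 0.0;
  for (int j = 1; j <= L; ++j) {
    std::swap(M, Mp); std::swap(I, Ip); std::swap(D, Dp);
    const int x = seq[j - 1];
    for (int k = 1; k <= m; ++k) {
      double acc = p.entry[k - 1];
      if (k > 1) {
        acc += Mp[k - 1] * p.t_mm[k - 2];
        acc += Ip[k - 1] * p.t_im[k - 2];
        acc += Dp[k - 1] * p.t_dm[k - 2];
      }
      M[k] = p.oe[(size_t)(k - 1) * 20 + x] * acc;
      I[k] = Mp[k] * p.t_mi[k - 1] + Ip[k] * p.t_ii[k - 1];
      D[k] = (k > 1) ? (M[k - 1] * p.t_md[k - 2] + D[k - 1] * p.t_dd[k - 2])
                     : 0.0;
    }
    double end = D[m]; // D_m -> E with prob 1
    for (int k = 1; k <= m; ++k) end += M[k] * p.exit_[k - 1];
    if (end > 0.0) log_end.push_back(std::log(end) + cumlog);
    // rescale to avoid underflow
    double mx = 0.0;
    for (int k = 1; k <= m; ++k) {
      if (M[k] > mx) mx = M[k];
      if (I[k] > mx) mx = I[k];
      if (D[k] > mx) mx = D[k];
    }
    if (mx > 0.0 && mx < 1e-100) {
      for (int k = 1; k <= m; ++k) { M[k] /= mx; I[k] /= mx; D[k] /= mx; }
      cumlog += std::log(mx);
    }
  }
  double lo = logsumexp(log_end);
  return lo / std::log(2.0);
}

static double viterbi_bits(const HmmPar& p, const int* seq, int L) {
  const int m = p.m;
  const double NEG = -INFINITY;
  std::vector<double> le(m), lmm(m), lmi(m), lmd(m), lim(m), lii(m),
      ldm(m), ldd(m), len_(m);
  for (int k = 0; k < m; ++k) {
    le[k] = std::log(p.entry[k]); len_[k] = std::log(p.exit_[k]);
    lmm[k] = std::log(p.t_mm[k]); lmi[k] = std::log(p.t_mi[k]);
    lmd[k] = std::log(p.t_md[k]); lim[k] = std::log(p.t_im[k]);
    lii[k] = std::log(p.t_ii[k]); ldm[k] = std::log(p.t_dm[k]);
    ldd[k] = std::log(p.t_dd[k]);
  }
  std::vector<double> M(m + 1, NEG), I(m + 1, NEG), D(m + 1, NEG);
  std::vector<double> Mp(m + 1, NEG), Ip(m + 1, NEG), Dp(m + 1, NEG);
  double best = NEG;
  for (int j = 1; j <= L; ++j) {
    std::swap(M, Mp); std::swap(I, Ip); std::swap(D, Dp);
    const int x = seq[j - 1];
    for (int k = 1; k <= m; ++k) {
      double acc = le[k - 1];
      if (k > 1) {
        acc = std::max(acc, Mp[k - 1] + lmm[k - 2]);
        acc = std::max(acc, Ip[k - 1] + lim[k - 2]);
        acc = std::max(acc, Dp[k - 1] + ldm[k - 2]);
      }
      M[k] = std::log(p.oe[(size_t)(k - 1) * 20 + x]) + acc;
      I[k] = std::max(Mp[k] + lmi[k - 1], Ip[k] + lii[k - 1]);
      D[k] = (k > 1) ? std::max(M[k - 1] + lmd[k - 2], D[k - 1] + ldd[k - 2])
                     : NEG;
    }
    double end = D[m];
    for (int k = 1; k <= m; ++k) end = std::max(end, M[k] + len_[k - 1]);
    best = std::max(best, end);
  }
  return best / std::log(2.0);
}

// [[Rcpp::export(name = ".hmm_forward_cpp")]]
double hmm_forward_cpp(List hmm, IntegerVector seq) {
  HmmPar p = unpack(hmm);
  std::vector<int> s(seq.begin(), seq.end());
  return forward_bits(p, s.data(), (int)s.size());
}

// [[Rcpp::export(name = ".hmm_forward_many_cpp")]]
NumericVector hmm_forward_many_cpp(List hmm, List seqs) {
  HmmPar p = unpack(hmm);
  const int n = seqs.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector sv = seqs[i];
    std::vector<int> s(sv.begin(), sv.end());
    out[i] = forward_bits(p, s.data(), (int)s.size());
  }
  return out;
}

// [[Rcpp::export(name = ".hmm_viterbi_cpp")]]
double hmm_viterbi_cpp(List hmm, IntegerVector seq) {
  HmmPar p = unpack(hmm);
  std::vector<int> s(seq.begin(), seq.end());
  return viterbi_bits(p, s.data(), (int)s.size());
}

// Null-search audit: for each of n_searches, draw seqs_per_search i.i.d.
// background sequences of length len and count forward scores >= threshold
// (the score at the chosen E-value cutoff). Uses R's RNG so results follow
// set.seed().
// [[Rcpp::export(name = ".hmm_null_counts_cpp")]]
IntegerVector hmm_null_counts_cpp(List hmm, int n_searches, int seqs_per_search,
                                  int len, NumericVector bg,
                                  double threshold_bits) {
  HmmPar p = unpack(hmm);
  std::vector<double> cum(20);
  double c = 0.0;
  for (int a = 0; a < 20; ++a) { c += bg[a]; cum[a] = c; }
  std::vector<int> s(len);
  IntegerVector out(n_searches);
  RNGScope scope;
  for (int i = 0; i < n_searches; ++i) {
    int hits = 0;
    for (int q = 0; q < seqs_per_search; ++q) {
      for (int j = 0; j < len; ++j) {
        double u = unif_rand() * c;
        int a = 0;
        while (a < 19 && u > cum[a]) ++a;
        s[j] = a;
      }
      if (forward_bits(p, s.data(), len) >= threshold_bits) ++hits;
    }
    out[i] = hits;
  }
  return out;
}
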