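#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Interval-agreement dynamic program over two ascending label tracks.
// A matched pair (i, j) may extend a previous pair (ii, jj) only when the
// label gaps agree: |dref - dmol| <= max(abs_tol, rel_tol * dref).
// Score: match_bonus per matched pair, minus a small graded deviation cost
// (gap_cost_per_bp * |dref - dmol|), minus miss/extra penalties per skipped
// reference/molecule label between consecutive matches. Ends are free
// (overlap-style local alignment): a molecule may cover any part of the
// reference and vice versa.

struct DpResult {
  double score;
  int n_matched;
  int best_i, best_j;
};

// score-only DP; S and Cnt are caller-provided m*r buffers
static DpResult dp_core(const double* mol, int m, const double* ref, int r,
                        double abs_tol, double rel_tol, double miss_penalty,
                        double extra_penalty, double match_bonus,
                        double gap_cost_per_bp, int max_skip,
                        std::vector<double>& S, std::vector<int>& Cnt,
                        std::vector<int>* Pi, std::vector<int>* Pj) {
  DpResult out = {R_NegInf, 0, -1, -1};
  if (m == 0 || r == 0) return out;
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < r; ++j) {
      double s = match_bonus;
      int cnt = 1, pi = -1, pj = -1;
      const int i0 = std::max(0, i - 1 - max_skip);
      const int j0 = std::max(0, j - 1 - max_skip);
      for (int ii = i - 1; ii >= i0; --ii) {
        const double dm = mol[i] - mol[ii];
        const double* Srow = &S[(size_t)ii * r];
        for (int jj = j - 1; jj >= j0; --jj) {
          const double dr = ref[j] - ref[jj];
          const double dev = std::fabs(dr - dm);
          const double tol = std::max(abs_tol, rel_tol * dr);
          if (dev > tol) continue;
          const double cand = Srow[jj] + match_bonus - gap_cost_per_bp * dev
            - miss_penalty * (j - jj - 1) - extra_penalty * (i - ii - 1);
          if (cand > s + 1e-12) {
            s = cand; pi = ii; pj = jj; cnt = Cnt[(size_t)ii * r + jj] + 1;
          }
        }
      }
      S[(size_t)i * r + j] = s;
      Cnt[(size_t)i * r + j] = cnt;
      if (Pi) { (*Pi)[(size_t)i * r + j] = pi; (*Pj)[(size_t)i * r + j] = pj; }
      if (s > out.score + 1e-12) {
        out.score = s; out.n_matched = cnt; out.best_i = i; out.best_j = j;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List dp_align_cpp(NumericVector mol, NumericVector ref,
                  double abs_tol, double rel_tol,
                  double miss_penalty, double extra_penalty,
                  double match_bonus, double gap_cost_per_bp,
                  int max_skip, bool want_path) {
  const int m = mol.size(), r = ref.size();
  if (m == 0 || r == 0)
    return List::create(_["score"] = R_NegInf, _["n_matched"] = 0);
  std::vector<double> S((size_t)m * r);
  std::vector<int> Cnt((size_t)m * r);
  std::vector<int> Pi, Pj;
  std::vector<int>* pPi = nullptr;
  std::vector<int>* pPj = nullptr;
  if (want_path) {
    Pi.assign((size_t)m * r, -1); Pj.assign((size_t)m * r, -1);
    pPi = &Pi; pPj = &Pj;
  }
  DpResult res = dp_core(&mol[0], m, &ref[0], r, abs_tol, rel_tol,
                         miss_penalty, extra_penalty, match_bonus,
                         gap_cost_per_bp, max_skip, S, Cnt, pPi, pPj);
  if (!want_path)
    return List::create(_["score"] = res.score, _["n_matched"] = res.n_matched);
  const int n = res.n_matched;
  IntegerVector mi(n), ri(n);
  int i = res.best_i, j = res.best_j;
  for (int k = n - 1; k >= 0; --k) {
    mi[k] = i + 1; ri[k] = j + 1;   // 1-based for R
    const int ni = Pi[(size_t)i * r + j], nj = Pj[(size_t)i * r + j];
    i = ni; j = nj;
    if (i < 0 && k > 0) stop("backtrack underflow");   // defensive
  }
  return List::create(_["score"] = res.score, _["n_matched"] = n,
                      _["mol_idx"] = mi, _["ref_idx"] = ri);
}

// Batch scan of one label track against every arm in both orientations.
// Returns a (n_arms x 4) matrix: score_fwd, n_fwd, score_rev, n_rev.
// The reverse orientation mirrors the track through length_bp.
// [[Rcpp::export]]
NumericMatrix dp_scan_cpp(NumericVector mol, double length_bp, List refs,
                          double abs_tol, double rel_tol,
                          double miss_penalty, double extra_penalty,
                          double match_bonus, double gap_cost_per_bp,
                          int max_skip) {
  const int m = mol.size();
  const int k = refs.size();
  NumericMatrix out(k, 4);
  std::fill(out.begin(), out.end(), R_NegInf);
  if (m == 0) return out;
  std::vector<double> fwd(mol.begin(), mol.end());
  std::vector<double> rev(m);
  for (int i = 0; i < m; ++i) rev[i] = length_bp - fwd[m - 1 - i];
  size_t rmax = 0;
  for (int a = 0; a < k; ++a)
    rmax = std::max(rmax, (size_t)Rf_length(VECTOR_ELT(refs, a)));
  std::vector<double> S((size_t)m * rmax);
  std::vector<int> Cnt((size_t)m * rmax);
  for (int a = 0; a < k; ++a) {
    NumericVector ref = refs[a];
    const int r = ref.size();
    if (r == 0) continue;
    DpResult rf = dp_core(&fwd[0], m, &ref[0], r, abs_tol, rel_tol,
                          miss_penalty, extra_penalty, match_bonus,
                          gap_cost_per_bp, max_skip, S, Cnt, nullptr, nullptr);
    DpResult rr = dp_core(&rev[0], m, &ref[0], r, abs_tol, rel_tol,
                          miss_penalty, extra_penalty, match_bonus,
                          gap_cost_per_bp, max_skip, S, Cnt, nullptr, nullptr);
    out(a, 0) = rf.score; out(a, 1) = rf.n_matched;
    out(a, 2) = rr.score; out(a, 3) = rr.n_matched;
  }
  return out;
}
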