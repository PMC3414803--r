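#include <Rcpp.h>
#include <climits>
#include <vector>
using namespace Rcpp;

// Sequences arrive as 0-based integer codes (0..20; 20 = X/unknown, which the
// R side maps to a zero-scoring row/column of the substitution matrix).
// Affine gap convention: a gap of length L costs gap_open + L * gap_extend.

static const int NEG = INT_MIN / 4;

// Smith-Waterman optimal local score, linear memory (Gotoh).
// [[Rcpp::export]]
int sw_score_cpp(const IntegerVector& a, const IntegerVector& b,
                 const IntegerMatrix& sub, int gap_open, int gap_extend) {
  const int n = a.size(), m = b.size();
  std::vector<int> Hprev(m + 1, 0), Hcur(m + 1, 0), Fcol(m + 1, NEG);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    int E = NEG;
    int Hdiag = 0;  // H[i-1][j-1], starts at H[i-1][0] = 0
    Hcur[0] = 0;
    const int ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      E = std::max(Hcur[j - 1] - gap_open - gap_extend, E - gap_extend);
      Fcol[j] = std::max(Hprev[j] - gap_open - gap_extend, Fcol[j] - gap_extend);
      int h = Hdiag + sub(ai, b[j - 1]);
      Hdiag = Hprev[j];
      if (E > h) h = E;
      if (Fcol[j] > h) h = Fcol[j];
      if (h < 0) h = 0;
      Hcur[j] = h;
      if (h > best) best = h;
    }
    std::swap(Hprev, Hcur);
  }
  return best;
}

// All-vs-all optimal local scores; symmetric matrix, diagonal left at 0
// (self-hits are excluded downstream).
// [[Rcpp::export]]
IntegerMatrix sw_scores_all_cpp(const List& seqs, const IntegerMatrix& sub,
                                int gap_open, int gap_extend) {
  const int n = seqs.size();
  IntegerMatrix out(n, n);
  std::vector<IntegerVector> sv(n);
  for (int i = 0; i < n; ++i) sv[i] = seqs[i];
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int s = sw_score_cpp(sv[i], sv[j], sub, gap_open, gap_extend);
      out(i, j) = s;
      out(j, i) = s;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Full Smith-Waterman with traceback for one pair.  Tie-break among equal
// moves: diagonal, then up (gap in b, consumes a), then left (gap in a).
// Returns 0-based half-open aligned ranges and alignment statistics.
// [[Rcpp::export]]
List sw_traceback_cpp(const IntegerVector& a, const IntegerVector& b,
                      const IntegerMatrix& sub, int gap_open, int gap_extend) {
  const int n = a.size(), m = b.size();
  std::vector<std::vector<int> > H(n + 1, std::vector<int>(m + 1, 0));
  std::vector<std::vector<int> > E(n + 1, std::vector<int>(m + 1, NEG));
  std::vector<std::vector<int> > F(n + 1, std::vector<int>(m + 1, NEG));
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      E[i][j] = std::max(H[i][j - 1] - gap_open - gap_extend,
                         E[i][j - 1] - gap_extend);
      F[i][j] = std::max(H[i - 1][j] - gap_open - gap_extend,
                         F[i - 1][j] - gap_extend);
      int h = H[i - 1][j - 1] + sub(a[i - 1], b[j - 1]);
      if (F[i][j] > h) h = F[i][j];
      if (E[i][j] > h) h = E[i][j];
      if (h < 0) h = 0;
      H[i][j] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  int matches = 0, mismatches = 0, gapopens = 0, gaps = 0, cols = 0;
  int i = bi, j = bj;
  int qe = bi, se = bj;
  while (i > 0 && j > 0 && H[i][j] > 0) {
    int h = H[i][j];
    if (h == H[i - 1][j - 1] + sub(a[i - 1], b[j - 1])) {
      if (a[i - 1] == b[j - 1]) ++matches; else ++mismatches;
      --i; --j; ++cols;
    } else if (h == F[i][j]) {  // up: gap in b
      ++gapopens;
      while (i > 0 && F[i][j] != H[i - 1][j] - gap_open - gap_extend) {
        --i; ++gaps; ++cols;
      }
      --i; ++gaps; ++cols;
    } else {                    // left: gap in a
      ++gapopens;
      while (j > 0 && E[i][j] != H[i][j - 1] - gap_open - gap_extend) {
        --j; ++gaps; ++cols;
      }
      --j; ++gaps; ++cols;
    }
  }
  return List::create(
    _["score"] = best,
    _["q_start"] = i, _["q_end"] = qe,
    _["s_start"] = j, _["s_end"] = se,
    _["matches"] = matches, _["mismatches"] = mismatches,
    _["gapopens"] = gapopens, _["gaps"] = gaps,
    _["aln_len"] = cols);
}

// Global (Needleman-Wunsch) alignment of two column profiles given the
// precomputed column-vs-column score matrix C (n x m).  End gaps are
// penalised.  Returns, per merged column, the 1-based source column in each
// profile or 0 for a gap.  Tie-break: diagonal, then up, then left.
// [[Rcpp::export]]
List nw_profile_path_cpp(const NumericMatrix& C, double gap_open,
                         double gap_extend) {
  const int n = C.nrow(), m = C.ncol();
  const double NEGD = -1e30;
  std::vector<std::vector<double> > H(n + 1, std::vector<double>(m + 1, NEGD));
  std::vector<std::vector<double> > E(n + 1, std::vector<double>(m + 1, NEGD));
  std::vector<std::vector<double> > F(n + 1, std::vector<double>(m + 1, NEGD));
  H[0][0] = 0.0;
  for (int j = 1; j <= m; ++j) {
    E[0][j] = -gap_open - j * gap_extend;
    H[0][j] = E[0][j];
  }
  for (int i = 1; i <= n; ++i) {
    F[i][0] = -gap_open - i * gap_extend;
    H[i][0] = F[i][0];
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      E[i][j] = std::max(H[i][j - 1] - gap_open - gap_extend,
                         E[i][j - 1] - gap_extend);
      F[i][j] = std::max(H[i - 1][j] - gap_open - gap_extend,
                         F[i - 1][j] - gap_extend);
      double h = H[i - 1][j - 1] + C(i - 1, j - 1);
      if (F[i][j] > h) h = F[i][j];
      if (E[i][j] > h) h = E[i][j];
      H[i][j] = h;
    }
  }
  std::vector<int> ai, bi_;
  int i = n, j = m;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        std::abs(H[i][j] - (H[i - 1][j - 1] + C(i - 1, j - 1))) < eps) {
      ai.push_back(i); bi_.push_back(j); --i; --j;
    } else if (i > 0 && (j == 0 || std::abs(H[i][j] - F[i][j]) < eps)) {
      // up: column from profile 1, gap in profile 2
      while (i > 0 &&
             !(std::abs(F[i][j] - (H[i - 1][j] - gap_open - gap_extend)) < eps)) {
        ai.push_back(i); bi_.push_back(0); --i;
        if (j == 0) break;
      }
      if (i > 0) { ai.push_back(i); bi_.push_back(0); --i; }
    } else {
      while (j > 0 &&
             !(std::abs(E[i][j] - (H[i][j - 1] - gap_open - gap_extend)) < eps)) {
        ai.push_back(0); bi_.push_back(j); --j;
        if (i == 0) break;
      }
      if (j > 0) { ai.push_back(0); bi_.push_back(j); --j; }
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi_.begin(), bi_.end());
  return List::create(_["a_cols"] = wrap(ai), _["b_cols"] = wrap(bi_));
}
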