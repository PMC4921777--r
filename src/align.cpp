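#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Affine-gap pairwise alignment engine (Needleman-Wunsch-Gotoh global and
// Smith-Waterman-Gotoh local). A gap of length k costs open + k * ext.
// Sequences arrive as 0-based integer codes indexing the substitution matrix.

static const double NEG = -1e30;

struct AlnStats {
  int matches;      // identical residue columns inside the core region
  int core_cols;    // aligned columns excluding terminal-gap columns
  int cov_a;        // residues of a inside the core region
  int cov_b;        // residues of b inside the core region
  int gap_opens;    // gap runs inside the core region
  int mismatches;   // non-identical residue columns (both non-gap) in core
};

// ops: 0 = diagonal, 1 = gap in b (consume a), 2 = gap in a (consume b)
static AlnStats path_stats(const std::vector<int> &ops,
                           const IntegerVector &a, const IntegerVector &b,
                           int ia0, int ib0) {
  AlnStats st;
  st.matches = st.core_cols = st.cov_a = st.cov_b = 0;
  st.gap_opens = st.mismatches = 0;
  int first = -1, last = -1;
  for (int k = 0; k < (int)ops.size(); ++k)
    if (ops[k] == 0) { if (first < 0) first = k; last = k; }
  if (first < 0) return st;  // no aligned residue pair at all
  int ia = ia0, ib = ib0;
  int prev_op = 0;
  for (int k = 0; k < (int)ops.size(); ++k) {
    int op = ops[k];
    if (k >= first && k <= last) {
      ++st.core_cols;
      if (op == 0) {
        ++st.cov_a; ++st.cov_b;
        if (a[ia] == b[ib]) ++st.matches; else ++st.mismatches;
        prev_op = 0;
      } else if (op == 1) {
        ++st.cov_a;
        if (prev_op != 1) ++st.gap_opens;
        prev_op = 1;
      } else {
        ++st.cov_b;
        if (prev_op != 2) ++st.gap_opens;
        prev_op = 2;
      }
    }
    if (op == 0) { ++ia; ++ib; }
    else if (op == 1) ++ia;
    else ++ib;
  }
  return st;
}

// Global affine DP. Score uses rolling rows; the traceback is byte-packed
// (2 bits per matrix per cell) so the whole direction table stays cache
// resident at typical protein lengths. Fills `ops`, returns score.
static double nwg_core(const IntegerVector &a, const IntegerVector &b,
                       const IntegerMatrix &S, double open, double ext,
                       std::vector<int> &ops) {
  const int la = a.size(), lb = b.size();
  const int w = lb + 1;
  // tb byte: bits 0-1 pred of M, 2-3 pred of X, 4-5 pred of Y
  std::vector<unsigned char> tb((size_t)(la + 1) * w, 0);
  std::vector<double> M(w), X(w), Y(w), Mp(w), Xp(w), Yp(w);
  const int *Sp = INTEGER(S);
  const int ns = S.nrow();
  Mp[0] = 0.0; Xp[0] = NEG; Yp[0] = NEG;
  for (int j = 1; j <= lb; ++j) {
    Mp[j] = NEG; Xp[j] = NEG;
    Yp[j] = -(open + j * ext);
    tb[j] = (unsigned char)(((j == 1 ? 0 : 2) << 4));
  }
  for (int i = 1; i <= la; ++i) {
    unsigned char *trow = &tb[(size_t)i * w];
    M[0] = NEG; Y[0] = NEG;
    X[0] = -(open + i * ext);
    trow[0] = (unsigned char)(((i == 1 ? 0 : 1)) << 2);
    const int *Sa = Sp + a[i - 1];  // column-major: S[ai + ns*bj]
    for (int j = 1; j <= lb; ++j) {
      unsigned char code;
      double best = Mp[j - 1]; unsigned char t = 0;
      if (Xp[j - 1] > best) { best = Xp[j - 1]; t = 1; }
      if (Yp[j - 1] > best) { best = Yp[j - 1]; t = 2; }
      M[j] = best + Sa[(size_t)ns * b[j - 1]];
      code = t;
      best = Mp[j] - (open + ext); t = 0;
      if (Xp[j] - ext > best) { best = Xp[j] - ext; t = 1; }
      if (Yp[j] - (open + ext) > best) { best = Yp[j] - (open + ext); t = 2; }
      X[j] = best;
      code |= (unsigned char)(t << 2);
      best = M[j - 1] - (open + ext); t = 0;
      if (X[j - 1] - (open + ext) > best) { best = X[j - 1] - (open + ext); t = 1; }
      if (Y[j - 1] - ext > best) { best = Y[j - 1] - ext; t = 2; }
      Y[j] = best;
      code |= (unsigned char)(t << 4);
      trow[j] = code;
    }
    std::swap(M, Mp); std::swap(X, Xp); std::swap(Y, Yp);
  }
  double score = Mp[lb]; int cur = 0;
  if (Xp[lb] > score) { score = Xp[lb]; cur = 1; }
  if (Yp[lb] > score) { score = Yp[lb]; cur = 2; }
  ops.clear();
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    const unsigned char code = tb[(size_t)i * w + j];
    if (cur == 0) { ops.push_back(0); cur = code & 3; --i; --j; }
    else if (cur == 1) { ops.push_back(1); cur = (code >> 2) & 3; --i; }
    else { ops.push_back(2); cur = (code >> 4) & 3; --j; }
  }
  std::reverse(ops.begin(), ops.end());
  return score;
}

static List stats_to_list(double score, const AlnStats &st, int la, int lb) {
  double id = st.core_cols > 0 ? (double)st.matches / st.core_cols : 0.0;
  return List::create(
    _["score"] = score,
    _["identity"] = id,
    _["coverage_a"] = (double)st.cov_a / la,
    _["coverage_b"] = (double)st.cov_b / lb,
    _["matches"] = st.matches,
    _["core_columns"] = st.core_cols,
    _["mismatches"] = st.mismatches,
    _["gap_opens"] = st.gap_opens);
}

// [[Rcpp::export(name = ".nwg_stats")]]
List nwg_stats(IntegerVector a, IntegerVector b, IntegerMatrix S,
               double open, double ext) {
  std::vector<int> ops;
  double score = nwg_core(a, b, S, open, ext, ops);
  AlnStats st = path_stats(ops, a, b, 0, 0);
  return stats_to_list(score, st, a.size(), b.size());
}

// [[Rcpp::export(name = ".nwg_path")]]
IntegerVector nwg_path(IntegerVector a, IntegerVector b, IntegerMatrix S,
                       double open, double ext) {
  std::vector<int> ops;
  nwg_core(a, b, S, open, ext, ops);
  return wrap(ops);
}

// Greedy UCLUST-style matcher: align `seq` against seeds in order, return the
// 1-based index of the FIRST seed meeting identity and coverage thresholds
// (0 when none), plus the stats of the matching alignment.
// [[Rcpp::export(name = ".greedy_first_match")]]
List greedy_first_match(IntegerVector seq, List seeds, IntegerMatrix S,
                        double open, double ext,
                        double id_thr, double cov_thr) {
  std::vector<int> ops;
  for (int k = 0; k < seeds.size(); ++k) {
    IntegerVector sd = seeds[k];
    double score = nwg_core(sd, seq, S, open, ext, ops);
    AlnStats st = path_stats(ops, sd, seq, 0, 0);
    double id = st.core_cols > 0 ? (double)st.matches / st.core_cols : 0.0;
    double ca = (double)st.cov_a / sd.size();
    double cb = (double)st.cov_b / seq.size();
    if (id >= id_thr && ca >= cov_thr && cb >= cov_thr) {
      return List::create(_["seed"] = k + 1, _["score"] = score,
                          _["identity"] = id,
                          _["coverage_seed"] = ca, _["coverage_seq"] = cb);
    }
  }
  return List::create(_["seed"] = 0);
}

// Smith-Waterman-Gotoh local score only, vectorised over targets.
// [[Rcpp::export(name = ".sw_score_vec")]]
NumericVector sw_score_vec(IntegerVector q, List targets, IntegerMatrix S,
                           double open, double ext) {
  const int lq = q.size();
  NumericVector out(targets.size());
  std::vector<double> M(lq + 1), X(lq + 1), Y(lq + 1), Mp(lq + 1), Xp(lq + 1), Yp(lq + 1);
  for (int t = 0; t < targets.size(); ++t) {
    IntegerVector s = targets[t];
    const int ls = s.size();
    double best = 0.0;
    std::fill(Mp.begin(), Mp.end(), 0.0);
    std::fill(Xp.begin(), Xp.end(), NEG);
    std::fill(Yp.begin(), Yp.end(), NEG);
    for (int i = 1; i <= ls; ++i) {
      M[0] = 0.0; X[0] = NEG; Y[0] = NEG;
      const int si = s[i - 1];
      for (int j = 1; j <= lq; ++j) {
        double pred = Mp[j - 1];
        if (Xp[j - 1] > pred) pred = Xp[j - 1];
        if (Yp[j - 1] > pred) pred = Yp[j - 1];
        if (pred < 0.0) pred = 0.0;
        double m = pred + S(si, q[j - 1]);
        M[j] = m > 0.0 ? m : 0.0;
        // X: gap in query (consume target row i)
        double x = Mp[j] - (open + ext);
        if (Xp[j] - ext > x) x = Xp[j] - ext;
        if (Yp[j] - (open + ext) > x) x = Yp[j] - (open + ext);
        X[j] = x;
        // Y: gap in target (consume query col j)
        double y = M[j - 1] - (open + ext);
        if (X[j - 1] - (open + ext) > y) y = X[j - 1] - (open + ext);
        if (Y[j - 1] - ext > y) y = Y[j - 1] - ext;
        Y[j] = y;
        if (M[j] > best) best = M[j];
      }
      std::swap(M, Mp); std::swap(X, Xp); std::swap(Y, Yp);
    }
    out[t] = best;
  }
  return out;
}

// Local alignment with traceback: returns score, 1-based endpoint coordinates
// and column statistics for hit-table emission.
// [[Rcpp::export(name = ".sw_align")]]
List sw_align(IntegerVector a, IntegerVector b, IntegerMatrix S,
              double open, double ext) {
  const int la = a.size(), lb = b.size();
  const int w = lb + 1;
  std::vector<double> M((la + 1) * w, 0.0), X((la + 1) * w, NEG), Y((la + 1) * w, NEG);
  // traceback codes: 0/1/2 = predecessor matrix, 3 = local start
  std::vector<signed char> tM((la + 1) * w, 3), tX(tM), tY(tM);
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= la; ++i) {
    const int ai = a[i - 1];
    for (int j = 1; j <= lb; ++j) {
      const int c = i * w + j, d = c - w - 1, u = c - w, l = c - 1;
      double pred = 0.0; signed char tb = 3;
      if (M[d] > pred) { pred = M[d]; tb = 0; }
      if (X[d] > pred) { pred = X[d]; tb = 1; }
      if (Y[d] > pred) { pred = Y[d]; tb = 2; }
      double v = pred + S(ai, b[j - 1]);
      if (v <= 0.0) { M[c] = 0.0; tM[c] = 3; }
      else {
        M[c] = v; tM[c] = tb;
        if (v > best) { best = v; bi = i; bj = j; }
      }
      double x = M[u] - (open + ext); signed char xb = 0;
      if (X[u] - ext > x) { x = X[u] - ext; xb = 1; }
      if (Y[u] - (open + ext) > x) { x = Y[u] - (open + ext); xb = 2; }
      X[c] = x; tX[c] = xb;
      double y = M[l] - (open + ext); signed char yb = 0;
      if (X[l] - (open + ext) > y) { y = X[l] - (open + ext); yb = 1; }
      if (Y[l] - ext > y) { y = Y[l] - ext; yb = 2; }
      Y[c] = y; tY[c] = yb;
    }
  }
  if (best <= 0.0) return List::create(_["score"] = 0.0);
  std::vector<int> ops;
  int i = bi, j = bj, cur = 0;
  while (true) {
    const int c = i * w + j;
    if (cur == 0) {
      signed char tb = tM[c];
      ops.push_back(0); --i; --j;
      if (tb == 3) break;
      cur = tb;
    } else if (cur == 1) {
      ops.push_back(1); cur = tX[c]; --i;
    } else {
      ops.push_back(2); cur = tY[c]; --j;
    }
  }
  std::reverse(ops.begin(), ops.end());
  const int sa = i + 1, sb = j + 1;  // 1-based alignment starts
  AlnStats st = path_stats(ops, a, b, i, j);
  return List::create(
    _["score"] = best,
    _["a_start"] = sa, _["a_end"] = bi,
    _["b_start"] = sb, _["b_end"] = bj,
    _["length"] = (int)ops.size(),
    _["matches"] = st.matches,
    _["mismatches"] = st.mismatches,
    _["gap_opens"] = st.gap_opens);
}

// Profile-profile affine DP on a precomputed column-score matrix.
// Returns the op path (0 diag, 1 = gap in B / consume column of A, 2 = gap in A).
// [[Rcpp::export(name = ".profile_nw_path")]]
IntegerVector profile_nw_path(NumericMatrix colscore, double open, double ext) {
  const int la = colscore.nrow(), lb = colscore.ncol();
  const int w = lb + 1;
  std::vector<double> M((la + 1) * w, NEG), X(M), Y(M);
  std::vector<signed char> tM((la + 1) * w, -1), tX(tM), tY(tM);
  M[0] = 0.0;
  for (int i = 1; i <= la; ++i) { X[i * w] = -(open + i * ext); tX[i * w] = (i == 1) ? 0 : 1; }
  for (int j = 1; j <= lb; ++j) { Y[j] = -(open + j * ext); tY[j] = (j == 1) ? 0 : 2; }
  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      const int c = i * w + j, d = c - w - 1, u = c - w, l = c - 1;
      double best = M[d]; signed char tb = 0;
      if (X[d] > best) { best = X[d]; tb = 1; }
      if (Y[d] > best) { best = Y[d]; tb = 2; }
      M[c] = best + colscore(i - 1, j - 1); tM[c] = tb;
      best = M[u] - (open + ext); tb = 0;
      if (X[u] - ext > best) { best = X[u] - ext; tb = 1; }
      if (Y[u] - (open + ext) > best) { best = Y[u] - (open + ext); tb = 2; }
      X[c] = best; tX[c] = tb;
      best = M[l] - (open + ext); tb = 0;
      if (X[l] - (open + ext) > best) { best = X[l] - (open + ext); tb = 1; }
      if (Y[l] - ext > best) { best = Y[l] - ext; tb = 2; }
      Y[c] = best; tY[c] = tb;
    }
  }
  const int end = la * w + lb;
  double score = M[end]; int cur = 0;
  if (X[end] > score) { score = X[end]; cur = 1; }
  if (Y[end] > score) { score = Y[end]; cur = 2; }
  std::vector<int> ops;
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    int c = i * w + j;
    if (cur == 0) { ops.push_back(0); cur = tM[c]; --i; --j; }
    else if (cur == 1) { ops.push_back(1); cur = tX[c]; --i; }
    else { ops.push_back(2); cur = tY[c]; --j; }
  }
  std::reverse(ops.begin(), ops.end());
  return wrap(ops);
}
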