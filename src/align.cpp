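#include <Rcpp.h>
using namespace Rcpp;

// Gap of length k costs gap_open + k * gap_extend (Biostrings/EMBOSS
// convention), so the first gapped residue costs gap_open + gap_extend.

// Local alignment (Smith-Waterman with Gotoh affine gaps).
// a, b: 0-based integer codes indexing into S.
// Deterministic traceback: tie order diagonal > up (gap in b) > left
// (gap in a); the traced cell is the first maximum in row-major order.
// [[Rcpp::export]]
List sw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix S,
                  double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e30;
  const double go = gap_open + gap_extend, ge = gap_extend;

  NumericMatrix H(n + 1, m + 1), E(n + 1, m + 1), F(n + 1, m + 1);
  // state pointers: 0 none/stop, 1 diag, 2 up(E), 3 left(F)
  IntegerMatrix PH(n + 1, m + 1);
  // for E: 1 if opened from H, 0 if extended; same for F
  IntegerMatrix PE(n + 1, m + 1), PF(n + 1, m + 1);

  for (int j = 0; j <= m; ++j) { E(0, j) = NEG; F(0, j) = NEG; }
  for (int i = 0; i <= n; ++i) { E(i, 0) = NEG; F(i, 0) = NEG; }

  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double eo = H(i - 1, j) - go, ee = E(i - 1, j) - ge;
      if (eo >= ee) { E(i, j) = eo; PE(i, j) = 1; }
      else          { E(i, j) = ee; PE(i, j) = 0; }
      double fo = H(i, j - 1) - go, fe = F(i, j - 1) - ge;
      if (fo >= fe) { F(i, j) = fo; PF(i, j) = 1; }
      else          { F(i, j) = fe; PF(i, j) = 0; }
      double diag = H(i - 1, j - 1) + S(a[i - 1], b[j - 1]);
      double h = 0.0; int ph = 0;
      if (diag >= h) { h = diag; ph = 1; }
      if (E(i, j) > h) { h = E(i, j); ph = 2; }
      if (F(i, j) > h) { h = F(i, j); ph = 3; }
      H(i, j) = h; PH(i, j) = ph;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  // traceback
  std::vector<int> ai, bi_idx;  // 1-based positions, 0 for gap
  int i = bi, j = bj, state = 0;  // 0 = in H
  while (i > 0 && j > 0) {
    if (state == 0) {
      int p = PH(i, j);
      if (p == 0) break;
      if (p == 1) {
        ai.push_back(i); bi_idx.push_back(j); --i; --j;
      } else if (p == 2) {
        state = 2;
      } else {
        state = 3;
      }
    } else if (state == 2) {  // in E: a[i] vs gap
      ai.push_back(i); bi_idx.push_back(0);
      int opened = PE(i, j); --i;
      if (opened) state = 0;
    } else {                  // in F: gap vs b[j]
      ai.push_back(0); bi_idx.push_back(j);
      int opened = PF(i, j); --j;
      if (opened) state = 0;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi_idx.begin(), bi_idx.end());

  int a_start = 0, a_end = 0, b_start = 0, b_end = 0;
  for (size_t k = 0; k < ai.size(); ++k) {
    if (ai[k] > 0) { if (!a_start) a_start = ai[k]; a_end = ai[k]; }
    if (bi_idx[k] > 0) { if (!b_start) b_start = bi_idx[k]; b_end = bi_idx[k]; }
  }
  return List::create(
    _["score"] = best,
    _["a_idx"] = wrap(ai), _["b_idx"] = wrap(bi_idx),
    _["a_start"] = a_start, _["a_end"] = a_end,
    _["b_start"] = b_start, _["b_end"] = b_end);
}

// Score-only variant used for bulk all-vs-all runs (no traceback matrices,
// O(m) memory). Also returns identity over the optimal alignment? No --
// identity needs traceback, so all_vs_all calls sw_align_cpp; this fast
// path serves score screens where only the raw score is needed.
// [[Rcpp::export]]
double sw_score_cpp(IntegerVector a, IntegerVector b, NumericMatrix S,
                    double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e30;
  const double go = gap_open + gap_extend, ge = gap_extend;
  std::vector<double> H(m + 1, 0.0), E(m + 1, NEG);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    double diagH = H[0];  // H(i-1, j-1)
    double F = NEG;
    for (int j = 1; j <= m; ++j) {
      E[j] = std::max(H[j] - go, E[j] - ge);
      F = std::max(H[j - 1] - go, F - ge);
      double h = std::max(0.0, diagH + S(a[i - 1], b[j - 1]));
      h = std::max(h, std::max(E[j], F));
      diagH = H[j];
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// Global (Needleman-Wunsch) affine alignment over a precomputed
// column-pair score matrix; used for profile-profile merges in the
// progressive MSA. Returns the aligned column index paths (0 = gap).
// Tie order: diagonal > up > left.
// [[Rcpp::export]]
List nw_profile_cpp(NumericMatrix S, double gap_open, double gap_extend) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e30;
  const double go = gap_open + gap_extend, ge = gap_extend;
  NumericMatrix H(n + 1, m + 1), E(n + 1, m + 1), F(n + 1, m + 1);
  IntegerMatrix PH(n + 1, m + 1), PE(n + 1, m + 1), PF(n + 1, m + 1);

  H(0, 0) = 0; E(0, 0) = F(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    E(i, 0) = -go - (i - 1) * ge; H(i, 0) = E(i, 0);
    F(i, 0) = NEG; PH(i, 0) = 2; PE(i, 0) = (i == 1);
  }
  for (int j = 1; j <= m; ++j) {
    F(0, j) = -go - (j - 1) * ge; H(0, j) = F(0, j);
    E(0, j) = NEG; PH(0, j) = 3; PF(0, j) = (j == 1);
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double eo = H(i - 1, j) - go, ee = E(i - 1, j) - ge;
      if (eo >= ee) { E(i, j) = eo; PE(i, j) = 1; }
      else          { E(i, j) = ee; PE(i, j) = 0; }
      double fo = H(i, j - 1) - go, fe = F(i, j - 1) - ge;
      if (fo >= fe) { F(i, j) = fo; PF(i, j) = 1; }
      else          { F(i, j) = fe; PF(i, j) = 0; }
      double diag = H(i - 1, j - 1) + S(i - 1, j - 1);
      double h = diag; int ph = 1;
      if (E(i, j) > h) { h = E(i, j); ph = 2; }
      if (F(i, j) > h) { h = F(i, j); ph = 3; }
      H(i, j) = h; PH(i, j) = ph;
    }
  }
  std::vector<int> ai, bj;
  int i = n, j = m, state = 0;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int p = PH(i, j);
      if (p == 1) { ai.push_back(i); bj.push_back(j); --i; --j; }
      else if (p == 2) state = 2;
      else state = 3;
    } else if (state == 2) {
      ai.push_back(i); bj.push_back(0);
      int opened = PE(i, j); --i;
      if (opened) state = 0;
    } else {
      ai.push_back(0); bj.push_back(j);
      int opened = PF(i, j); --j;
      if (opened) state = 0;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bj.begin(), bj.end());
  return List::create(_["score"] = H(n, m),
                      _["a_idx"] = wrap(ai), _["b_idx"] = wrap(bj));
}
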