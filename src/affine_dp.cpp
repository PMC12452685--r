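#include <Rcpp.h>
using namespace Rcpp;

// Global alignment with affine gap penalties over a precomputed
// column-score matrix C (n x m): C(i, j) is the score of pairing
// row-object i+1 of A with column-object j+1 of B. The caller builds C,
// so the same kernel serves residue-residue and profile-profile
// alignment. A gap run of length L costs gap_open + L * gap_extend;
// runs touching either end of the alignment are scaled by term_factor
// (1 = classic global, 0.5 = half-weighted terminal gaps).
//
// Traceback ties are resolved deterministically: diagonal (match) is
// preferred over consuming A (gap in B), which is preferred over
// consuming B (gap in A).
// [[Rcpp::export]]
List affine_dp_cpp(NumericMatrix C, double gap_open, double gap_extend,
                   double term_factor) {
  const int n = C.nrow(), m = C.ncol();
  const double NEG = -1e30;

  // state 0 = M (diagonal), 1 = E (consume A, gap in B), 2 = F (consume B)
  NumericMatrix M(n + 1, m + 1), E(n + 1, m + 1), F(n + 1, m + 1);
  IntegerMatrix pM(n + 1, m + 1), pE(n + 1, m + 1), pF(n + 1, m + 1);

  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) { M(i, j) = E(i, j) = F(i, j) = NEG; }
  M(0, 0) = 0.0;
  for (int i = 1; i <= n; ++i) {   // leading gap in B (consume A)
    E(i, 0) = -term_factor * (gap_open + i * gap_extend);
    pE(i, 0) = 1;
  }
  for (int j = 1; j <= m; ++j) {   // leading gap in A (consume B)
    F(0, j) = -term_factor * (gap_open + j * gap_extend);
    pF(0, j) = 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: pair i with j
      double best = M(i - 1, j - 1); int arg = 0;
      if (E(i - 1, j - 1) > best) { best = E(i - 1, j - 1); arg = 1; }
      if (F(i - 1, j - 1) > best) { best = F(i - 1, j - 1); arg = 2; }
      M(i, j) = best + C(i - 1, j - 1);
      pM(i, j) = arg;

      // E: gap in B; a trailing run sits at j == m
      double s = (j == m) ? term_factor : 1.0;
      best = M(i - 1, j) - s * (gap_open + gap_extend); arg = 0;
      double cand = E(i - 1, j) - s * gap_extend;
      if (cand > best) { best = cand; arg = 1; }
      cand = F(i - 1, j) - s * (gap_open + gap_extend);
      if (cand > best) { best = cand; arg = 2; }
      E(i, j) = best;
      pE(i, j) = arg;

      // F: gap in A; a trailing run sits at i == n
      double t = (i == n) ? term_factor : 1.0;
      best = M(i, j - 1) - t * (gap_open + gap_extend); arg = 0;
      cand = E(i, j - 1) - t * (gap_open + gap_extend);
      if (cand > best) { best = cand; arg = 1; }
      cand = F(i, j - 1) - t * gap_extend;
      if (cand > best) { best = cand; arg = 2; }
      F(i, j) = best;
      pF(i, j) = arg;
    }
  }

  double score = M(n, m); int state = 0;
  if (E(n, m) > score) { score = E(n, m); state = 1; }
  if (F(n, m) > score) { score = F(n, m); state = 2; }

  // traceback
  std::vector<int> ai, bi;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int prev = pM(i, j);
      ai.push_back(i); bi.push_back(j);
      --i; --j;
      state = prev;
    } else if (state == 1) {
      int prev = pE(i, j);
      ai.push_back(i); bi.push_back(0);
      --i;
      state = prev;
    } else {
      int prev = pF(i, j);
      ai.push_back(0); bi.push_back(j);
      --j;
      state = prev;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());

  return List::create(_["score"] = score,
                      _["a_index"] = IntegerVector(ai.begin(), ai.end()),
                      _["b_index"] = IntegerVector(bi.begin(), bi.end()));
}
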