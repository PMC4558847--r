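#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment of two profiles with affine gap
// costs, Gotoh three-state recursion.  `S` holds the precomputed
// column-vs-column scores (n x m).  gap_open is the cost of the first
// gapped column of a run, gap_extend of each subsequent one (both <= 0).
// Returns 1-based column indices into each profile along the optimal path,
// 0 marking a gap.  Ties are broken deterministically: match > gap-in-B >
// gap-in-A.
// [[Rcpp::export]]
List align_profiles_dp(NumericMatrix S, double gap_open, double gap_extend) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e300;
  std::vector<double> M((n + 1) * (m + 1), NEG), X((n + 1) * (m + 1), NEG),
      Y((n + 1) * (m + 1), NEG);
  std::vector<unsigned char> tM((n + 1) * (m + 1)), tX((n + 1) * (m + 1)),
      tY((n + 1) * (m + 1));
  // state codes: 0 = M, 1 = X (consume A row, gap in B), 2 = Y (gap in A)
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[at(i, 0)] = gap_open + (i - 1) * gap_extend;
    tX[at(i, 0)] = 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[at(0, j)] = gap_open + (j - 1) * gap_extend;
    tY[at(0, j)] = 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int d = at(i - 1, j - 1), u = at(i - 1, j), l = at(i, j - 1),
                c = at(i, j);
      // M
      double best = M[d];
      unsigned char tb = 0;
      if (X[d] > best) { best = X[d]; tb = 1; }
      if (Y[d] > best) { best = Y[d]; tb = 2; }
      M[c] = best + S(i - 1, j - 1);
      tM[c] = tb;
      // X: gap in B
      best = M[u] + gap_open;
      tb = 0;
      if (X[u] + gap_extend > best) { best = X[u] + gap_extend; tb = 1; }
      if (Y[u] + gap_open > best) { best = Y[u] + gap_open; tb = 2; }
      X[c] = best;
      tX[c] = tb;
      // Y: gap in A
      best = M[l] + gap_open;
      tb = 0;
      if (X[l] + gap_open > best) { best = X[l] + gap_open; tb = 1; }
      if (Y[l] + gap_extend > best) { best = Y[l] + gap_extend; tb = 2; }
      Y[c] = best;
      tY[c] = tb;
    }
  }
  // traceback from the best end state
  int i = n, j = m;
  int state = 0;
  double bestEnd = M[at(n, m)];
  if (X[at(n, m)] > bestEnd) { bestEnd = X[at(n, m)]; state = 1; }
  if (Y[at(n, m)] > bestEnd) { bestEnd = Y[at(n, m)]; state = 2; }
  std::vector<int> ai, bi;
  ai.reserve(n + m);
  bi.reserve(n + m);
  while (i > 0 || j > 0) {
    if (state == 0) {
      int prev = tM[at(i, j)];
      ai.push_back(i);
      bi.push_back(j);
      --i; --j;
      state = prev;
    } else if (state == 1) {
      int prev = tX[at(i, j)];
      ai.push_back(i);
      bi.push_back(0);
      --i;
      state = prev;
    } else {
      int prev = tY[at(i, j)];
      ai.push_back(0);
      bi.push_back(j);
      --j;
      state = prev;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["a"] = wrap(ai), _["b"] = wrap(bi),
                      _["score"] = bestEnd);
}
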