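#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch/Gotoh) alignment of two column sequences given a
// precomputed column-pair score matrix S (n1 x n2).  Affine gaps: a gap of
// length L costs gap_open + L * gap_ext (terminal gaps penalised).  Returns
// the optimal score and the aligned column path (0 = gap).
// [[Rcpp::export]]
List affine_global_dp(NumericMatrix S, double gap_open, double gap_ext) {
  const int n1 = S.nrow(), n2 = S.ncol();
  const double NEG = -1e30;
  // M: i aligned to j; X: gap in seq2 (consume i); Y: gap in seq1 (consume j)
  NumericMatrix M(n1 + 1, n2 + 1), X(n1 + 1, n2 + 1), Y(n1 + 1, n2 + 1);
  IntegerMatrix tm(n1 + 1, n2 + 1), tx(n1 + 1, n2 + 1), ty(n1 + 1, n2 + 1);
  M(0, 0) = 0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= n1; ++i) {
    M(i, 0) = NEG; Y(i, 0) = NEG;
    X(i, 0) = -gap_open - gap_ext * i;
    tx(i, 0) = 1; // came from X
  }
  for (int j = 1; j <= n2; ++j) {
    M(0, j) = NEG; X(0, j) = NEG;
    Y(0, j) = -gap_open - gap_ext * j;
    ty(0, j) = 2;
  }
  for (int i = 1; i <= n1; ++i) {
    for (int j = 1; j <= n2; ++j) {
      // M
      double m0 = M(i - 1, j - 1), m1 = X(i - 1, j - 1), m2 = Y(i - 1, j - 1);
      int bm = 0; double vm = m0;
      if (m1 > vm) { vm = m1; bm = 1; }
      if (m2 > vm) { vm = m2; bm = 2; }
      M(i, j) = vm + S(i - 1, j - 1); tm(i, j) = bm;
      // X: gap in seq2
      double xo = M(i - 1, j) - gap_open - gap_ext;
      double xe = X(i - 1, j) - gap_ext;
      double yo = Y(i - 1, j) - gap_open - gap_ext;
      if (xe >= xo && xe >= yo) { X(i, j) = xe; tx(i, j) = 1; }
      else if (xo >= yo)        { X(i, j) = xo; tx(i, j) = 0; }
      else                      { X(i, j) = yo; tx(i, j) = 2; }
      // Y: gap in seq1
      double yo2 = M(i, j - 1) - gap_open - gap_ext;
      double ye = Y(i, j - 1) - gap_ext;
      double xo2 = X(i, j - 1) - gap_open - gap_ext;
      if (ye >= yo2 && ye >= xo2) { Y(i, j) = ye; ty(i, j) = 2; }
      else if (yo2 >= xo2)        { Y(i, j) = yo2; ty(i, j) = 0; }
      else                        { Y(i, j) = xo2; ty(i, j) = 1; }
    }
  }
  double best = M(n1, n2); int state = 0;
  if (X(n1, n2) > best) { best = X(n1, n2); state = 1; }
  if (Y(n1, n2) > best) { best = Y(n1, n2); state = 2; }

  std::vector<int> p1, p2;
  int i = n1, j = n2;
  while (i > 0 || j > 0) {
    if (j == 0) state = 1;
    else if (i == 0) state = 2;
    if (state == 0) {
      int prev = tm(i, j);
      p1.push_back(i); p2.push_back(j); --i; --j; state = prev;
    } else if (state == 1) {
      int prev = tx(i, j);
      p1.push_back(i); p2.push_back(0); --i; state = prev;
    } else {
      int prev = ty(i, j);
      p1.push_back(0); p2.push_back(j); --j; state = prev;
    }
  }
  std::reverse(p1.begin(), p1.end());
  std::reverse(p2.begin(), p2.end());
  return List::create(_["score"] = best,
                      _["path1"] = wrap(p1), _["path2"] = wrap(p2));
}
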