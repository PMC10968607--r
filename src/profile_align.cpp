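#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch, linear gap) alignment of two profiles.
// A, B: integer matrices, rows = sequences, cols = alignment columns;
// codes 0 = gap, 1..21 = residue codes indexing `sub` (code + 1).
// sub: (k+1) x (k+1) scoring matrix including the gap row/column.
// Column-vs-column score is the mean pairwise substitution score, computed
// as fA' S fB from per-column residue frequency vectors.
// [[Rcpp::export]]
List nw_profile(IntegerMatrix A, IntegerMatrix B, NumericMatrix sub,
                double gap) {
  const int la = A.ncol(), lb = B.ncol();
  const int k = sub.nrow();  // number of codes incl. gap

  // frequency vectors per column
  NumericMatrix fA(k, la), fB(k, lb);
  for (int j = 0; j < la; ++j) {
    for (int i = 0; i < A.nrow(); ++i) fA(A(i, j), j) += 1.0;
    for (int c = 0; c < k; ++c) fA(c, j) /= A.nrow();
  }
  for (int j = 0; j < lb; ++j) {
    for (int i = 0; i < B.nrow(); ++i) fB(B(i, j), j) += 1.0;
    for (int c = 0; c < k; ++c) fB(c, j) /= B.nrow();
  }
  // vA = S fA, precomputed per column of A
  NumericMatrix vA(k, la);
  for (int j = 0; j < la; ++j)
    for (int r = 0; r < k; ++r) {
      double s = 0.0;
      for (int c = 0; c < k; ++c) s += sub(r, c) * fA(c, j);
      vA(r, j) = s;
    }

  NumericMatrix S(la + 1, lb + 1);
  IntegerMatrix tb(la + 1, lb + 1);  // 0 diag, 1 up (gap in B), 2 left (gap in A)
  for (int i = 1; i <= la; ++i) { S(i, 0) = i * gap; tb(i, 0) = 1; }
  for (int j = 1; j <= lb; ++j) { S(0, j) = j * gap; tb(0, j) = 2; }
  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      double m = 0.0;
      for (int c = 0; c < k; ++c) m += vA(c, i - 1) * fB(c, j - 1);
      double d = S(i - 1, j - 1) + m;
      double u = S(i - 1, j) + gap;
      double l = S(i, j - 1) + gap;
      if (d >= u && d >= l)      { S(i, j) = d; tb(i, j) = 0; }
      else if (u >= l)           { S(i, j) = u; tb(i, j) = 1; }
      else                       { S(i, j) = l; tb(i, j) = 2; }
    }
  }

  // traceback; path entries are source column indices, 0 for a gap
  std::vector<int> pa, pb;
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    int t = tb(i, j);
    if (t == 0)      { pa.push_back(i); pb.push_back(j); --i; --j; }
    else if (t == 1) { pa.push_back(i); pb.push_back(0); --i; }
    else             { pa.push_back(0); pb.push_back(j); --j; }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["a"] = wrap(pa), _["b"] = wrap(pb),
                      _["score"] = S(la, lb));
}
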