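#include <Rcpp.h>
using namespace Rcpp;

// Global affine-gap alignment of two amino-acid profiles.
//
// A profile is an integer matrix (rows = sequences, columns = alignment
// columns); entries are 1-based codes into the substitution matrix, 0 for
// a gap. The score of matching column i of A with column j of B is the
// mean substitution score over all residue pairs (gap-containing pairs
// contribute 0). Gap open/extension penalties are positive costs applied
// per inserted column. Three-state (match / gap-in-B / gap-in-A) DP with
// traceback; ties prefer match, then a gap in the second profile, which
// makes the result deterministic.
//
// Returns two integer vectors over the merged columns: the source column
// in A (0 = gap) and in B (0 = gap).

// [[Rcpp::export(name = ".cppProfileAlign")]]
List cppProfileAlign(IntegerMatrix A, IntegerMatrix B, NumericMatrix S,
                     double gap_open, double gap_ext) {
  const int la = A.ncol(), lb = B.ncol();
  const int na = A.nrow(), nb = B.nrow();
  const double NEG = -1e30;

  // column score cache
  NumericMatrix colScore(la, lb);
  for (int i = 0; i < la; ++i) {
    for (int j = 0; j < lb; ++j) {
      double s = 0.0;
      for (int r = 0; r < na; ++r) {
        int a = A(r, i);
        if (a == 0) continue;
        for (int q = 0; q < nb; ++q) {
          int b = B(q, j);
          if (b == 0) continue;
          s += S(a - 1, b - 1);
        }
      }
      colScore(i, j) = s / (double)(na * nb);
    }
  }

  std::vector<std::vector<double> > M(la + 1, std::vector<double>(lb + 1, NEG));
  std::vector<std::vector<double> > X(la + 1, std::vector<double>(lb + 1, NEG));
  std::vector<std::vector<double> > Y(la + 1, std::vector<double>(lb + 1, NEG));
  M[0][0] = 0.0;
  for (int i = 1; i <= la; ++i) X[i][0] = -gap_open - gap_ext * (i - 1);
  for (int j = 1; j <= lb; ++j) Y[0][j] = -gap_open - gap_ext * (j - 1);

  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      double diag = std::max(M[i - 1][j - 1],
                             std::max(X[i - 1][j - 1], Y[i - 1][j - 1]));
      M[i][j] = diag + colScore(i - 1, j - 1);
      X[i][j] = std::max(M[i - 1][j] - gap_open, X[i - 1][j] - gap_ext);
      double yo = std::max(M[i][j - 1] - gap_open, Y[i][j - 1] - gap_ext);
      // also allow leaving an X-run into a Y-run and vice versa
      X[i][j] = std::max(X[i][j], Y[i - 1][j] - gap_open);
      Y[i][j] = std::max(yo, X[i][j - 1] - gap_open);
    }
  }

  // traceback
  std::vector<int> ai, bi;
  int i = la, j = lb;
  int state;  // 0 = M, 1 = X, 2 = Y
  double best = M[la][lb]; state = 0;
  if (X[la][lb] > best) { best = X[la][lb]; state = 1; }
  if (Y[la][lb] > best) { best = Y[la][lb]; state = 2; }
  double final_score = best;
  const double tol = 1e-9;
  while (i > 0 || j > 0) {
    if (state == 0) {
      double diag = M[i][j] - colScore(i - 1, j - 1);
      ai.push_back(i); bi.push_back(j);
      if (std::abs(M[i - 1][j - 1] - diag) < tol) state = 0;
      else if (std::abs(X[i - 1][j - 1] - diag) < tol) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {
      ai.push_back(i); bi.push_back(0);
      double v = X[i][j];
      if (std::abs((X[i - 1][j] - gap_ext) - v) < tol) state = 1;
      else if (std::abs((M[i - 1][j] - gap_open) - v) < tol) state = 0;
      else state = 2;
      --i;
      if (i == 0 && j > 0) state = 2;
    } else {
      ai.push_back(0); bi.push_back(j);
      double v = Y[i][j];
      if (std::abs((Y[i][j - 1] - gap_ext) - v) < tol) state = 2;
      else if (std::abs((M[i][j - 1] - gap_open) - v) < tol) state = 0;
      else state = 1;
      --j;
      if (j == 0 && i > 0) state = 1;
    }
    if (i == 0 && j > 0 && state != 2) state = 2;
    if (j == 0 && i > 0 && state != 1) state = 1;
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["a"] = wrap(ai), _["b"] = wrap(bi),
                      _["score"] = final_score);
}
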