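#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (a gap of length k costs
// open + k * ext) and a fully deterministic traceback:
//   * start cell: maximum score, ties broken by smallest query index i,
//     then smallest target index j;
//   * move preference at equal score: diagonal, then gap-in-target
//     (consume query), then gap-in-query (consume target).
// The pure-R oracle in the test suite mirrors these conventions.

// [[Rcpp::export]]
List sw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix sub,
                  double open, double ext) {
  const int n = a.size(), m = b.size();
  const int W = m + 1;
  std::vector<double> H((n + 1) * W, 0.0), E((n + 1) * W, R_NegInf),
      F((n + 1) * W, R_NegInf);
  std::vector<signed char> pH((n + 1) * W, 0), pE((n + 1) * W, 0),
      pF((n + 1) * W, 0);
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j;
      // E: last column consumes b[j] only (gap in query)
      double eH = H[c - 1] - open - ext;
      double eE = E[c - 1] - ext;
      if (eH >= eE) { E[c] = eH; pE[c] = 1; } else { E[c] = eE; pE[c] = 2; }
      // F: last column consumes a[i] only (gap in target)
      double fH = H[c - W] - open - ext;
      double fF = F[c - W] - ext;
      if (fH >= fF) { F[c] = fH; pF[c] = 1; } else { F[c] = fF; pF[c] = 2; }
      double d = H[c - W - 1] + sub(a[i - 1], b[j - 1]);
      double h = 0.0;
      signed char p = 0;
      if (d > h) { h = d; p = 1; }
      if (F[c] > h) { h = F[c]; p = 2; }
      if (E[c] > h) { h = E[c]; p = 3; }
      H[c] = h;
      pH[c] = p;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0.0)
    return List::create(_["aligned"] = false, _["score"] = 0.0,
                        _["n_match"] = 0, _["aln_length"] = 0,
                        _["q_start"] = 0, _["q_end"] = 0,
                        _["t_start"] = 0, _["t_end"] = 0);
  int i = bi, j = bj, state = 0; // 0 = H, 1 = F, 2 = E
  int n_match = 0, aln_len = 0;
  while (true) {
    const int c = i * W + j;
    if (state == 0) {
      signed char p = pH[c];
      if (p == 0) break;
      if (p == 1) {
        ++aln_len;
        if (a[i - 1] == b[j - 1]) ++n_match;
        --i; --j;
      } else if (p == 2) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      ++aln_len;
      if (pF[c] == 1) state = 0;
      --i;
    } else {
      ++aln_len;
      if (pE[c] == 1) state = 0;
      --j;
    }
  }
  return List::create(_["aligned"] = true, _["score"] = best,
                      _["n_match"] = n_match, _["aln_length"] = aln_len,
                      _["q_start"] = i + 1, _["q_end"] = bi,
                      _["t_start"] = j + 1, _["t_end"] = bj);
}
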