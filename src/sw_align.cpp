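#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment score with affine gaps.
//
// Sequences arrive as 0-based integer codes into `sub` (a symmetric
// substitution matrix). Gap convention follows EMBOSS `water`: a gap of
// length L costs gap_open + (L - 1) * gap_extend, i.e. the first gapped
// residue pays the opening penalty and each further residue pays the
// extension penalty.
//
// Recurrences (H = best alignment ending at (i,j), E = ending with a gap
// in `a`, F = ending with a gap in `b`); the empty alignment floors H at 0.

// [[Rcpp::export]]
double sw_score_cpp(IntegerVector a, IntegerVector b, NumericMatrix sub,
                    double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0), Fprev(m + 1, R_NegInf),
      Fcur(m + 1, R_NegInf);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    Hcur[0] = 0.0;
    double E = R_NegInf;
    Fcur[0] = R_NegInf;
    const int ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      E = std::max(Hcur[j - 1] - gap_open, E - gap_extend);
      Fcur[j] = std::max(Hprev[j] - gap_open, Fprev[j] - gap_extend);
      double h = Hprev[j - 1] + sub(ai, b[j - 1]);
      h = std::max(h, E);
      h = std::max(h, Fcur[j]);
      h = std::max(h, 0.0);
      Hcur[j] = h;
      if (h > best) best = h;
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
  }
  return best;
}

// All-vs-all upper-triangle scores for a list of encoded sequences;
// returns the full symmetric matrix of raw Smith-Waterman scores.

// [[Rcpp::export]]
NumericMatrix sw_score_matrix_cpp(List seqs, NumericMatrix sub,
                                  double gap_open, double gap_extend) {
  const int n = seqs.size();
  NumericMatrix out(n, n);
  std::vector<IntegerVector> enc(n);
  for (int i = 0; i < n; ++i) enc[i] = as<IntegerVector>(seqs[i]);
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      double s = sw_score_cpp(enc[i], enc[j], sub, gap_open, gap_extend);
      out(i, j) = s;
      out(j, i) = s;
    }
  }
  return out;
}
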