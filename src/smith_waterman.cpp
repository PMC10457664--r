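#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment score with affine gaps.
// Gap of length L costs gap_open + (L - 1) * gap_extend: the first gapped
// residue pays the opening penalty, each further residue the extension.
// Three-state recurrence: M (match/mismatch), X (gap in b), Y (gap in a),
// all floored at zero as usual for local alignment.
//
// seq_a / seq_b are integer codes (0-based rows into the substitution
// matrix); `sub` is the symmetric substitution matrix.
// [[Rcpp::export(name = ".sw_score_cpp")]]
int sw_score_cpp(IntegerVector seq_a, IntegerVector seq_b,
                 IntegerMatrix sub, int gap_open, int gap_extend) {
  const int n = seq_a.size(), m = seq_b.size();
  if (n == 0 || m == 0) return 0;
  const int NEG = -1000000000;
  std::vector<int> Mrow(m + 1, 0), Xrow(m + 1, NEG), Yrow(m + 1, NEG);
  std::vector<int> Mprev(m + 1, 0), Xprev(m + 1, NEG), Yprev(m + 1, NEG);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    std::swap(Mrow, Mprev); std::swap(Xrow, Xprev); std::swap(Yrow, Yprev);
    Mrow[0] = 0; Xrow[0] = NEG; Yrow[0] = NEG;
    const int ai = seq_a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int s = sub(ai, seq_b[j - 1]);
      int diag = std::max(std::max(Mprev[j - 1], Xprev[j - 1]),
                          Yprev[j - 1]);
      int M = std::max(0, diag + s);
      // gap in b (consume a residue of a): extend down
      int X = std::max(std::max(Mprev[j], Yprev[j]) - gap_open,
                       Xprev[j] - gap_extend);
      // gap in a (consume a residue of b): extend right
      int Y = std::max(std::max(Mrow[j - 1], Xrow[j - 1]) - gap_open,
                       Yrow[j - 1] - gap_extend);
      Mrow[j] = M; Xrow[j] = X; Yrow[j] = Y;
      int cell = std::max(M, std::max(X, Y));
      if (cell > best) best = cell;
    }
  }
  return best;
}
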