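#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive maximisation of a pairwise-additive partition score by
// depth-first enumeration of restricted-growth strings (RGS). The caller
// supplies B, where B(i, j) is the score contribution of placing nodes i
// and j (i < j) in the same block; per-node constant terms are handled on
// the R side. Enumeration order is RGS-lexicographic and a candidate
// replaces the incumbent only when strictly better (by `tol`), so ties
// resolve to the lexicographically smallest RGS.

namespace {

struct Search {
  const NumericMatrix &B;
  int n;
  double tol;
  std::vector<int> rgs, best_rgs;
  double best;

  Search(const NumericMatrix &B_, double tol_)
      : B(B_), n(B_.nrow()), tol(tol_), rgs(B_.nrow(), 0),
        best_rgs(B_.nrow(), 0), best(R_NegInf) {}

  void dfs(int t, int max_block, double score) {
    if (t == n) {
      if (score > best + tol) {
        best = score;
        best_rgs = rgs;
      }
      return;
    }
    for (int b = 0; b <= max_block + 1; ++b) {
      double gain = 0.0;
      for (int j = 0; j < t; ++j)
        if (rgs[j] == b) gain += B(j, t);
      rgs[t] = b;
      dfs(t + 1, b > max_block ? b : max_block, score + gain);
    }
    rgs[t] = 0;
  }
};

} // namespace

// [[Rcpp::export]]
List exact_partition_rgs(NumericMatrix B, double tol) {
  int n = B.nrow();
  if (n == 0)
    return List::create(_["assignment"] = IntegerVector(0),
                        _["score"] = 0.0);
  Search s(B, tol);
  s.rgs[0] = 0; // node 0 always opens block 0
  s.dfs(1, 0, 0.0);
  IntegerVector assignment(n);
  for (int i = 0; i < n; ++i) assignment[i] = s.best_rgs[i] + 1;
  return List::create(_["assignment"] = assignment, _["score"] = s.best);
}
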