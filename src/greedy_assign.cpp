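#include <Rcpp.h>
using namespace Rcpp;

// Greedy one-to-one assignment over a k x k cost matrix whose entries are
// visited in the ascending order given by `ord` (1-based indices into the
// column-major matrix, as returned by order()). Row i receives column j at
// the first visit where both are free; ties were already broken upstream by
// order()'s stable index ordering.
// [[Rcpp::export]]
IntegerVector greedy_assign_cpp(IntegerVector ord, int k) {
  IntegerVector perm(k, 0);
  std::vector<bool> used(k, false);
  int left = k;
  for (int m = 0; m < ord.size(); m++) {
    int idx = ord[m] - 1;
    int i = idx % k;
    int j = idx / k;
    if (perm[i] == 0 && !used[j]) {
      perm[i] = j + 1;
      used[j] = true;
      if (--left == 0) break;
    }
  }
  return perm;
}
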