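#include <Rcpp.h>
using namespace Rcpp;

// Window scores for PWM scanning. `idx` holds base codes 1..4 (A,C,G,T)
// with anything else treated as N/unknown; `scores` is the 4 x W
// integer-scaled score matrix. Windows containing a non-ACGT code are
// skipped. Returns the 1-based start positions and scores of windows
// scoring >= cutoff.
// [[Rcpp::export(name = ".window_hits")]]
List window_hits(IntegerVector idx, NumericMatrix scores, double cutoff) {
  const int l = idx.size();
  const int w = scores.ncol();
  // flat layout: col j holds entries [4j .. 4j+3]
  std::vector<double> s(4 * w);
  for (int j = 0; j < w; ++j)
    for (int b = 0; b < 4; ++b) s[4 * j + b] = scores(b, j);
  const int *x = INTEGER(idx);
  std::vector<int> pos;
  std::vector<double> sc;
  for (int p = 0; p + w <= l; ++p) {
    double tot = 0.0;
    bool ok = true;
    const int *xp = x + p;
    for (int j = 0; j < w; ++j) {
      const unsigned int b = (unsigned int)(xp[j] - 1);
      if (b > 3u) { ok = false; break; }
      tot += s[4 * j + b];
    }
    if (ok && tot >= cutoff) {
      pos.push_back(p + 1);
      sc.push_back(tot);
    }
  }
  return List::create(_["pos"] = pos, _["score"] = sc);
}
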