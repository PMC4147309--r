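#include <Rcpp.h>
using namespace Rcpp;

// Minimal-mismatch ungapped hits of a short read within a set of reference
// sequences. Scans every in-bounds offset of every reference, counting
// character mismatches with early exit, and returns all (reference, offset)
// pairs achieving the minimal mismatch count within `allow`. Strand-specific:
// sequences are compared exactly as given.
// [[Rcpp::export(name = ".bestHitsC")]]
SEXP best_hits(std::string read, CharacterVector refs, int allow) {
  const int n = (int) read.size();
  if (n == 0) return R_NilValue;
  int best = allow + 1;
  std::vector<int> hitRef, hitStart;
  for (int j = 0; j < refs.size(); ++j) {
    const char *ref = CHAR(STRING_ELT(refs, j));
    const int m = (int) LENGTH(STRING_ELT(refs, j));
    for (int s = 0; s + n <= m; ++s) {
      int mm = 0;
      for (int k = 0; k < n; ++k) {
        if (ref[s + k] != read[k] && ++mm >= best + 1) break;
      }
      if (mm < best) {
        best = mm;
        hitRef.clear(); hitStart.clear();
        hitRef.push_back(j + 1); hitStart.push_back(s + 1);
      } else if (mm == best && best <= allow) {
        hitRef.push_back(j + 1); hitStart.push_back(s + 1);
      }
    }
  }
  if (best > allow || hitRef.empty()) return R_NilValue;
  return List::create(_["mismatches"] = best,
                      _["refIndex"] = wrap(hitRef),
                      _["start"] = wrap(hitStart));
}
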