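#include <Rcpp.h>
using namespace Rcpp;

// 32-bit FNV-1a over UTF-8 bytes. Stable across runs and platforms; used as
// the feature-identifier hash for circular fingerprints. Returned as doubles
// because R integers cannot hold the full unsigned 32-bit range.
// [[Rcpp::export]]
NumericVector fnv1a32(CharacterVector x) {
  const uint32_t prime = 16777619u;
  const uint32_t offset = 2166136261u;
  R_xlen_t n = x.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (CharacterVector::is_na(x[i])) { out[i] = NA_REAL; continue; }
    const char *s = CHAR(STRING_ELT(x, i));
    uint32_t h = offset;
    for (; *s; ++s) {
      h ^= (uint32_t)(unsigned char)(*s);
      h *= prime;
    }
    out[i] = (double)h;
  }
  return out;
}
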