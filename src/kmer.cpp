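#include <Rcpp.h>
#include <unordered_set>
#include <cstdint>
using namespace Rcpp;

// Exact shared-k-mer test via a 64-bit polynomial rolling hash.
//
// Used as a provably safe reject-filter before whole-genome alignment at
// high identity thresholds: any global alignment with identity >= t has at
// most (1-t)*cols non-identical columns, so its longest exact run spans at
// least t/(1-t) columns (~99 for t = 0.99). If the two sequences share no
// exact k-mer with k below that bound, no alignment can reach the
// threshold. Hash collisions can only produce false "shared" answers,
// which merely cost one alignment; they never cause a wrong rejection.

// [[Rcpp::export]]
bool cpp_shared_kmer(CharacterVector a, CharacterVector b, int k) {
  const char* sa = CHAR(STRING_ELT(a, 0));
  const char* sb = CHAR(STRING_ELT(b, 0));
  const size_t na = strlen(sa), nb = strlen(sb);
  if (na < (size_t)k || nb < (size_t)k) return false;
  const uint64_t base = 1099511628211ULL;
  uint64_t pw = 1;  // base^(k-1)
  for (int i = 1; i < k; ++i) pw *= base;

  std::unordered_set<uint64_t> seen;
  seen.reserve(na * 2);
  uint64_t h = 0;
  for (size_t i = 0; i < na; ++i) {
    if (i >= (size_t)k) h -= pw * (uint64_t)(unsigned char)sa[i - k];
    h = h * base + (uint64_t)(unsigned char)sa[i];
    if (i + 1 >= (size_t)k) seen.insert(h);
  }
  h = 0;
  for (size_t i = 0; i < nb; ++i) {
    if (i >= (size_t)k) h -= pw * (uint64_t)(unsigned char)sb[i - k];
    h = h * base + (uint64_t)(unsigned char)sb[i];
    if (i + 1 >= (size_t)k && seen.count(h)) return true;
  }
  return false;
}
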