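#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

// Finalizer from the splitmix64 generator; good avalanche, no crypto.
static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// Seeded FNV-1a over the bytes of a string, finalized with mix64.
static inline uint64_t hash_bytes(const char *s, size_t n, uint64_t seed) {
  uint64_t h = 14695981039346656037ULL ^ mix64(seed);
  for (size_t i = 0; i < n; ++i) {
    h ^= (uint64_t)(unsigned char)s[i];
    h *= 1099511628211ULL;
  }
  return mix64(h);
}

// Hash values are truncated to 53 bits so every value is exactly
// representable as an R double; ordering comparisons stay exact.
static const uint64_t MASK53 = (1ULL << 53) - 1ULL;

// [[Rcpp::export(name = ".hash_strings")]]
NumericVector hash_strings_cpp(CharacterVector x, double seed) {
  const uint64_t s = (uint64_t)seed;
  const R_xlen_t n = x.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *p = CHAR(STRING_ELT(x, i));
    out[i] = (double)(hash_bytes(p, std::strlen(p), s) & MASK53);
  }
  return out;
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 0;
  }
}

// Canonical k-mer set of a nucleotide string: each window of length k made
// only of A/C/G/T (case-insensitive) contributes the lexicographic minimum
// of the window and its reverse complement; other windows are skipped.
// [[Rcpp::export(name = ".canonical_kmer_set")]]
CharacterVector canonical_kmer_set_cpp(std::string seq, int k) {
  if (k < 2) stop("k-mer size must be >= 2");
  std::unordered_set<std::string> seen;
  const size_t n = seq.size();
  if (n >= (size_t)k) {
    for (size_t i = 0; i < n; ++i) {
      char c = seq[i];
      if (c >= 'a' && c <= 'z') seq[i] = c - ('a' - 'A');
    }
    std::string fwd((size_t)k, 'N'), rev((size_t)k, 'N');
    // last_bad: most recent position holding a non-ACGT symbol
    long long last_bad = -1;
    for (size_t i = 0; i + (size_t)k <= n; ++i) {
      if (i == 0) {
        for (size_t j = 0; j < (size_t)k; ++j)
          if (!comp_base(seq[j])) last_bad = (long long)j;
      } else {
        if (!comp_base(seq[i + (size_t)k - 1]))
          last_bad = (long long)(i + (size_t)k - 1);
      }
      if (last_bad >= (long long)i) continue;
      for (size_t j = 0; j < (size_t)k; ++j) {
        char c = seq[i + j];
        fwd[j] = c;
        rev[(size_t)k - 1 - j] = comp_base(c);
      }
      seen.insert(rev < fwd ? rev : fwd);
    }
  }
  CharacterVector out(seen.size());
  R_xlen_t i = 0;
  for (const auto &s : seen) out[i++] = s;
  return out;
}
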