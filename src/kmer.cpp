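#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// splitmix64: a high-quality seedable 64-bit mixer (bijective on uint64).
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1; // ambiguity codes / N: window is skipped
  }
}

// Collect hash values of all (optionally canonical) k-mers of `seqs`,
// pooled across records; windows containing non-ACGT characters are skipped
// and no window spans a record boundary. Hashes are splitmix64 of the
// 2-bit-packed k-mer xored with a seed-derived constant, truncated to the top
// 53 bits so each value is exactly representable as an R double.
static void collect_hashes(const std::vector<std::string>& seqs, int k,
                           bool canonical, double hash_seed,
                           std::vector<double>& out) {
  const uint64_t seed_mix =
      splitmix64(static_cast<uint64_t>(hash_seed) ^ (0xABCDULL + (uint64_t)k));
  const int shift_rc = 2 * (k - 1);
  const uint64_t mask =
      (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  for (const std::string& s : seqs) {
    const int n = (int)s.size();
    if (n < k) continue;
    uint64_t fwd = 0, rc = 0;
    int run = 0; // length of current valid-base run
    for (int i = 0; i < n; ++i) {
      int c = base_code(s[i]);
      if (c < 0) { run = 0; fwd = 0; rc = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      rc = (rc >> 2) | ((uint64_t)(3 - c) << shift_rc);
      if (++run >= k) {
        uint64_t code = canonical ? std::min(fwd, rc) : fwd;
        out.push_back((double)(splitmix64(code ^ seed_mix) >> 11));
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector kmer_hashes_cpp(std::vector<std::string> seqs, int k,
                              bool canonical, double hash_seed) {
  if (k < 1 || k > 32) stop("k must be in 1..32");
  std::vector<double> out;
  collect_hashes(seqs, k, canonical, hash_seed, out);
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
  return wrap(out);
}

// Number of distinct (non-canonical unless asked) k-mers, pooled over records.
// [[Rcpp::export]]
double kmer_distinct_count_cpp(std::vector<std::string> seqs, int k,
                               bool canonical) {
  if (k < 1 || k > 32) stop("k must be in 1..32");
  std::vector<double> out;
  collect_hashes(seqs, k, canonical, 0.0, out);
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
  return (double)out.size();
}

// Size of the intersection of two sorted unique double vectors.
// [[Rcpp::export]]
double sorted_intersection_size_cpp(NumericVector a, NumericVector b) {
  R_xlen_t i = 0, j = 0;
  double n = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] < b[j]) ++i;
    else if (a[i] > b[j]) ++j;
    else { ++n; ++i; ++j; }
  }
  return n;
}
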