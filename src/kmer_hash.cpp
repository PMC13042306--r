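#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <string>

using namespace Rcpp;

// MurmurHash3 64-bit finalizer (fmix64). Applied to the 2-bit-packed
// canonical k-mer XORed with the seed. Hashes are truncated to the top
// 53 bits so they round-trip exactly through R doubles.
static inline uint64_t fmix64(uint64_t k) {
  k ^= k >> 33;
  k *= 0xff51afd7ed558ccdULL;
  k ^= k >> 33;
  k *= 0xc4ceb9fe1a85ec53ULL;
  k ^= k >> 33;
  return k;
}

static inline uint64_t hash_code(uint64_t code, uint64_t seed) {
  // mix the seed in twice so seed = 0 is a real permutation too
  uint64_t h = fmix64(code ^ (seed * 0x9e3779b97f4a7c15ULL + 1));
  return h >> 11;  // keep 53 bits: exactly representable as double
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;  // N or any ambiguity code: k-mer is skipped
  }
}

// Collect hashes of all canonical k-mers (lexicographic min of forward
// strand and reverse complement; with A<C<G<T this equals numeric order
// of the 2-bit packing). k-mers containing non-ACGT bases are skipped.
static void canonical_hashes(const std::string& seq, int k, uint64_t seed,
                             std::vector<uint64_t>& out) {
  const size_t n = seq.size();
  if (k < 1 || n < (size_t)k) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rev = 0;
  int run = 0;  // length of current run of valid bases
  for (size_t i = 0; i < n; ++i) {
    int c = base_code(seq[i]);
    if (c < 0) { run = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
    if (++run >= k) {
      uint64_t canon = fwd < rev ? fwd : rev;
      out.push_back(hash_code(canon, seed));
    }
  }
}

// [[Rcpp::export]]
NumericVector kmer_hashes_cpp(std::string seq, int k, double seed) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  std::vector<uint64_t> h;
  canonical_hashes(seq, k, (uint64_t)seed, h);
  std::sort(h.begin(), h.end());
  h.erase(std::unique(h.begin(), h.end()), h.end());
  NumericVector out(h.size());
  for (size_t i = 0; i < h.size(); ++i) out[i] = (double)h[i];
  return out;
}

// Bottom-s sketch: the s smallest distinct canonical k-mer hashes plus
// the count of distinct k-mers observed.
// [[Rcpp::export]]
List sketch_cpp(std::string seq, int k, int s, double seed) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  if (s < 1) stop("sketch size must be >= 1");
  std::vector<uint64_t> h;
  canonical_hashes(seq, k, (uint64_t)seed, h);
  std::sort(h.begin(), h.end());
  h.erase(std::unique(h.begin(), h.end()), h.end());
  const size_t keep = std::min((size_t)s, h.size());
  NumericVector hashes(keep);
  for (size_t i = 0; i < keep; ++i) hashes[i] = (double)h[i];
  return List::create(_["hashes"] = hashes,
                      _["n_kmers"] = (double)h.size());
}

// Hash one k-mer string as-is (no canonicalization): used by tests as a
// scalar oracle against the rolling packing above.
// [[Rcpp::export]]
double hash_kmer_cpp(std::string kmer, double seed) {
  uint64_t code = 0;
  for (size_t i = 0; i < kmer.size(); ++i) {
    int c = base_code(kmer[i]);
    if (c < 0) stop("k-mer contains a non-ACGT base");
    code = (code << 2) | (uint64_t)c;
  }
  return (double)hash_code(code, (uint64_t)seed);
}

// FNV-1a over raw bytes; used for run-config provenance hashes.
// [[Rcpp::export]]
std::string hash_string_cpp(std::string s) {
  uint64_t h = 0xcbf29ce484222325ULL;
  for (size_t i = 0; i < s.size(); ++i) {
    h ^= (uint64_t)(unsigned char)s[i];
    h *= 0x100000001b3ULL;
  }
  char buf[17];
  snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
  return std::string(buf);
}
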