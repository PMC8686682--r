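#ifndef POLARMIN_KMERS_H
#define POLARMIN_KMERS_H

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <unordered_map>

// 2-bit packed k-mers over {A,C,G,T}; k <= 31 so a packed k-mer plus
// headroom fits in 64 bits.
static const int POLARMIN_MAX_K = 31;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline char code_base(int c) {
  static const char b[4] = {'A', 'C', 'G', 'T'};
  return b[c & 3];
}

// splitmix64 finalizer: avalanche mixing for the seeded pseudo-random rank
static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline uint64_t kmer_hash(uint64_t packed, uint64_t seed) {
  return mix64(packed ^ mix64(seed));
}

// Strict total order on k-mers: layer index (smaller compares less, k-mers
// outside all layers get INT_MAX), then seeded hash, then the packed value
// (lexicographic rank) to break hash collisions.
struct KmerRank {
  int layer;
  uint64_t hash;
  uint64_t packed;
  bool operator<(const KmerRank& o) const {
    if (layer != o.layer) return layer < o.layer;
    if (hash != o.hash) return hash < o.hash;
    return packed < o.packed;
  }
  bool operator==(const KmerRank& o) const { return packed == o.packed; }
};

struct KmerScan {
  std::vector<uint64_t> packed;  // packed[i] meaningful iff valid[i]
  std::vector<char> valid;       // k-mer starting at i lies in one fragment
};

inline KmerScan scan_kmers(const Rcpp::IntegerVector& codes, int k) {
  int n = codes.size();
  KmerScan ks;
  ks.packed.assign(n, 0);
  ks.valid.assign(n, 0);
  if (k < 1 || k > POLARMIN_MAX_K) Rcpp::stop("k must be between 1 and 31");
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t cur = 0;
  int run = 0;
  for (int i = 0; i < n; i++) {
    int c = codes[i];
    if (c < 0) { run = 0; cur = 0; continue; }
    cur = ((cur << 2) | (uint64_t)c) & mask;
    run++;
    if (run >= k) {
      ks.packed[i - k + 1] = cur;
      ks.valid[i - k + 1] = 1;
    }
  }
  return ks;
}

inline bool pack_kmer_string(const std::string& s, int k, uint64_t* out) {
  if ((int)s.size() != k) return false;
  uint64_t p = 0;
  for (int i = 0; i < k; i++) {
    int c = base_code(s[i]);
    if (c < 0) return false;
    p = (p << 2) | (uint64_t)c;
  }
  *out = p;
  return true;
}

inline std::string unpack_kmer(uint64_t p, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; i--) {
    s[i] = code_base((int)(p & 3));
    p >>= 2;
  }
  return s;
}

// layer lookup table built from flattened (kmer, layer id) pairs
inline std::unordered_map<uint64_t, int> build_layer_map(
    const Rcpp::CharacterVector& layer_kmers,
    const Rcpp::IntegerVector& layer_ids, int k) {
  std::unordered_map<uint64_t, int> m;
  if (layer_kmers.size() != layer_ids.size())
    Rcpp::stop("layer k-mers and layer ids must have equal length");
  for (int i = 0; i < layer_kmers.size(); i++) {
    std::string s = Rcpp::as<std::string>(layer_kmers[i]);
    uint64_t p;
    if (!pack_kmer_string(s, k, &p))
      Rcpp::stop("invalid layer k-mer '%s' (need length %d over ACGT)",
                 s.c_str(), k);
    auto it = m.find(p);
    if (it == m.end() || layer_ids[i] < it->second) m[p] = layer_ids[i];
  }
  return m;
}

#endif
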