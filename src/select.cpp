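#include "kmers.h"
#include <deque>
using namespace Rcpp;

// Encode sequence records to integer codes (A,C,G,T -> 0..3, anything else
// -1). Multiple records are concatenated with a single -1 separator so that
// windows never span record boundaries.
// [[Rcpp::export]]
IntegerVector cpp_encode_records(CharacterVector records) {
  size_t total = 0;
  for (int r = 0; r < records.size(); r++)
    total += LENGTH(STRING_ELT(records, r)) + (r > 0 ? 1 : 0);
  IntegerVector codes((R_xlen_t)total);
  size_t j = 0;
  for (int r = 0; r < records.size(); r++) {
    if (r > 0) codes[j++] = -1;
    const char* s = CHAR(STRING_ELT(records, r));
    int len = LENGTH(STRING_ELT(records, r));
    for (int i = 0; i < len; i++) codes[j++] = base_code(s[i]);
  }
  return codes;
}

// TRUE where a break-free k-mer starts.
// [[Rcpp::export]]
LogicalVector cpp_valid_starts(IntegerVector codes, int k) {
  KmerScan ks = scan_kmers(codes, k);
  int n = codes.size();
  LogicalVector out(n);
  for (int i = 0; i < n; i++) out[i] = ks.valid[i] != 0;
  return out;
}

// Window-by-window minimizer selection over every fragment (maximal break
// free run) of the sequence. Returns 0-based selected positions, charged
// context count and bookkeeping totals.
// [[Rcpp::export]]
List cpp_select_positions(IntegerVector codes, int w, int k,
                          CharacterVector layer_kmers, IntegerVector layer_ids,
                          int seed) {
  if (w < 2) stop("w must be >= 2");
  KmerScan ks = scan_kmers(codes, k);
  std::unordered_map<uint64_t, int> lmap =
      build_layer_map(layer_kmers, layer_ids, k);
  uint64_t useed = (uint64_t)seed;
  int n = codes.size();

  auto rank_at = [&](int i) {
    KmerRank r;
    r.packed = ks.packed[i];
    auto it = lmap.find(r.packed);
    r.layer = (it == lmap.end()) ? INT_MAX : it->second;
    r.hash = kmer_hash(r.packed, useed);
    return r;
  };

  std::vector<int> positions;
  long long n_charged = 0, n_windows = 0, n_contexts = 0, n_kmers = 0;
  long long n_fragments = 0, n_frag_windows = 0;

  int i = 0;
  while (i < n) {
    if (!ks.valid[i]) { i++; continue; }
    int j = i;
    while (j < n && ks.valid[j]) j++;  // valid k-mer starts [i, j)
    int nk = j - i;
    n_fragments++;
    n_kmers += nk;
    if (nk >= w) {
      n_frag_windows++;
      n_windows += nk - w + 1;
      n_contexts += nk - w;
      std::deque<int> dq;  // candidate positions, ranks increasing
      int prev_sel = -1;
      for (int t = i; t < j; t++) {
        KmerRank rt = rank_at(t);
        while (!dq.empty() && rt < rank_at(dq.back())) dq.pop_back();
        dq.push_back(t);
        int wstart = t - w + 1;
        if (wstart < i) continue;
        while (dq.front() < wstart) dq.pop_front();
        int sel = dq.front();
        if (sel != prev_sel) {
          positions.push_back(sel);
          if (prev_sel >= 0) n_charged++;  // context ending here is charged
          prev_sel = sel;
        }
      }
    }
    i = j;
  }

  return List::create(
      _["positions"] = wrap(positions), _["n_selected"] = (double)positions.size(),
      _["n_charged"] = (double)n_charged, _["n_windows"] = (double)n_windows,
      _["n_contexts"] = (double)n_contexts, _["n_kmers"] = (double)n_kmers,
      _["n_fragments"] = (double)n_fragments,
      _["n_fragments_with_windows"] = (double)n_frag_windows);
}

// Dense ranks (1-based, leftmost-tie-free: equal k-mers share a rank) of a
// set of k-mers under the layered + seeded-hash order.
// [[Rcpp::export]]
IntegerVector cpp_rank_kmers(CharacterVector kmers, CharacterVector layer_kmers,
                             IntegerVector layer_ids, int k, int seed) {
  int m = kmers.size();
  std::unordered_map<uint64_t, int> lmap =
      build_layer_map(layer_kmers, layer_ids, k);
  std::vector<KmerRank> rk(m);
  for (int i = 0; i < m; i++) {
    std::string s = as<std::string>(kmers[i]);
    uint64_t p;
    if (!pack_kmer_string(s, k, &p))
      stop("invalid k-mer '%s' (need length %d over ACGT)", s.c_str(), k);
    auto it = lmap.find(p);
    rk[i] = {it == lmap.end() ? INT_MAX : it->second, kmer_hash(p, (uint64_t)seed), p};
  }
  std::vector<int> idx(m);
  for (int i = 0; i < m; i++) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return rk[a] < rk[b]; });
  IntegerVector out(m);
  int r = 0;
  for (int i = 0; i < m; i++) {
    if (i > 0 && !(rk[idx[i]] == rk[idx[i - 1]])) r = i;
    out[idx[i]] = r + 1;
  }
  return out;
}

// Positions (0-based) of all occurrences of the given k-mers, with the
// 1-based index of the matching k-mer. Used for polar set validation and
// link energy, where member occurrence lists are needed.
// [[Rcpp::export]]
List cpp_find_kmer_occurrences(IntegerVector codes, int k,
                               CharacterVector kmers) {
  KmerScan ks = scan_kmers(codes, k);
  std::unordered_map<uint64_t, int> want;
  for (int i = 0; i < kmers.size(); i++) {
    uint64_t p;
    std::string s = as<std::string>(kmers[i]);
    if (!pack_kmer_string(s, k, &p))
      stop("invalid k-mer '%s' (need length %d over ACGT)", s.c_str(), k);
    if (want.count(p)) stop("duplicated k-mer '%s'", s.c_str());
    want[p] = i + 1;
  }
  std::vector<int> pos, idx;
  int n = codes.size();
  for (int i = 0; i < n; i++) {
    if (!ks.valid[i]) continue;
    auto it = want.find(ks.packed[i]);
    if (it != want.end()) {
      pos.push_back(i);
      idx.push_back(it->second);
    }
  }
  return List::create(_["pos"] = wrap(pos), _["kmer"] = wrap(idx));
}
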