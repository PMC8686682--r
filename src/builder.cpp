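#include "kmers.h"
#include "blocks.h"
#include <random>
#include <set>
#include <unordered_set>
using namespace Rcpp;

// Union view over two linked-block structures: the frozen elements of all
// previous layers and the mutable elements of the layer under
// construction. Link-energy aggregates are maintained over the union.
struct UnionBlocks {
  LinkedBlocksImpl prev, cur;
  int w;
  long long acov, aele, aseg;

  UnionBlocks(int n, int w_) : prev(n, w_), cur(n, w_), w(w_),
                               acov(0), aele(0), aseg(0) {}

  int peekL(int x) const {
    int a = prev.peekL(x), b = cur.peekL(x);
    return a > b ? a : b;
  }
  int peekR(int x) const {
    int a = prev.peekR(x), b = cur.peekR(x);
    if (a < 0) return b;
    if (b < 0) return a;
    return a < b ? a : b;
  }

  // x is absent from both block sets when deltas are computed
  void apply(int x, int sign) {
    int pl = peekL(x), pr = peekR(x);
    if (sign > 0 &&
        ((pl >= 0 && 2 * (x - pl) <= w) || (pr >= 0 && 2 * (pr - x) <= w)))
      stop("internal error: polar spacing violated at %d", x);
    long long dl = pl >= 0 ? x - pl : -1, dr = pr >= 0 ? pr - x : -1;
    long long ov_l = dl >= 0 ? (w - dl + 1) : 0;
    long long ov_r = dr >= 0 ? (w - dr + 1) : 0;
    long long ov_lr = (dl >= 0 && dr >= 0 && dl + dr <= w) ? (w - dl - dr + 1) : 0;
    acov += sign * ((w + 1) - ov_l - ov_r + ov_lr);
    aele += sign;
    aseg += sign * (1 - (dl >= 0 ? 1 : 0) - (dr >= 0 ? 1 : 0));
  }

  void addPrev(int x) { apply(x, +1); prev.set_raw(x); }
  void addCur(int x) { apply(x, +1); cur.set_raw(x); }
  void removeCur(int x) { cur.clear_raw(x); apply(x, -1); }

  double L() const { return 2.0 * (double)acov / (w + 1.0) - aele - aseg; }
};

static std::vector<int> sa_occ(const IntegerVector& sa, const IntegerVector& isa,
                               const IntegerVector& lcp, int t, int k) {
  int n = sa.size();
  int r = isa[t];
  std::vector<int> res;
  res.push_back(sa[r]);
  for (int j = r; j > 0 && lcp[j] >= k; j--) res.push_back(sa[j - 1]);
  for (int j = r + 1; j < n && lcp[j] >= k; j++) res.push_back(sa[j]);
  std::sort(res.begin(), res.end());
  return res;
}

// One round of the polar set heuristic (a single layer). Locations
// congruent to `offset` mod w are visited in a seeded shuffled order; each
// new admissible k-mer is inserted, evicting conflicting current-layer
// k-mers (non-monotonic) or only when the total link energy strictly
// increases (monotonic). Previous-layer elements drive coverage queries and
// proximity filtering. Finally, members forming no link are pruned.
// [[Rcpp::export]]
List cpp_polar_round(IntegerVector codes, int w, int k,
                     IntegerVector sa, IntegerVector isa, IntegerVector lcp,
                     IntegerVector freq, IntegerVector prev_elements,
                     int thr, int offset, int max_freq, int seed,
                     bool monotonic) {
  if (w < 2) stop("w must be >= 2");
  if (thr < 1 || 2 * thr <= w)
    stop("spacing threshold must exceed w/2 (slackness < 1/2)");
  int n = codes.size();
  KmerScan ks = scan_kmers(codes, k);
  UnionBlocks ub(n, w);
  for (int i = 0; i < prev_elements.size(); i++) ub.addPrev(prev_elements[i]);
  double L_before = ub.L();

  // covered by previous layers: elements l < p < r with r - l <= w
  auto covered = [&](int p) {
    int l = ub.prev.peekL(p - 1), r = ub.prev.peekR(p + 1);
    return l >= 0 && r >= 0 && r - l <= w;
  };

  std::vector<int> cand;
  for (int t = offset; t < n; t += w)
    if (ks.valid[t]) cand.push_back(t);
  std::mt19937_64 rng((uint64_t)(unsigned int)seed);
  std::shuffle(cand.begin(), cand.end(), rng);

  std::unordered_set<uint64_t> processed;
  std::unordered_map<uint64_t, std::vector<int> > members;
  std::vector<uint64_t> pos_kmer(n, 0);
  std::vector<double> trace;
  long long n_considered = 0, n_accepted = 0, n_rejected_mono = 0, n_evicted = 0;

  for (size_t ci = 0; ci < cand.size(); ci++) {
    int t = cand[ci];
    uint64_t m = ks.packed[t];
    if (processed.count(m)) continue;
    processed.insert(m);
    if (freq[t] > max_freq) continue;
    std::vector<int> occ = sa_occ(sa, isa, lcp, t, k);
    std::vector<int> U;
    for (size_t i = 0; i < occ.size(); i++)
      if (!covered(occ[i])) U.push_back(occ[i]);
    if (U.empty()) continue;
    bool ok = true;
    for (size_t i = 1; i < U.size() && ok; i++)
      if (U[i] - U[i - 1] < thr) ok = false;  // self-collision
    for (size_t i = 0; i < U.size() && ok; i++) {
      int pl = ub.prev.peekL(U[i]), pr = ub.prev.peekR(U[i]);
      if ((pl >= 0 && U[i] - pl < thr) || (pr >= 0 && pr - U[i] < thr))
        ok = false;  // too close to a previous layer
    }
    if (!ok) continue;
    n_considered++;

    // conflicting current-layer k-mers via nearest-element peeks
    std::set<uint64_t> confl;
    for (size_t i = 0; i < U.size(); i++) {
      int cl = ub.cur.peekL(U[i]), cr = ub.cur.peekR(U[i]);
      if (cl >= 0 && U[i] - cl < thr) confl.insert(pos_kmer[cl]);
      if (cr >= 0 && cr - U[i] < thr) confl.insert(pos_kmer[cr]);
    }

    long long a0 = ub.acov, e0 = ub.aele, s0 = ub.aseg;
    std::vector<int> evicted;
    for (std::set<uint64_t>::iterator it = confl.begin(); it != confl.end(); ++it) {
      std::vector<int>& mem = members[*it];
      for (size_t q = 0; q < mem.size(); q++) {
        ub.removeCur(mem[q]);
        evicted.push_back(mem[q]);
      }
    }
    for (size_t i = 0; i < U.size(); i++) ub.addCur(U[i]);

    bool keep = true;
    if (monotonic) {
      long long dA = ub.acov - a0, dE = ub.aele - e0, dS = ub.aseg - s0;
      keep = 2 * dA > (long long)(w + 1) * (dE + dS);  // strict DL > 0
    }
    if (keep) {
      for (std::set<uint64_t>::iterator it = confl.begin(); it != confl.end(); ++it) {
        n_evicted += members[*it].size();
        members.erase(*it);
      }
      members[m] = U;
      for (size_t i = 0; i < U.size(); i++) pos_kmer[U[i]] = m;
      n_accepted++;
      trace.push_back(ub.L());
    } else {
      n_rejected_mono++;
      for (size_t i = 0; i < U.size(); i++) ub.removeCur(U[i]);
      for (size_t q = 0; q < evicted.size(); q++) ub.addCur(evicted[q]);
    }
  }

  // prune members that form no link (removing an unlinked element never
  // unlinks another, so one simultaneous pass suffices)
  std::vector<uint64_t> prune;
  for (std::unordered_map<uint64_t, std::vector<int> >::iterator it = members.begin();
       it != members.end(); ++it) {
    bool linked = false;
    for (size_t i = 0; i < it->second.size() && !linked; i++) {
      int p = it->second[i];
      int pl = ub.peekL(p - 1), pr = ub.peekR(p + 1);
      if ((pl >= 0 && p - pl <= w) || (pr >= 0 && pr - p <= w)) linked = true;
    }
    if (!linked) prune.push_back(it->first);
  }
  for (size_t i = 0; i < prune.size(); i++) {
    std::vector<int>& mem = members[prune[i]];
    for (size_t q = 0; q < mem.size(); q++) ub.removeCur(mem[q]);
    members.erase(prune[i]);
  }

  CharacterVector kmers(members.size());
  std::vector<int> elements;
  int ki = 0;
  for (std::unordered_map<uint64_t, std::vector<int> >::iterator it = members.begin();
       it != members.end(); ++it) {
    kmers[ki++] = unpack_kmer(it->first, k);
    for (size_t q = 0; q < it->second.size(); q++)
      elements.push_back(it->second[q]);
  }
  std::sort(elements.begin(), elements.end());

  return List::create(
      _["kmers"] = kmers, _["elements"] = wrap(elements),
      _["acov"] = (double)ub.acov, _["aele"] = (double)ub.aele,
      _["aseg"] = (double)ub.aseg, _["L"] = ub.L(),
      _["L_before"] = L_before, _["trace"] = wrap(trace),
      _["n_candidates"] = (double)cand.size(),
      _["n_considered"] = (double)n_considered,
      _["n_accepted"] = (double)n_accepted,
      _["n_rejected_monotonic"] = (double)n_rejected_mono,
      _["n_evicted"] = (double)n_evicted,
      _["n_pruned"] = (double)prune.size());
}
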