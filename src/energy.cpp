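#include "kmers.h"
using namespace Rcpp;

// Sliding-window context energies. A context is w+1 consecutive k-mers;
// its energy is 2/u if its last k-mer occurs exactly once within the
// context and 1/u otherwise, u being the distinct-k-mer count. Aggregates:
// E0 = sum of energies, deficit D = sum of max(0, 2/(w+1) - E) and surplus
// X = sum of max(0, E - 2/(w+1)). With `detail`, per-context u, last-unique
// flags and energies are also returned (small inputs only).
// [[Rcpp::export]]
List cpp_energy_profile(IntegerVector codes, int w, int k, bool detail) {
  if (w < 2) stop("w must be >= 2");
  KmerScan ks = scan_kmers(codes, k);
  int n = codes.size();
  double base = 2.0 / (w + 1);
  double E0 = 0, D = 0, X = 0;
  long long n_contexts = 0, n_savers = 0, n_spenders = 0;
  long long n_kmers = 0, n_frag_win = 0;
  std::vector<int> det_u;
  std::vector<int> det_last;
  std::vector<double> det_E;

  std::unordered_map<uint64_t, int> cnt;
  int i = 0;
  while (i < n) {
    if (!ks.valid[i]) { i++; continue; }
    int j = i;
    while (j < n && ks.valid[j]) j++;
    int nk = j - i;
    n_kmers += nk;
    if (nk >= w) n_frag_win++;
    if (nk >= w + 1) {
      cnt.clear();
      int u = 0;
      for (int t = i; t < j; t++) {
        int& c = cnt[ks.packed[t]];
        if (c == 0) u++;
        c++;
        if (t - i >= w + 1) {  // drop k-mer leaving the w+1 window
          int& d = cnt[ks.packed[t - w - 1]];
          d--;
          if (d == 0) u--;
        }
        if (t - i >= w) {
          bool last_unique = cnt[ks.packed[t]] == 1;
          double E = last_unique ? 2.0 / u : 1.0 / u;
          E0 += E;
          if (E < base) { D += base - E; n_savers++; }
          else if (E > base) { X += E - base; n_spenders++; }
          n_contexts++;
          if (detail) {
            det_u.push_back(u);
            det_last.push_back(last_unique ? 1 : 0);
            det_E.push_back(E);
          }
        }
      }
    }
    i = j;
  }

  List out = List::create(
      _["E0"] = E0, _["deficit"] = D, _["surplus"] = X,
      _["n_contexts"] = (double)n_contexts, _["n_savers"] = (double)n_savers,
      _["n_spenders"] = (double)n_spenders, _["n_kmers"] = (double)n_kmers,
      _["n_fragments_with_windows"] = (double)n_frag_win);
  if (detail) {
    out["u"] = wrap(det_u);
    out["last_unique"] = wrap(det_last);
    out["energy"] = wrap(det_E);
  }
  return out;
}
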