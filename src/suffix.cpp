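#include "kmers.h"
using namespace Rcpp;

// Suffix array by prefix doubling (O(n log^2 n)), inverse suffix array and
// LCP heights (Kasai). Break characters become a sentinel smaller than any
// base, so occurrence queries never cross fragment boundaries: a k-mer that
// spans a break can never share an LCP >= k with a break-free k-mer.
// [[Rcpp::export]]
List cpp_suffix_array(IntegerVector codes) {
  int n = codes.size();
  if (n == 0) stop("empty sequence");
  std::vector<int> v(n);
  for (int i = 0; i < n; i++) v[i] = codes[i] < 0 ? 0 : codes[i] + 1;

  std::vector<int> sa(n), rnk(n), tmp(n);
  for (int i = 0; i < n; i++) { sa[i] = i; rnk[i] = v[i]; }
  for (int len = 1;; len <<= 1) {
    auto cmp = [&](int a, int b) {
      if (rnk[a] != rnk[b]) return rnk[a] < rnk[b];
      int ra = a + len < n ? rnk[a + len] : -1;
      int rb = b + len < n ? rnk[b + len] : -1;
      return ra < rb;
    };
    std::sort(sa.begin(), sa.end(), cmp);
    tmp[sa[0]] = 0;
    for (int i = 1; i < n; i++)
      tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
    rnk = tmp;
    if (rnk[sa[n - 1]] == n - 1) break;
  }

  std::vector<int> lcp(n, 0);
  int h = 0;
  for (int i = 0; i < n; i++) {
    if (rnk[i] > 0) {
      int j = sa[rnk[i] - 1];
      while (i + h < n && j + h < n && v[i + h] == v[j + h]) h++;
      lcp[rnk[i]] = h;
      if (h) h--;
    } else {
      h = 0;
    }
  }

  return List::create(_["sa"] = wrap(sa), _["isa"] = wrap(rnk),
                      _["lcp"] = wrap(lcp));
}

// All positions sharing the k-mer at position t (0-based), via the inverse
// suffix array and an outward scan while LCP >= k.
// [[Rcpp::export]]
IntegerVector cpp_sa_occurrences(IntegerVector sa, IntegerVector isa,
                                 IntegerVector lcp, int t, int k) {
  int n = sa.size();
  if (t < 0 || t >= n) stop("position out of range");
  int r = isa[t];
  std::vector<int> res;
  res.push_back(sa[r]);
  for (int j = r; j > 0 && lcp[j] >= k; j--) res.push_back(sa[j - 1]);
  for (int j = r + 1; j < n && lcp[j] >= k; j++) res.push_back(sa[j]);
  std::sort(res.begin(), res.end());
  return wrap(res);
}

// Occurrence count of the k-mer starting at each position (0 where no valid
// k-mer starts). Runs of suffixes sharing LCP >= k form one k-mer group.
// [[Rcpp::export]]
IntegerVector cpp_kmer_freq(IntegerVector sa, IntegerVector lcp,
                            LogicalVector valid, int k) {
  int n = sa.size();
  IntegerVector out(n, 0);
  int i = 0;
  while (i < n) {
    int j = i + 1;
    while (j < n && lcp[j] >= k) j++;
    int cnt = 0;
    for (int t = i; t < j; t++)
      if (valid[sa[t]]) cnt++;
    if (cnt > 0)
      for (int t = i; t < j; t++)
        if (valid[sa[t]]) out[sa[t]] = cnt;
    i = j;
  }
  return out;
}
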