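#ifndef POLARMIN_BLOCKS_H
#define POLARMIN_BLOCKS_H

#include <Rcpp.h>
#include <vector>
#include <algorithm>

// Linked blocks: the sequence is divided into h = floor(w/2) wide blocks,
// each holding at most one selected location (guaranteed by polar spacing
// > w/2). Supports nearest-selected queries within w bases (PeekL/PeekR,
// <= 4 block probes) and incremental maintenance of the covered-context
// count Acov, the element count Aele and the segment count Aseg, from which
// the total link energy is L = 2*Acov/(w+1) - Aele - Aseg.
//
// Acov counts, for every element p, the context start positions p-w..p
// (interval union, occurrence-relative: not clipped at fragment ends) so
// that the identity with the pairwise link-energy sum is exact everywhere.
struct LinkedBlocksImpl {
  int n, w, h, nb;
  std::vector<int> C;  // -1 empty, else offset j: location b*h + j selected
  long long acov, aele, aseg;

  LinkedBlocksImpl(int n_, int w_)
      : n(n_), w(w_), h(std::max(1, w_ / 2)), nb(n_ > 0 ? (n_ + std::max(1, w_ / 2) - 1) / std::max(1, w_ / 2) : 0),
        C(nb, -1), acov(0), aele(0), aseg(0) {
    if (w_ < 2) Rcpp::stop("w must be >= 2");
    if (n_ < 1) Rcpp::stop("sequence length must be >= 1");
  }

  // nearest selected p with x - w <= p <= x, or -1
  int peekL(int x) const {
    if (x < 0) return -1;
    if (x >= n) x = n - 1;
    int lo = x - w;
    for (int b = x / h; b >= 0 && (b + 1) * h > lo; b--) {
      if (C[b] >= 0) {
        int p = b * h + C[b];
        if (p <= x) return p >= lo ? p : -1;
        // p > x can only happen in the first probed block; keep going
      }
    }
    return -1;
  }

  // nearest selected p with x <= p <= x + w, or -1
  int peekR(int x) const {
    if (x >= n) return -1;
    if (x < 0) x = 0;
    int hi = x + w;
    for (int b = x / h; b < nb && b * h <= hi; b++) {
      if (C[b] >= 0) {
        int p = b * h + C[b];
        if (p >= x) return p <= hi ? p : -1;
      }
    }
    return -1;
  }

  bool occupied(int x) const {
    int b = x / h;
    return C[b] >= 0 && b * h + C[b] == x;
  }

  void set_raw(int x) {
    int b = x / h;
    if (C[b] >= 0) Rcpp::stop("linked block already occupied");
    C[b] = x - b * h;
  }

  void clear_raw(int x) {
    int b = x / h;
    if (C[b] < 0 || b * h + C[b] != x)
      Rcpp::stop("location is not selected");
    C[b] = -1;
  }

  // aggregate deltas for inserting/removing a location whose nearest
  // neighbours (within w) sit dl bases left and dr bases right (-1 = none)
  void apply_delta(long long dl, long long dr, int sign) {
    long long ov_l = dl >= 0 ? (w - dl + 1) : 0;
    long long ov_r = dr >= 0 ? (w - dr + 1) : 0;
    long long ov_lr = (dl >= 0 && dr >= 0 && dl + dr <= w) ? (w - dl - dr + 1) : 0;
    acov += sign * ((w + 1) - ov_l - ov_r + ov_lr);
    aele += sign;
    aseg += sign * (1 - (dl >= 0 ? 1 : 0) - (dr >= 0 ? 1 : 0));
  }

  void check_spacing(int x, int pl, int pr) const {
    if ((pl >= 0 && 2 * (x - pl) <= w) || (pr >= 0 && 2 * (pr - x) <= w))
      Rcpp::stop("polar spacing violated: another selected location lies "
                 "within w/2 bases of %d", x);
  }

  // x is absent from the structure when the deltas are computed, so
  // peekL(x)/peekR(x) see exactly the neighbours within w bases
  void add(int x) {
    if (x < 0 || x >= n) Rcpp::stop("location out of range");
    if (occupied(x)) Rcpp::stop("location already selected");
    int pl = peekL(x), pr = peekR(x);
    check_spacing(x, pl, pr);
    apply_delta(pl >= 0 ? x - pl : -1, pr >= 0 ? pr - x : -1, +1);
    set_raw(x);
  }

  void remove(int x) {
    if (x < 0 || x >= n) Rcpp::stop("location out of range");
    clear_raw(x);
    int pl = peekL(x), pr = peekR(x);
    apply_delta(pl >= 0 ? x - pl : -1, pr >= 0 ? pr - x : -1, -1);
  }

  double L() const { return 2.0 * (double)acov / (w + 1.0) - aele - aseg; }
};

#endif
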