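#include "blocks.h"
using namespace Rcpp;

typedef XPtr<LinkedBlocksImpl> LBPtr;

// [[Rcpp::export]]
SEXP cpp_lb_new(int n, int w) {
  return LBPtr(new LinkedBlocksImpl(n, w), true);
}

// [[Rcpp::export]]
void cpp_lb_add(SEXP ptr, int x) { LBPtr(ptr)->add(x); }

// [[Rcpp::export]]
void cpp_lb_remove(SEXP ptr, int x) { LBPtr(ptr)->remove(x); }

// [[Rcpp::export]]
int cpp_lb_peek_left(SEXP ptr, int x) { return LBPtr(ptr)->peekL(x); }

// [[Rcpp::export]]
int cpp_lb_peek_right(SEXP ptr, int x) { return LBPtr(ptr)->peekR(x); }

// [[Rcpp::export]]
List cpp_lb_stats(SEXP ptr) {
  LBPtr p(ptr);
  return List::create(_["acov"] = (double)p->acov, _["aele"] = (double)p->aele,
                      _["aseg"] = (double)p->aseg, _["L"] = p->L());
}

// [[Rcpp::export]]
IntegerVector cpp_lb_locations(SEXP ptr) {
  LBPtr p(ptr);
  std::vector<int> out;
  for (int b = 0; b < p->nb; b++)
    if (p->C[b] >= 0) out.push_back(b * p->h + p->C[b]);
  return wrap(out);
}
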