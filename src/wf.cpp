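#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Assemble one generation of gametes from parental haplotypes.
//
// geno:   S x H parental haplotype matrix (sites in rows, haplotypes in
//         columns), entries 0/1. Rows [0, n_sorted) are sorted by global
//         position and copied segment-wise; rows [n_sorted, S) are a small
//         unsorted tail of recent mutations, resolved per site.
// gpos:   global (concatenated-genome) position of each site; ties with
//         switch points have measure zero because switches are continuous
// hapA/B: 0-based parental haplotype column for each offspring gamete
// start:  0/1, which parental haplotype the gamete starts on
// sw_off/sw_val: strand-switch points (crossovers plus independent-
//         assortment flips at chromosome starts) flattened over gametes:
//         gamete i's switches are sw_val[sw_off[i] .. sw_off[i+1]-1],
//         sorted by position
// n_extra: zeroed spare rows appended to the result, to be filled with this
//         generation's new mutations without reallocating the matrix
// [[Rcpp::export]]
IntegerMatrix make_gametes_cpp(const IntegerMatrix& geno,
                               const NumericVector& gpos,
                               const IntegerVector& hapA,
                               const IntegerVector& hapB,
                               const IntegerVector& start,
                               const IntegerVector& sw_off,
                               const NumericVector& sw_val,
                               int n_sorted, int n_extra) {
  const int S = geno.nrow();
  const int n = hapA.size();
  IntegerMatrix out(no_init(S + n_extra, n));
  const int* gp = INTEGER(geno);
  int* op = INTEGER(out);
  // only the spare mutation rows need zeroing; the rest is overwritten
  if (n_extra > 0) {
    for (int i = 0; i < n; ++i) {
      int* dst = op + (R_xlen_t) i * (S + n_extra);
      std::fill(dst + S, dst + S + n_extra, 0);
    }
  }
  const double* pp = REAL(gpos);
  const R_xlen_t Sout = S + n_extra;
  for (int i = 0; i < n; ++i) {
    const int* src[2] = { gp + (R_xlen_t) hapA[i] * S,
                          gp + (R_xlen_t) hapB[i] * S };
    int* dst = op + (R_xlen_t) i * Sout;
    const double* swb = REAL(sw_val) + sw_off[i];
    const double* swe = REAL(sw_val) + sw_off[i + 1];
    int cur = start[i];
    int s0 = 0;
    for (const double* sw = swb; sw < swe; ++sw) {
      const int s1 = std::upper_bound(pp, pp + n_sorted, *sw) - pp;
      if (s1 > s0) {
        std::copy(src[cur] + s0, src[cur] + s1, dst + s0);
        s0 = s1;
      }
      cur ^= 1;
    }
    if (s0 < n_sorted) std::copy(src[cur] + s0, src[cur] + n_sorted, dst + s0);
    // unsorted tail: locate each site's segment independently
    for (int s = n_sorted; s < S; ++s) {
      const int cnt = std::upper_bound(swb, swe, gpos[s]) - swb;
      const int par = (start[i] + cnt) & 1;
      dst[s] = src[par][s];
    }
  }
  return out;
}
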