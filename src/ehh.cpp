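#include <Rcpp.h>
#include <map>
#include <vector>
using namespace Rcpp;

// Extend haplotype classes one direction from a core site, returning the EHH
// value at each successive site and the trapezoid integral over physical
// distance (iHH). Classes are defined over the span (core, x]: at distance 0
// every haplotype shares the empty span, so EHH(core) = 1. Haplotypes with a
// missing allele anywhere in the current span are dropped from the
// computation (the denominator shrinks with them). Integration stops at the
// first site where EHH < cutoff (that point is included) or at the end of the
// matrix.
static void ehh_one_side(const IntegerMatrix& geno, const NumericVector& pos,
                         int core, int dir, double cutoff,
                         std::vector<double>& out_pos,
                         std::vector<double>& out_ehh,
                         double& ihh) {
  const int H = geno.nrow(), S = geno.ncol();
  std::vector<int> cls(H, 0);
  std::vector<int> active;
  active.reserve(H);
  for (int h = 0; h < H; ++h) active.push_back(h);
  double prev_ehh = 1.0, prev_d = 0.0;
  ihh = 0.0;
  int j = core;
  while (true) {
    j += dir;
    if (j < 0 || j >= S) break;
    std::vector<int> keep;
    keep.reserve(active.size());
    for (size_t t = 0; t < active.size(); ++t)
      if (geno(active[t], j) != NA_INTEGER) keep.push_back(active[t]);
    active.swap(keep);
    const int n = (int) active.size();
    if (n < 2) break;
    // refine classes by the allele at j, compressing ids
    std::map<std::pair<int, int>, int> remap;
    std::map<int, int> count;
    for (size_t t = 0; t < active.size(); ++t) {
      const int h = active[t];
      std::pair<int, int> key(cls[h], geno(h, j));
      std::map<std::pair<int, int>, int>::iterator it = remap.find(key);
      int id;
      if (it == remap.end()) {
        id = (int) remap.size();
        remap[key] = id;
      } else id = it->second;
      cls[h] = id;
      count[id] += 1;
    }
    double pairs = 0.0;
    for (std::map<int, int>::iterator it = count.begin(); it != count.end(); ++it) {
      const double c = it->second;
      pairs += c * (c - 1.0) / 2.0;
    }
    const double ehh = pairs / (n * (n - 1.0) / 2.0);
    const double d = std::abs(pos[j] - pos[core]);
    ihh += 0.5 * (prev_ehh + ehh) * (d - prev_d);
    out_pos.push_back(pos[j]);
    out_ehh.push_back(ehh);
    prev_ehh = ehh;
    prev_d = d;
    if (ehh < cutoff) break;
  }
}

// Full EHH curve (both sides) and per-side iHH for one core.
// [[Rcpp::export]]
List ehh_curve_cpp(const IntegerMatrix& geno, const NumericVector& pos,
                   int core, double cutoff) {
  std::vector<double> lp, le, rp, re;
  double ihl = 0.0, ihr = 0.0;
  ehh_one_side(geno, pos, core, -1, cutoff, lp, le, ihl);
  ehh_one_side(geno, pos, core, +1, cutoff, rp, re, ihr);
  return List::create(_["pos_left"] = wrap(lp), _["ehh_left"] = wrap(le),
                      _["pos_right"] = wrap(rp), _["ehh_right"] = wrap(re),
                      _["ihh_left"] = ihl, _["ihh_right"] = ihr);
}

// Total iHH (left + right) for every core site; used by the XP-EHH scan.
// [[Rcpp::export]]
NumericVector ihh_all_cpp(const IntegerMatrix& geno, const NumericVector& pos,
                          const IntegerVector& cores, double cutoff) {
  const int m = cores.size();
  NumericVector out(m);
  std::vector<double> dp, de;
  for (int i = 0; i < m; ++i) {
    double ihl = 0.0, ihr = 0.0;
    dp.clear(); de.clear();
    ehh_one_side(geno, pos, cores[i], -1, cutoff, dp, de, ihl);
    dp.clear(); de.clear();
    ehh_one_side(geno, pos, cores[i], +1, cutoff, dp, de, ihr);
    out[i] = ihl + ihr;
  }
  return out;
}
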