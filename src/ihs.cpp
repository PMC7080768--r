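// Integrated EHH core for the iHS scan. EHH is tracked by incremental
// partition refinement over the carrier set; the integral over physical
// distance uses the trapezoid rule and truncates at the first marker
// where EHH falls below the cutoff (that trapezoid is included).
#include <Rcpp.h>
#include <unordered_map>
using namespace Rcpp;

namespace {

// status codes shared with the R wrapper
constexpr int OK = 0, LOW_MAF = 1, EDGE = 2, GAP = 3;

double ihh_one_side(const IntegerMatrix& hap, const NumericVector& pos,
                    const std::vector<int>& carriers, int core, int dir,
                    double cutoff, double max_gap, double max_extend,
                    int& status) {
  const int L = hap.ncol();
  const int n = static_cast<int>(carriers.size());
  const double denom = 0.5 * n * (n - 1);
  std::vector<int> grp(n, 0);
  int ngrp = 1;
  double ehh = 1.0, ihh = 0.0;
  int prev = core;
  for (int j = core + dir; j >= 0 && j < L; j += dir) {
    const double gap = std::abs(pos[j] - pos[prev]);
    if (gap > max_gap) { status = GAP; return ihh; }
    if (std::abs(pos[j] - pos[core]) > max_extend) { status = EDGE; return ihh; }
    // refine the carrier partition by the allele at marker j; group ids
    // are dense, so a flat remap table suffices
    std::vector<int> remap(2 * ngrp, -1);
    std::vector<int> counts;
    counts.reserve(2 * ngrp);
    for (int i = 0; i < n; ++i) {
      const int key = 2 * grp[i] + hap(carriers[i], j);
      if (remap[key] < 0) {
        remap[key] = static_cast<int>(counts.size());
        counts.push_back(0);
      }
      grp[i] = remap[key];
      ++counts[grp[i]];
    }
    ngrp = static_cast<int>(counts.size());
    double num = 0.0;
    for (int c : counts) num += 0.5 * c * (c - 1);
    const double ehh_new = num / denom;
    ihh += 0.5 * (ehh + ehh_new) * gap;
    if (ehh_new < cutoff) { status = OK; return ihh; }
    ehh = ehh_new;
    prev = j;
  }
  status = EDGE;  // ran off the chromosome before reaching the cutoff
  return ihh;
}

double ihh_both(const IntegerMatrix& hap, const NumericVector& pos,
                const std::vector<int>& carriers, int core,
                double cutoff, double max_gap, double max_extend,
                int& status) {
  int s_left = OK, s_right = OK;
  const double left = ihh_one_side(hap, pos, carriers, core, -1, cutoff,
                                   max_gap, max_extend, s_left);
  const double right = ihh_one_side(hap, pos, carriers, core, +1, cutoff,
                                    max_gap, max_extend, s_right);
  status = (s_left != OK) ? s_left : s_right;
  return left + right;
}

}  // namespace

// [[Rcpp::export]]
List ihs_scan_cpp(IntegerMatrix hap, NumericVector pos, IntegerVector anc,
                  double maf_min, double cutoff, double max_gap,
                  double max_extend) {
  const int L = hap.ncol(), n_hap = hap.nrow();
  NumericVector derived_freq(L), ihh_a(L, NA_REAL), ihh_d(L, NA_REAL);
  IntegerVector reason(L);
  for (int s = 0; s < L; ++s) {
    const int anc_allele = anc[s];
    const int der_allele = 1 - anc_allele;
    std::vector<int> car_a, car_d;
    car_a.reserve(n_hap);
    car_d.reserve(n_hap);
    for (int i = 0; i < n_hap; ++i) {
      if (hap(i, s) == der_allele) car_d.push_back(i); else car_a.push_back(i);
    }
    const double fd = static_cast<double>(car_d.size()) / n_hap;
    derived_freq[s] = fd;
    if (std::min(fd, 1.0 - fd) <= maf_min) { reason[s] = LOW_MAF; continue; }
    int st_a = OK, st_d = OK;
    const double ia = ihh_both(hap, pos, car_a, s, cutoff, max_gap,
                               max_extend, st_a);
    const double id = ihh_both(hap, pos, car_d, s, cutoff, max_gap,
                               max_extend, st_d);
    ihh_a[s] = ia;
    ihh_d[s] = id;
    reason[s] = (st_a != OK) ? st_a : st_d;
    if (reason[s] == OK && (ia <= 0.0 || id <= 0.0)) reason[s] = EDGE;
  }
  return List::create(_["derived_freq"] = derived_freq, _["ihh_a"] = ihh_a,
                      _["ihh_d"] = ihh_d, _["reason"] = reason);
}
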