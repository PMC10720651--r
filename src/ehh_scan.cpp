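#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Status codes shared with the R wrappers (see R/haplostats.R):
//   0 ok, 1 gap truncation before EHH cutoff, 2 chromosome edge before
//   cutoff, 3 fewer than 2 carriers of one allele, 4 zero integral.

struct WalkResult {
  double ihh;
  int status;
};

// Walk outward from core column `s` in direction `dir` over the carrier
// rows `car`, refining identity groups site by site.  EHH at extension x is
// sum_g C(m_g,2)/C(nc,2) over groups of haplotypes identical from the core
// to x.  The integral is trapezoidal against physical distance (iHS) or
// site count (nSL).  The trapezoid into the first site where EHH drops
// below `cutoff` is included, then integration stops.
static WalkResult walk_ihh(const IntegerMatrix &hap,
                           const std::vector<int> &car,
                           int s, int dir,
                           const NumericVector &pos,
                           double cutoff, double maxgap, double maxextend,
                           bool site_scale) {
  const int S = hap.ncol();
  const int nc = static_cast<int>(car.size());
  const double denom = 0.5 * nc * (nc - 1.0);

  std::vector<int> grp(nc, 0);
  std::vector<int> key(nc), remap(2 * nc, -1), cnt(nc, 0);
  int ngrp = 1;

  double ehh_prev = 1.0, d_prev = 0.0, ihh = 0.0;
  int j = s;

  for (;;) {
    const int jn = j + dir;
    if (jn < 0 || jn >= S) return {ihh, 2};  // ran off the chromosome

    double dj, gap;
    if (site_scale) {
      dj = std::abs(jn - s);
      gap = 1.0;
    } else {
      dj = std::abs(pos[jn] - pos[s]);
      gap = std::abs(pos[jn] - pos[j]);
    }
    if (!site_scale && gap > maxgap) return {ihh, 1};

    // refine: new key = old group * 2 + allele, then compact
    for (int i = 0; i < nc; ++i)
      key[i] = grp[i] * 2 + hap(car[i], jn);
    int nnew = 0;
    for (int i = 0; i < nc; ++i) {
      int k = key[i];
      if (remap[k] < 0) remap[k] = nnew++;
      grp[i] = remap[k];
    }
    for (int i = 0; i < nc; ++i) remap[key[i]] = -1;  // reset for next round
    ngrp = nnew;

    std::fill(cnt.begin(), cnt.begin() + ngrp, 0);
    for (int i = 0; i < nc; ++i) ++cnt[grp[i]];
    double hom = 0.0;
    for (int g = 0; g < ngrp; ++g) hom += 0.5 * cnt[g] * (cnt[g] - 1.0);
    const double ehh = hom / denom;

    ihh += 0.5 * (ehh_prev + ehh) * (dj - d_prev);
    if (ehh < cutoff) return {ihh, 0};
    if (dj >= maxextend) return {ihh, 0};

    ehh_prev = ehh;
    d_prev = dj;
    j = jn;
  }
}

// Per-SNP integrated haplotype homozygosity for both alleles.
// hap: haplotypes x sites in {0,1}; pos: physical positions (bp).
// site_scale = true gives the nSL variant (unit distance per site, no gap
// rule; pass maxgap = Inf).
// [[Rcpp::export]]
List cpp_scan_ihh(const IntegerMatrix &hap, const NumericVector &pos,
                  double cutoff, double maxgap, double maxextend,
                  bool site_scale) {
  const int S = hap.ncol();
  const int n = hap.nrow();
  NumericVector ihh_a(S, NA_REAL), ihh_d(S, NA_REAL), freq(S);
  IntegerVector status(S, 0);

  std::vector<int> anc, der;
  anc.reserve(n);
  der.reserve(n);

  for (int s = 0; s < S; ++s) {
    anc.clear();
    der.clear();
    for (int i = 0; i < n; ++i)
      (hap(i, s) == 1 ? der : anc).push_back(i);
    freq[s] = static_cast<double>(der.size()) / n;

    if (der.size() < 2 || anc.size() < 2) {
      status[s] = 3;
      continue;
    }

    double ia = 0.0, id = 0.0;
    int st = 0;
    for (int pass = 0; pass < 2 && st == 0; ++pass) {
      const std::vector<int> &car = (pass == 0) ? anc : der;
      for (int dir = -1; dir <= 1 && st == 0; dir += 2) {
        WalkResult w =
            walk_ihh(hap, car, s, dir, pos, cutoff, maxgap, maxextend,
                     site_scale);
        if (w.status != 0) st = w.status;
        else (pass == 0 ? ia : id) += w.ihh;
      }
    }
    if (st == 0 && (ia <= 0.0 || id <= 0.0)) st = 4;
    status[s] = st;
    if (st == 0) {
      ihh_a[s] = ia;
      ihh_d[s] = id;
    }
  }

  return List::create(_["freq"] = freq, _["ihh_a"] = ihh_a,
                      _["ihh_d"] = ihh_d, _["status"] = status);
}
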