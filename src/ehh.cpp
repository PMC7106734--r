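#include <Rcpp.h>
#include <unordered_map>
using namespace Rcpp;

// Area under the EHH curve for one flank of one core site.
// Haplotype classes are refined marker by marker; EHH_x = sum_h nh(nh-1)/(n(n-1)).
// The walk stops at the first marker with EHH below `cutoff` (that marker's
// trapezoid is included) or at the end of the interval; the latter sets `edge`.
static double flank_area(const IntegerMatrix &H, int core, int dir,
                         const NumericVector &pos, double cutoff,
                         double max_extend, bool &edge) {
  const int n = H.nrow(), S = H.ncol();
  std::vector<int> cls(n, 0);
  std::vector<int> cnt;
  double ehh_prev = 1.0, dist_prev = 0.0, area = 0.0;
  bool truncated = false;
  for (int j = core + dir; j >= 0 && j < S; j += dir) {
    if (std::abs(pos[j] - pos[core]) > max_extend) { truncated = true; break; }
    std::unordered_map<long long, int> remap;
    remap.reserve(n * 2);
    cnt.assign(n, 0);
    int nc = 0;
    for (int h = 0; h < n; ++h) {
      long long key = (long long)cls[h] * 64LL + (long long)H(h, j);
      auto it = remap.find(key);
      int id;
      if (it == remap.end()) { id = nc++; remap.emplace(key, id); }
      else id = it->second;
      cls[h] = id;
      cnt[id]++;
    }
    double num = 0.0;
    for (int c = 0; c < nc; ++c) num += (double)cnt[c] * (cnt[c] - 1);
    double e = num / ((double)n * (n - 1));
    double dist = std::abs(pos[j] - pos[core]);
    area += (ehh_prev + e) / 2.0 * (dist - dist_prev);
    ehh_prev = e;
    dist_prev = dist;
    if (e < cutoff || e == 0.0) { truncated = true; break; }
  }
  if (!truncated) edge = true;
  return area;
}

// [[Rcpp::export]]
NumericMatrix cpp_xpehh_ihh(IntegerMatrix hcase, IntegerMatrix hctrl,
                            NumericVector pos, double cutoff,
                            double max_extend) {
  const int S = pos.size();
  if (hcase.ncol() != S || hctrl.ncol() != S)
    stop("haplotype matrices and positions disagree on site count");
  NumericMatrix out(S, 4);  // ihh_case, ihh_control, edge_case, edge_control
  for (int s = 0; s < S; ++s) {
    bool ec = false, eu = false;
    double ic = flank_area(hcase, s, +1, pos, cutoff, max_extend, ec) +
                flank_area(hcase, s, -1, pos, cutoff, max_extend, ec);
    double iu = flank_area(hctrl, s, +1, pos, cutoff, max_extend, eu) +
                flank_area(hctrl, s, -1, pos, cutoff, max_extend, eu);
    out(s, 0) = ic;
    out(s, 1) = iu;
    out(s, 2) = ec ? 1.0 : 0.0;
    out(s, 3) = eu ? 1.0 : 0.0;
  }
  return out;
}
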