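#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sliding-window normalized cross-correlation lag search between adjacent
// A-lines. For each pair (i, i+1) and window center c, the window of line
// i+1 is correlated against lag-shifted windows of line i over integer lags
// in [-maxlag, maxlag]; pshift is the argmax lag (ties: smaller |lag|, then
// the non-negative one), rho the NCC value there. A window is valid only if
// the mask is true across the whole window on both lines. With refine, a
// parabolic fit through the peak and its neighbours yields a sub-sample lag
// (offset confined to [-0.5, 0.5], total clamped to the search range).
// [[Rcpp::export]]
List corr_lag_search_cpp(NumericMatrix x, LogicalMatrix mask, int wlen,
                         int maxlag, int hop, bool refine) {
  const int n = x.nrow(), nl = x.ncol();
  const int half = wlen / 2;
  const int cmin = half + maxlag;            // 0-based feasible center range
  const int cmax = n - 1 - half - maxlag;
  if (wlen > n) stop("correlate_adjacent: window_len exceeds line length");
  if (cmax < cmin) stop("correlate_adjacent: window_len + 2*max_lag exceeds line length");
  if (nl < 2) stop("correlate_adjacent: need at least 2 lines");
  std::vector<int> centers;
  for (int c = cmin; c <= cmax; c += hop) centers.push_back(c);
  const int nw = (int)centers.size(), np = nl - 1, nlag = 2 * maxlag + 1;

  NumericMatrix pshift(nw, np), rho(nw, np);
  LogicalMatrix valid(nw, np);
  std::vector<double> cc(nlag);

  for (int p = 0; p < np; ++p) {
    for (int w = 0; w < nw; ++w) {
      const int c = centers[w];
      pshift(w, p) = NA_REAL; rho(w, p) = NA_REAL; valid(w, p) = FALSE;

      bool ok = true;
      for (int k = c - half; k <= c + half; ++k)
        if (!mask(k, p) || !mask(k, p + 1)) { ok = false; break; }
      if (!ok) continue;

      double sa = 0, saa = 0;
      for (int k = c - half; k <= c + half; ++k) {
        const double v = x(k, p + 1); sa += v; saa += v * v;
      }
      const double ma = sa / wlen, va = saa - wlen * ma * ma;
      if (va <= 0) continue;

      int bestl = 0; double bestv = 0; bool any = false;
      for (int l = -maxlag; l <= maxlag; ++l) {
        double sb = 0, sbb = 0, sab = 0;
        for (int k = c - half; k <= c + half; ++k) {
          const double b = x(k + l, p);
          sb += b; sbb += b * b; sab += x(k, p + 1) * b;
        }
        const double mb = sb / wlen, vb = sbb - wlen * mb * mb;
        double v = NA_REAL;
        if (vb > 0) v = (sab - wlen * ma * mb) / std::sqrt(va * vb);
        cc[l + maxlag] = v;
        if (!std::isfinite(v)) continue;
        bool better = false;
        if (!any || v > bestv) better = true;
        else if (v == bestv) {
          if (std::abs(l) < std::abs(bestl)) better = true;
          else if (std::abs(l) == std::abs(bestl) && l > bestl) better = true;
        }
        if (better) { bestv = v; bestl = l; any = true; }
      }
      if (!any) continue;

      double ps = bestl;
      if (refine && bestl > -maxlag && bestl < maxlag) {
        const double cm = cc[bestl - 1 + maxlag], c0 = cc[bestl + maxlag],
                     cp = cc[bestl + 1 + maxlag];
        const double den = cm - 2 * c0 + cp;
        if (std::isfinite(cm) && std::isfinite(cp) && den < 0) {
          double d = (cm - cp) / (2 * den);
          if (d > 0.5) d = 0.5;
          if (d < -0.5) d = -0.5;
          ps = bestl + d;
        }
      }
      if (ps > maxlag) ps = maxlag;
      if (ps < -maxlag) ps = -maxlag;
      pshift(w, p) = ps; rho(w, p) = bestv; valid(w, p) = TRUE;
    }
  }
  IntegerVector wc(nw);
  for (int w = 0; w < nw; ++w) wc[w] = centers[w] + 1;   // 1-based for R
  return List::create(_["pshift"] = pshift, _["rho"] = rho,
                      _["valid"] = valid, _["window_centers"] = wc);
}
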