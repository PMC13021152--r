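#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Translation- and border-corrected spatial summary functions for a point
// pattern in an axis-aligned rectangular window.
//
//   K(r)  : Ripley's K, translation edge correction
//             K(r) = |W|/(n(n-1)) * sum_{i!=j} 1{d_ij <= r} * w_ij,
//             w_ij = |W| / ((Wx - |dx|)(Wy - |dy|))
//   G(r)  : reduced-sample (border) nearest-neighbour CDF: among points
//             farther than r from the boundary, fraction with nn dist <= r
//   g(r)  : pair correlation, Epanechnikov kernel of half-width bw,
//             translation correction, normalised so CSR expectation is 1
//
// All three share one O(n^2) pair pass. Radii must be sorted increasing.
// Entries that cannot be computed (G with empty denominator, g at r = 0)
// are NA.

// [[Rcpp::export]]
List cpp_spatial_stats(NumericVector px, NumericVector py,
                       NumericVector radii,
                       double xmin, double xmax, double ymin, double ymax,
                       double bw, bool doK, bool doG, bool doPcf) {
  const int n = px.size();
  const int nr = radii.size();
  const double Wx = xmax - xmin, Wy = ymax - ymin;
  const double area = Wx * Wy;

  NumericVector K(nr, NA_REAL), G(nr, NA_REAL), pcf(nr, NA_REAL);
  if (n < 2) return List::create(_["K"] = K, _["G"] = G, _["g"] = pcf);

  std::vector<double> kbin(nr, 0.0), gacc(nr, 0.0);
  std::vector<double> nnd(n, R_PosInf);

  for (int i = 0; i < n; ++i) {
    const double xi = px[i], yi = py[i];
    for (int j = i + 1; j < n; ++j) {
      const double dx = std::fabs(xi - px[j]);
      const double dy = std::fabs(yi - py[j]);
      const double d = std::sqrt(dx * dx + dy * dy);
      if (d < nnd[i]) nnd[i] = d;
      if (d < nnd[j]) nnd[j] = d;
      const double denom = (Wx - dx) * (Wy - dy);
      // pairs spanning the full window extent have zero overlap area and
      // carry no usable translation weight; they cannot occur for points
      // strictly inside the window
      const double w = (denom > 0.0) ? area / denom : 0.0;
      if (doK) {
        // first radius >= d receives this pair; cumulated below
        const int idx = static_cast<int>(
            std::lower_bound(radii.begin(), radii.end(), d) - radii.begin());
        if (idx < nr) kbin[idx] += 2.0 * w;
      }
      if (doPcf && bw > 0.0) {
        const int lo = static_cast<int>(
            std::lower_bound(radii.begin(), radii.end(), d - bw) - radii.begin());
        const int hi = static_cast<int>(
            std::upper_bound(radii.begin(), radii.end(), d + bw) - radii.begin());
        for (int t = lo; t < hi; ++t) {
          const double u = (radii[t] - d) / bw;
          const double kv = 0.75 * (1.0 - u * u) / bw;
          if (kv > 0.0) gacc[t] += 2.0 * w * kv;
        }
      }
    }
  }

  const double pairScale = area / (static_cast<double>(n) * (n - 1.0));
  if (doK) {
    double cum = 0.0;
    for (int t = 0; t < nr; ++t) {
      cum += kbin[t];
      K[t] = pairScale * cum;
    }
  }
  if (doPcf) {
    for (int t = 0; t < nr; ++t) {
      const double r = radii[t];
      pcf[t] = (r > 0.0) ? pairScale * gacc[t] / (2.0 * M_PI * r) : NA_REAL;
    }
  }
  if (doG) {
    std::vector<double> bdist(n);
    for (int i = 0; i < n; ++i) {
      const double bx = std::min(px[i] - xmin, xmax - px[i]);
      const double by = std::min(py[i] - ymin, ymax - py[i]);
      bdist[i] = std::min(bx, by);
    }
    for (int t = 0; t < nr; ++t) {
      const double r = radii[t];
      int denomN = 0, num = 0;
      for (int i = 0; i < n; ++i) {
        if (bdist[i] > r) {
          ++denomN;
          if (nnd[i] <= r) ++num;
        }
      }
      G[t] = (denomN > 0) ? static_cast<double>(num) / denomN : NA_REAL;
    }
  }
  return List::create(_["K"] = K, _["G"] = G, _["g"] = pcf);
}
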