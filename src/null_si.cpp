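#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Null spatial-information distribution for one neuron.
//
// Each shuffle circularly shifts the event trace by shifts[k] frames and
// permutes the order of contiguous blocks (perms column k, 1-based block
// ids over [blockStarts, blockEnds]), then recomputes Skaggs SI against
// the fixed behavior: per-bin mean activity over movement frames, with
// the occupancy weights o and per-bin movement-frame counts cnt
// precomputed in R. Bins with zero activity contribute 0; unvisited bins
// (cnt == 0) are excluded.
//
// [[Rcpp::export(name = ".nullSpatialInformation")]]
NumericVector nullSpatialInformation(NumericVector ev, IntegerVector movIdx,
                                     IntegerVector bin, int nBins,
                                     NumericVector o, IntegerVector cnt,
                                     IntegerVector blockStarts,
                                     IntegerVector blockEnds,
                                     IntegerMatrix perms,
                                     IntegerVector shifts) {
  const int T = ev.size();
  const int nMov = movIdx.size();
  const int nS = shifts.size();
  const int nB = blockStarts.size();
  std::vector<int> permIdx(T);
  std::vector<double> sums(nBins);
  NumericVector out(nS);
  const double log2e = 1.0 / std::log(2.0);
  for (int k = 0; k < nS; ++k) {
    const int s = shifts[k];
    int c = 0;
    for (int b = 0; b < nB; ++b) {
      const int blk = perms(b, k) - 1;
      for (int t = blockStarts[blk] - 1; t < blockEnds[blk]; ++t)
        permIdx[c++] = (t + s) % T;
    }
    std::fill(sums.begin(), sums.end(), 0.0);
    for (int m = 0; m < nMov; ++m)
      sums[bin[m] - 1] += ev[permIdx[movIdx[m] - 1]];
    double abar = 0.0;
    for (int i = 0; i < nBins; ++i)
      if (cnt[i] > 0) abar += o[i] * (sums[i] / cnt[i]);
    double si = 0.0;
    if (abar > 0) {
      for (int i = 0; i < nBins; ++i) {
        if (cnt[i] > 0 && sums[i] > 0) {
          const double a = sums[i] / cnt[i];
          si += o[i] * a * std::log(a / abar) * log2e;
        }
      }
    }
    out[k] = si;
  }
  return out;
}
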