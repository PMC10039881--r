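#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Simplex-projection prediction kernel shared by univariate forecasting and
// cross-mapping. `emb` holds one delay vector per row; `target` holds, for
// every row, the value that row predicts (already tp-displaced by the
// caller; NaN where the displacement runs off the series). `lib` and `pred`
// are 1-based row indices. For each prediction row the k = E+1 nearest
// library rows (Euclidean distance, ties broken by earlier row index, the
// row itself always excluded) predict via weights exp(-d/dmin); rows at
// distance exactly zero take all the weight.
//
// Top-k selection by insertion on squared distances: O(nlib * k) per
// prediction with no per-row allocation.
//
// Returns a vector of predictions aligned with `pred` (NaN when fewer than
// k usable neighbours exist).
// [[Rcpp::export]]
NumericVector edm_predict_cpp(NumericMatrix emb,
                              NumericVector target,
                              IntegerVector lib,
                              IntegerVector pred,
                              int n_neighbors) {
  const int E = emb.ncol();
  const int nrow = emb.nrow();
  const int nlib = lib.size();
  const int npred = pred.size();
  const int k = n_neighbors;
  NumericVector out(npred, NA_REAL);

  // column-major access: emb(i, j) = embp[j * nrow + i]
  const double *embp = REAL(emb);
  const double *tg = REAL(target);
  const int *libp = INTEGER(lib);

  std::vector<double> bd(k);
  std::vector<int> bi(k);

  for (int p = 0; p < npred; ++p) {
    const int pi = pred[p] - 1;
    int filled = 0;
    double worst = R_PosInf;
    for (int l = 0; l < nlib; ++l) {
      const int li = libp[l] - 1;
      if (li == pi) continue;              // leave-one-out: self excluded
      if (ISNAN(tg[li])) continue;
      // accumulate in extended precision (as base R's sum() does) and
      // compare on the distance scale itself: both choices matter for
      // reproducing exact ties, which are broken by time index
      long double s2 = 0.0;
      for (int j = 0; j < E; ++j) {
        const double diff = embp[j * nrow + pi] - embp[j * nrow + li];
        const double sq = diff * diff;   // square in double, accumulate in
        s2 += sq;                        // extended precision, as base R does
      }
      const double s = std::sqrt((double)s2);
      if (filled == k && (s > worst || (s == worst && li > bi[k - 1])))
        continue;
      // insertion into the sorted top-k (distance, then earlier index)
      int pos = (filled < k ? filled : k - 1);
      while (pos > 0 && (bd[pos - 1] > s ||
                         (bd[pos - 1] == s && bi[pos - 1] > li))) {
        if (pos < k) { bd[pos] = bd[pos - 1]; bi[pos] = bi[pos - 1]; }
        --pos;
      }
      if (pos < k) { bd[pos] = s; bi[pos] = li; }
      if (filled < k) ++filled;
      if (filled == k) worst = bd[k - 1];
    }
    if (filled < k) continue;
    const double dmin = bd[0];
    double wsum = 0.0, psum = 0.0;
    if (dmin <= 0.0) {
      // exact-match convention: zero-distance neighbours share all weight
      for (int i = 0; i < k; ++i) {
        if (bd[i] <= 0.0) { psum += tg[bi[i]]; wsum += 1.0; }
      }
    } else {
      for (int i = 0; i < k; ++i) {
        const double w = std::exp(-bd[i] / dmin);
        psum += w * tg[bi[i]];
        wsum += w;
      }
    }
    out[p] = psum / wsum;
  }
  return out;
}
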