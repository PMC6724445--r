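#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Iterated two-pass chamfer sweep (steps 1 and sqrt(2)) from all source
// pixels, repeated until no value changes, then capped at d_max. The fixed
// point equals the shortest 8-connected chamfer-path distance to the
// nearest source pixel, independent of scan order.
// [[Rcpp::export]]
NumericMatrix chamfer_sweep(const IntegerMatrix& mask, double d_max) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double SQ2 = std::sqrt(2.0);
  const double INF = R_PosInf;
  NumericMatrix d(nr, nc);
  bool any_src = false;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      d(i, j) = mask(i, j) != 0 ? 0.0 : INF;
      if (mask(i, j) != 0) any_src = true;
    }
  if (!any_src) stop("no centerline pixels");

  bool changed = true;
  while (changed) {
    changed = false;
    // forward pass: top-left to bottom-right
    for (int i = 0; i < nr; ++i) {
      for (int j = 0; j < nc; ++j) {
        double v = d(i, j);
        if (i > 0) {
          if (d(i - 1, j) + 1.0 < v) v = d(i - 1, j) + 1.0;
          if (j > 0 && d(i - 1, j - 1) + SQ2 < v) v = d(i - 1, j - 1) + SQ2;
          if (j < nc - 1 && d(i - 1, j + 1) + SQ2 < v) v = d(i - 1, j + 1) + SQ2;
        }
        if (j > 0 && d(i, j - 1) + 1.0 < v) v = d(i, j - 1) + 1.0;
        if (v < d(i, j)) { d(i, j) = v; changed = true; }
      }
    }
    // backward pass: bottom-right to top-left
    for (int i = nr - 1; i >= 0; --i) {
      for (int j = nc - 1; j >= 0; --j) {
        double v = d(i, j);
        if (i < nr - 1) {
          if (d(i + 1, j) + 1.0 < v) v = d(i + 1, j) + 1.0;
          if (j > 0 && d(i + 1, j - 1) + SQ2 < v) v = d(i + 1, j - 1) + SQ2;
          if (j < nc - 1 && d(i + 1, j + 1) + SQ2 < v) v = d(i + 1, j + 1) + SQ2;
        }
        if (j < nc - 1 && d(i, j + 1) + 1.0 < v) v = d(i, j + 1) + 1.0;
        if (v < d(i, j)) { d(i, j) = v; changed = true; }
      }
    }
  }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (d(i, j) > d_max) d(i, j) = d_max;
  return d;
}
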