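#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Exact nearest-neighbour squared Euclidean distances.
//
// P and E hold one descriptor per column (dim x n), so the inner loop walks
// contiguous memory. Entries are visited in order of |‖e‖ - ‖p‖|; since
// ‖p - e‖² >= (‖p‖ - ‖e‖)², a side of the norm-sorted list can be abandoned
// as soon as its bound reaches the current best, and the early break on
// s >= best skips provably worse candidates. Neither pruning step can change
// the returned minimum: only candidates that cannot beat it are skipped.
// [[Rcpp::export]]
NumericVector nn_min_sq(NumericMatrix P, NumericMatrix E) {
  const int d = P.nrow();
  const int np = P.ncol(), ne = E.ncol();
  const double *p = P.begin(), *e = E.begin();

  std::vector<double> enorm(ne);
  for (int j = 0; j < ne; ++j) {
    const double *ej = e + (size_t)j * d;
    double s = 0.0;
    for (int k = 0; k < d; ++k) s += ej[k] * ej[k];
    enorm[j] = std::sqrt(s);
  }
  std::vector<int> ord(ne);
  for (int j = 0; j < ne; ++j) ord[j] = j;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return enorm[a] < enorm[b]; });
  std::vector<double> snorm(ne);
  for (int j = 0; j < ne; ++j) snorm[j] = enorm[ord[j]];

  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    const double *pi = p + (size_t)i * d;
    double s = 0.0;
    for (int k = 0; k < d; ++k) s += pi[k] * pi[k];
    const double pn = std::sqrt(s);

    int r = (int)(std::lower_bound(snorm.begin(), snorm.end(), pn) -
                  snorm.begin());
    int l = r - 1;
    double best = R_PosInf;
    while (l >= 0 || r < ne) {
      int j;
      double gap;
      const double gl = (l >= 0) ? pn - snorm[l] : R_PosInf;
      const double gr = (r < ne) ? snorm[r] - pn : R_PosInf;
      if (gl <= gr) { j = l; gap = gl; --l; } else { j = r; gap = gr; ++r; }
      if (gap * gap >= best) {
        if (gl <= gr) l = -1; else r = ne;   // this side is exhausted
        continue;
      }
      const double *ej = e + (size_t)ord[j] * d;
      double dist = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = pi[k] - ej[k];
        dist += diff * diff;
        if (dist >= best) break;
      }
      if (dist < best) best = dist;
    }
    out[i] = best;
  }
  return out;
}
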