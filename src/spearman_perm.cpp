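#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Pearson correlation of two centered double vectors.
static double corr(const std::vector<double>& a,
                   const std::vector<double>& b) {
  const int n = (int) a.size();
  double sab = 0.0, saa = 0.0, sbb = 0.0, ma = 0.0, mb = 0.0;
  for (int i = 0; i < n; ++i) { ma += a[i]; mb += b[i]; }
  ma /= n; mb /= n;
  for (int i = 0; i < n; ++i) {
    const double da = a[i] - ma, db = b[i] - mb;
    sab += da * db; saa += da * da; sbb += db * db;
  }
  if (saa <= 0.0 || sbb <= 0.0) return NA_REAL;
  return sab / std::sqrt(saa * sbb);
}

// Exact two-sided permutation p-value for the correlation of two (tied)
// rank vectors: the proportion of distinct arrangements of ry whose
// |correlation| with rx reaches the observed one. std::next_permutation
// enumerates distinct arrangements of a multiset, each of which stands for
// the same number of underlying permutations, so the proportion is exact
// under ties as well. Intended for n <= 10 (at most 10! arrangements).
// [[Rcpp::export]]
double spearman_perm_pvalue(NumericVector rx, NumericVector ry) {
  const int n = rx.size();
  if (ry.size() != n) stop("rank vectors must have equal length");
  if (n < 3) stop("need at least 3 pairs");
  if (n > 10) stop("exact permutation p limited to n <= 10");
  std::vector<double> a(rx.begin(), rx.end());
  std::vector<double> b(ry.begin(), ry.end());
  const double robs = corr(a, b);
  if (!std::isfinite(robs)) return NA_REAL;
  const double thr = std::fabs(robs) - 1e-12;
  std::sort(b.begin(), b.end());
  long double hits = 0.0L, total = 0.0L;
  do {
    total += 1.0L;
    const double r = corr(a, b);
    if (std::isfinite(r) && std::fabs(r) >= thr) hits += 1.0L;
  } while (std::next_permutation(b.begin(), b.end()));
  return (double) (hits / total);
}
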