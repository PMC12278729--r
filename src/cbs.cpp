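#include <Rcpp.h>
using namespace Rcpp;

// Maximal two-sample t statistic over all arcs of the circularised
// sequence. An arc (i, j) with 0 <= i < j <= n covers elements
// (i+1)..j (1-based); its complement is the rest of the circle. The
// full-sequence arc (0, n) is excluded so both groups are non-empty.
// Zero pooled variance: t = 0 when the group means agree, +/-Inf
// otherwise. Ties are broken by smallest i, then smallest j (the first
// maximum found in the scan order is kept).
// [[Rcpp::export]]
List max_arc_stat_cpp(NumericVector x) {
  const int n = x.size();
  if (n < 2) stop("need at least 2 values");

  std::vector<long double> cs(n + 1, 0.0L), cq(n + 1, 0.0L);
  for (int k = 0; k < n; ++k) {
    cs[k + 1] = cs[k] + x[k];
    cq[k + 1] = cq[k] + (long double)x[k] * x[k];
  }
  const long double q_tot = cq[n];
  const long double var_eps = 1e-12L * std::max((long double)1.0L, q_tot);

  double best_abs = -1.0;
  int best_i = 0, best_j = 1;
  double best_t = 0.0;

  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j <= n; ++j) {
      if (i == 0 && j == n) continue;  // complement would be empty
      const int n1 = j - i, n2 = n - n1;
      const long double s1 = cs[j] - cs[i];
      const long double q1 = cq[j] - cq[i];
      const long double m1 = s1 / n1;
      const long double m2 = (cs[n] - s1) / n2;
      const long double ss =
          (q1 - n1 * m1 * m1) + ((q_tot - q1) - n2 * m2 * m2);
      const long double diff = m1 - m2;
      double t;
      if (n <= 2 || ss <= var_eps) {
        long double scale = std::max((long double)1.0L,
                                     std::max(fabsl(m1), fabsl(m2)));
        if (fabsl(diff) <= 1e-9L * scale) {
          t = 0.0;
        } else {
          t = diff > 0 ? R_PosInf : R_NegInf;
        }
      } else {
        const long double pooled = ss / (n - 2);
        t = (double)(diff / sqrtl(pooled * (1.0L / n1 + 1.0L / n2)));
      }
      const double at = std::abs(t);
      if (at > best_abs) {
        best_abs = at;
        best_i = i;
        best_j = j;
        best_t = t;
      }
    }
  }
  return List::create(_["i"] = best_i, _["j"] = best_j,
                      _["statistic"] = best_t);
}

// Permutation reference distribution of max |t| over arcs. Permutations
// are drawn with R's RNG so set.seed() on the R side pins them.
// [[Rcpp::export]]
int perm_count_geq_cpp(NumericVector x, double observed_abs, int nperm) {
  const int n = x.size();
  int count = 0;
  for (int p = 0; p < nperm; ++p) {
    // independent Fisher-Yates shuffle of the input with R's unif_rand
    NumericVector work = clone(x);
    for (int k = n - 1; k > 0; --k) {
      int idx = (int)(unif_rand() * (k + 1));
      if (idx > k) idx = k;
      std::swap(work[k], work[idx]);
    }
    List r = max_arc_stat_cpp(work);
    double at = std::abs(as<double>(r["statistic"]));
    if (at >= observed_abs) ++count;
  }
  return count;
}
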