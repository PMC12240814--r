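#include <Rcpp.h>
using namespace Rcpp;

// Maximal circular-arc two-sample statistic for a series.
//
// For boundaries 0 <= i < j <= n with arc length k = j - i (1 <= k <= n-1),
// the statistic is |mean(arc) - mean(complement)| / sqrt(s2 * (1/k + 1/(n-k)))
// where s2 is the variance of the whole segment (fixed, hence invariant under
// permutation). Arcs that wrap around the circle define the same partition as
// the complement of a linear arc, so scanning linear arcs is exhaustive.

static double max_arc_stat(const std::vector<double>& S, int n, double s2,
                           int* best_i, int* best_j) {
  double T = S[n];
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j <= n; ++j) {
      int k = j - i;
      if (k == n) continue;
      double arc = S[j] - S[i];
      double d = arc / k - (T - arc) / (n - k);
      double t = std::fabs(d) / std::sqrt(s2 * (1.0 / k + 1.0 / (n - k)));
      if (t > best) { best = t; bi = i; bj = j; }
    }
  }
  if (best_i) *best_i = bi;
  if (best_j) *best_j = bj;
  return best;
}

static double variance_of(const NumericVector& x) {
  int n = x.size();
  double m = 0.0;
  for (int i = 0; i < n; ++i) m += x[i];
  m /= n;
  double v = 0.0;
  for (int i = 0; i < n; ++i) v += (x[i] - m) * (x[i] - m);
  return v / (n - 1);
}

// [[Rcpp::export]]
List cbs_max_stat_cpp(NumericVector x) {
  int n = x.size();
  if (n < 2) return List::create(_["stat"] = 0.0, _["i"] = 0, _["j"] = 0);
  double s2 = variance_of(x);
  if (s2 <= 0.0)
    return List::create(_["stat"] = 0.0, _["i"] = 0, _["j"] = 0);
  std::vector<double> S(n + 1, 0.0);
  for (int i = 0; i < n; ++i) S[i + 1] = S[i] + x[i];
  int bi, bj;
  double stat = max_arc_stat(S, n, s2, &bi, &bj);
  return List::create(_["stat"] = stat, _["i"] = bi, _["j"] = bj);
}

// Permutation distribution of the maximal arc statistic. Shuffles use R's
// RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericVector cbs_perm_stats_cpp(NumericVector x, int nperm) {
  int n = x.size();
  NumericVector out(nperm);
  if (n < 2) return out;
  double s2 = variance_of(x);
  if (s2 <= 0.0) return out;
  std::vector<double> y(x.begin(), x.end());
  std::vector<double> S(n + 1, 0.0);
  RNGScope scope;
  for (int p = 0; p < nperm; ++p) {
    for (int i = n - 1; i > 0; --i) {
      int k = (int)(unif_rand() * (i + 1));
      std::swap(y[i], y[k]);
    }
    for (int i = 0; i < n; ++i) S[i + 1] = S[i] + y[i];
    out[p] = max_arc_stat(S, n, s2, NULL, NULL);
  }
  return out;
}

// One-sided permutation p-value for the two-sample mean difference between
// x[0..n1) and x[n1..n): used to validate retained changepoints against
// their flanking segments.
// [[Rcpp::export]]
double two_sample_perm_pvalue_cpp(NumericVector x, int n1, int nperm) {
  int n = x.size();
  int n2 = n - n1;
  if (n1 < 1 || n2 < 1) return 1.0;
  double s2 = variance_of(x);
  if (s2 <= 0.0) return 1.0;
  double T = 0.0;
  for (int i = 0; i < n; ++i) T += x[i];
  double s1 = 0.0;
  for (int i = 0; i < n1; ++i) s1 += x[i];
  double denom = std::sqrt(s2 * (1.0 / n1 + 1.0 / n2));
  double obs = std::fabs(s1 / n1 - (T - s1) / n2) / denom;
  std::vector<double> y(x.begin(), x.end());
  RNGScope scope;
  int count = 0;
  for (int p = 0; p < nperm; ++p) {
    for (int i = n - 1; i > 0; --i) {
      int k = (int)(unif_rand() * (i + 1));
      std::swap(y[i], y[k]);
    }
    double ps = 0.0;
    for (int i = 0; i < n1; ++i) ps += y[i];
    double stat = std::fabs(ps / n1 - (T - ps) / n2) / denom;
    if (stat >= obs - 1e-12) ++count;
  }
  return (count + 1.0) / (nperm + 1.0);
}
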