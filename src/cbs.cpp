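#include <Rcpp.h>
using namespace Rcpp;

// Max arc t-statistic scan for circular binary segmentation.
//
// For a segment x[0..m-1], consider every arc (i, j] (0 <= i < j <= m,
// excluding the full segment); the arc and its circular complement are
// compared by a two-sample t-like statistic using the segment-wide variance.
// Both the arc and its complement must contain at least min_width bins.
// Returns the arc with the largest |t|.
static void max_t_scan(const double *x, int m, int min_width,
                       int &best_i, int &best_j, double &best_t) {
  std::vector<double> cs(m + 1, 0.0);
  double ss = 0.0;
  for (int k = 0; k < m; ++k) {
    cs[k + 1] = cs[k] + x[k];
    ss += x[k] * x[k];
  }
  double total = cs[m];
  double mean = total / m;
  double var = (ss - m * mean * mean) / std::max(1, m - 1);
  if (var <= 0) var = 1e-12;
  best_i = -1; best_j = -1; best_t = 0.0;
  for (int i = 0; i <= m - min_width; ++i) {
    for (int j = i + min_width; j <= m; ++j) {
      int k = j - i;           // arc size
      int r = m - k;           // complement size
      if (r < min_width) continue;
      double sa = cs[j] - cs[i];
      double diff = sa / k - (total - sa) / r;
      double t = std::fabs(diff) / std::sqrt(var * (1.0 / k + 1.0 / r));
      if (t > best_t) { best_t = t; best_i = i; best_j = j; }
    }
  }
}

// [[Rcpp::export(name = ".cbs_max_t")]]
List cbs_max_t(NumericVector x, int min_width) {
  int m = x.size();
  int i, j; double t;
  max_t_scan(REAL(x), m, min_width, i, j, t);
  return List::create(_["i"] = i, _["j"] = j, _["t"] = t);
}

// Permutation p-value for the observed max |t|; shuffles use R's RNG so the
// result is reproducible under set.seed().
// [[Rcpp::export(name = ".cbs_perm_pvalue")]]
double cbs_perm_pvalue(NumericVector x, double observed_t, int nperm,
                       int min_width) {
  int m = x.size();
  std::vector<double> y(REAL(x), REAL(x) + m);
  int exceed = 0;
  for (int p = 0; p < nperm; ++p) {
    // Fisher-Yates shuffle driven by R's RNG
    for (int k = m - 1; k > 0; --k) {
      int idx = (int)(unif_rand() * (k + 1));
      if (idx > k) idx = k;
      std::swap(y[k], y[idx]);
    }
    int i, j; double t;
    max_t_scan(y.data(), m, min_width, i, j, t);
    if (t >= observed_t) ++exceed;
  }
  return (exceed + 1.0) / (nperm + 1.0);
}
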