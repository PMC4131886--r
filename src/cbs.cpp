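#include <Rcpp.h>
using namespace Rcpp;

// Circular max-T scan. Arcs are (i, j] in 0-based split coordinates:
// the arc is x[i+1..j] (1-based values), its complement wraps around.
// T is the two-sample t-like statistic with pooled within-group variance.
// Both groups must contain at least min_width values.
static void max_t_scan(const double *x, int n, int min_width,
                       int *bi, int *bj, double *bT) {
  std::vector<double> cs(n + 1, 0.0), css(n + 1, 0.0);
  for (int k = 0; k < n; ++k) {
    cs[k + 1] = cs[k] + x[k];
    css[k + 1] = css[k] + x[k] * x[k];
  }
  double total = cs[n], totss = css[n];
  double bestT = 0.0;
  int besti = 0, bestj = n;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j <= n; ++j) {
      int n1 = j - i, n2 = n - n1;
      if (n1 < min_width || n2 < min_width) continue;
      double s1 = cs[j] - cs[i];
      double ss1 = css[j] - css[i];
      double s2 = total - s1, ss2 = totss - ss1;
      double m1 = s1 / n1, m2 = s2 / n2;
      double sse = (ss1 - n1 * m1 * m1) + (ss2 - n2 * m2 * m2);
      if (sse < 0) sse = 0;
      double s2p = (n > 2) ? sse / (n - 2) : 0.0;
      double T;
      if (s2p <= 0) {
        T = (m1 == m2) ? 0.0 : R_PosInf;
      } else {
        T = std::fabs(m1 - m2) / std::sqrt(s2p * (1.0 / n1 + 1.0 / n2));
      }
      if (T > bestT) {
        bestT = T;
        besti = i;
        bestj = j;
      }
    }
  }
  *bi = besti;
  *bj = bestj;
  *bT = bestT;
}

// [[Rcpp::export]]
List cpp_max_t(NumericVector x, int min_width = 2) {
  int n = x.size();
  if (n < 4) stop("need at least 4 values");
  int i, j;
  double T;
  max_t_scan(REAL(x), n, min_width, &i, &j, &T);
  return List::create(_["i"] = i, _["j"] = j, _["T"] = T);
}

// Fisher-Yates shuffle using R's RNG so set.seed() governs.
static void shuffle(std::vector<double> &v) {
  int n = v.size();
  for (int k = n - 1; k > 0; --k) {
    int idx = (int)(unif_rand() * (k + 1));
    if (idx > k) idx = k;
    std::swap(v[k], v[idx]);
  }
}

// Recursive circular binary segmentation with permutation testing.
// Returns sorted 0-based breakpoints (split after value k, 1-based).
// p = (b+1)/(n_perm+1); a split is accepted when p <= alpha.  With
// early_stop the permutation loop halts once the exceedance count already
// forces p > alpha (the decision is unchanged; only RNG consumption
// differs from the full loop).
// [[Rcpp::export]]
IntegerVector cpp_cbs_segment(NumericVector x, double alpha = 0.01,
                              int n_perm = 1000, int min_width = 2,
                              bool early_stop = true) {
  int n = x.size();
  std::vector<int> breaks;
  if (n < 4) return IntegerVector(0);
  RNGScope scope;
  // b_max: largest exceedance count still giving p <= alpha
  int b_max = (int)std::floor(alpha * (n_perm + 1)) - 1;
  std::vector<std::pair<int, int> > stack;  // [lo, hi] 1-based inclusive
  stack.push_back(std::make_pair(1, n));
  while (!stack.empty()) {
    int lo = stack.back().first, hi = stack.back().second;
    stack.pop_back();
    int m = hi - lo + 1;
    if (m < 4 || m < 2 * min_width) continue;
    std::vector<double> seg(x.begin() + (lo - 1), x.begin() + hi);
    int i, j;
    double T;
    max_t_scan(seg.data(), m, min_width, &i, &j, &T);
    if (!(T > 0)) continue;
    int b = 0;
    std::vector<double> perm = seg;
    for (int r = 0; r < n_perm; ++r) {
      shuffle(perm);
      int pi, pj;
      double pT;
      max_t_scan(perm.data(), m, min_width, &pi, &pj, &pT);
      if (pT >= T) ++b;
      if (early_stop && b > b_max) break;
    }
    double p = (b + 1.0) / (n_perm + 1.0);
    if (p > alpha) continue;
    // accepted: record interior splits, recurse on pieces
    int g1 = lo - 1 + i;  // global split after g1 (may equal lo-1: no split)
    int g2 = lo - 1 + j;  // global split after g2 (may equal hi: no split)
    if (i > 0) breaks.push_back(g1);
    if (j < m) breaks.push_back(g2);
    if (i > 0 && g1 - lo + 1 >= 4) stack.push_back(std::make_pair(lo, g1));
    if (g2 - g1 >= 4) stack.push_back(std::make_pair(g1 + 1, g2));
    if (j < m && hi - g2 >= 4) stack.push_back(std::make_pair(g2 + 1, hi));
  }
  std::sort(breaks.begin(), breaks.end());
  breaks.erase(std::unique(breaks.begin(), breaks.end()), breaks.end());
  return wrap(breaks);
}
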