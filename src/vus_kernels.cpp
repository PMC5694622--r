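#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Tie-weighted trivariate concordance sum over all index triples (i, j, l):
//   num = sum_i sum_j sum_l w(t_i, t_j, t_l) d1_i d2_j d3_l,
// with w = 1 for a < b < c, 1/2 for a = b < c or a < b = c, 1/6 for
// a = b = c, 0 otherwise, normalised by the product of column sums.
// One pass over subjects sorted by t, accumulating class-1 mass strictly
// below and class-3 mass strictly above each tie block; `skip` (-1 for
// none) drops one subject for the leave-one-out jackknife.
static double vus_pass(const std::vector<int>& ord, const NumericVector& t,
                       const NumericMatrix& d, int skip) {
  const int n = ord.size();
  double tot1 = 0, tot2 = 0, tot3 = 0;
  for (int s = 0; s < n; ++s) {
    int i = ord[s];
    if (i == skip) continue;
    tot1 += d(i, 0); tot2 += d(i, 1); tot3 += d(i, 2);
  }
  const double den = tot1 * tot2 * tot3;
  if (!(den > 0)) return NA_REAL;

  double below1 = 0, below3 = 0, num = 0;
  int s = 0;
  while (s < n) {
    int e = s;
    const double tv = t[ord[s]];
    while (e < n && t[ord[e]] == tv) ++e;
    double eq1 = 0, eq3 = 0, eq2num = 0;  // block sums
    for (int u = s; u < e; ++u) {
      int i = ord[u];
      if (i == skip) continue;
      eq1 += d(i, 0); eq3 += d(i, 2); eq2num += d(i, 1);
    }
    const double above3 = tot3 - below3 - eq3;
    if (eq2num != 0)
      num += eq2num * (below1 * above3 + 0.5 * eq1 * above3 +
                       0.5 * below1 * eq3 + eq1 * eq3 / 6.0);
    below1 += eq1; below3 += eq3;
    s = e;
  }
  return num / den;
}

static std::vector<int> sort_order(const NumericVector& t) {
  std::vector<int> ord(t.size());
  for (int i = 0; i < (int)ord.size(); ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&t](int a, int b) { return t[a] < t[b]; });
  return ord;
}

// [[Rcpp::export]]
double cpp_vus(NumericVector t, NumericMatrix d) {
  if (t.size() != d.nrow()) stop("length(t) must equal nrow(d)");
  std::vector<int> ord = sort_order(t);
  return vus_pass(ord, t, d, -1);
}

// Leave-one-out VUS values for the jackknife; element i is the estimate
// with subject i removed (NA when a column sum becomes non-positive).
// [[Rcpp::export]]
NumericVector cpp_vus_loo(NumericVector t, NumericMatrix d) {
  if (t.size() != d.nrow()) stop("length(t) must equal nrow(d)");
  const int n = t.size();
  std::vector<int> ord = sort_order(t);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = vus_pass(ord, t, d, i);
  return out;
}
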