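// O(n^2) kernels for the implicit circular design operator.
// Pair vectors use the same linearization as R's dist objects:
// index(i,j) = n*(i-1) - i*(i-1)/2 + (j-i) for 1 <= i < j <= n,
// here translated to 0-based arithmetic.

#include <Rcpp.h>
using namespace Rcpp;

static inline int pidx(int i, int j, int n) {
  // 0-based i < j < n
  return n * i - i * (i + 1) / 2 + (j - i) - 1;
}

// [[Rcpp::export(name = ".apply_A_cpp")]]
NumericVector apply_A_cpp(NumericVector x, int n) {
  int m = n * (n - 1) / 2;
  NumericVector y(m);
  if (n == 2) { y[0] = x[0]; return y; }
  // column sums of the symmetric expansion of x
  std::vector<double> cs(n, 0.0);
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) {
      double v = x[pidx(i, j, n)];
      cs[i] += v; cs[j] += v;
    }
  for (int i = 0; i + 1 < n; ++i)        // adjacent pairs
    y[pidx(i, i + 1, n)] = cs[i + 1];
  for (int i = 0; i + 2 < n; ++i)
    y[pidx(i, i + 2, n)] = y[pidx(i, i + 1, n)] + y[pidx(i + 1, i + 2, n)]
      - 2.0 * x[pidx(i + 1, i + 2, n)];
  for (int o = 3; o <= n - 1; ++o)
    for (int i = 0; i + o < n; ++i) {
      int j = i + o;
      y[pidx(i, j, n)] = y[pidx(i, j - 1, n)] + y[pidx(i + 1, j, n)]
        - y[pidx(i + 1, j - 1, n)] - 2.0 * x[pidx(i + 1, j, n)];
    }
  return y;
}

// [[Rcpp::export(name = ".apply_At_cpp")]]
NumericVector apply_At_cpp(NumericVector x, int n) {
  int m = n * (n - 1) / 2;
  NumericVector y(m);
  if (n == 2) { y[0] = x[0]; return y; }
  std::vector<double> cs(n, 0.0);
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) {
      double v = x[pidx(i, j, n)];
      cs[i] += v; cs[j] += v;
    }
  for (int i = 0; i + 1 < n; ++i)
    y[pidx(i, i + 1, n)] = cs[i];
  for (int i = 0; i + 2 < n; ++i)
    y[pidx(i, i + 2, n)] = y[pidx(i, i + 1, n)] + y[pidx(i + 1, i + 2, n)]
      - 2.0 * x[pidx(i, i + 1, n)];
  for (int o = 3; o <= n - 1; ++o)
    for (int i = 0; i + o < n; ++i) {
      int j = i + o;
      y[pidx(i, j, n)] = y[pidx(i, j - 1, n)] + y[pidx(i + 1, j, n)]
        - y[pidx(i + 1, j - 1, n)] - 2.0 * x[pidx(i, j - 1, n)];
    }
  return y;
}

// [[Rcpp::export(name = ".apply_Ainv_cpp")]]
NumericVector apply_Ainv_cpp(NumericVector x, int n) {
  int m = n * (n - 1) / 2;
  NumericVector y(m);
  if (n == 2) { y[0] = x[0]; return y; }
  // cyclic Crofton formula; index -1 wraps to n-1, entries (a,a) read 0
  for (int k = 0; k < n - 1; ++k)
    for (int l = k + 1; l < n; ++l) {
      int km = (k == 0) ? n - 1 : k - 1;
      int lm = l - 1;
      double a = (km == lm) ? 0.0 :
        x[pidx(std::min(km, lm), std::max(km, lm), n)];
      double b = x[pidx(k, l, n)];
      double c = (k == lm) ? 0.0 :
        x[pidx(std::min(k, lm), std::max(k, lm), n)];
      double d = (km == l) ? 0.0 :
        x[pidx(std::min(km, l), std::max(km, l), n)];
      y[pidx(k, l, n)] = 0.5 * (a + b - c - d);
    }
  return y;
}
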