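#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Row-wise softmax of a dense matrix, written column-major to match R's
// storage. Three sequential passes (row max, exponentiate + row sum,
// normalize) keep the access pattern cache-friendly; this sits on the hot
// path of every attention evaluation.

// [[Rcpp::export]]
NumericMatrix softmax_rows_cpp(NumericMatrix S) {
  const int n = S.nrow(), m = S.ncol();
  NumericMatrix A(no_init(n, m));
  std::vector<double> mx(n, R_NegInf), rs(n, 0.0);
  const double *s = REAL(S);
  double *a = REAL(A);
  for (int j = 0; j < m; ++j) {
    const double *col = s + (size_t)j * n;
    for (int i = 0; i < n; ++i) mx[i] = std::max(mx[i], col[i]);
  }
  for (int j = 0; j < m; ++j) {
    const double *col = s + (size_t)j * n;
    double *out = a + (size_t)j * n;
    for (int i = 0; i < n; ++i) {
      double e = std::exp(col[i] - mx[i]);
      out[i] = e;
      rs[i] += e;
    }
  }
  for (int i = 0; i < n; ++i) rs[i] = 1.0 / rs[i];
  for (int j = 0; j < m; ++j) {
    double *out = a + (size_t)j * n;
    for (int i = 0; i < n; ++i) out[i] *= rs[i];
  }
  return A;
}

// Backward pass of row softmax: dS = A * (dA - rowSums(A * dA)).

// [[Rcpp::export]]
NumericMatrix softmax_rows_bwd_cpp(NumericMatrix A, NumericMatrix dA) {
  const int n = A.nrow(), m = A.ncol();
  NumericMatrix dS(no_init(n, m));
  std::vector<double> dot(n, 0.0);
  const double *a = REAL(A), *da = REAL(dA);
  double *ds = REAL(dS);
  for (int j = 0; j < m; ++j) {
    const double *ca = a + (size_t)j * n, *cda = da + (size_t)j * n;
    for (int i = 0; i < n; ++i) dot[i] += ca[i] * cda[i];
  }
  for (int j = 0; j < m; ++j) {
    const double *ca = a + (size_t)j * n, *cda = da + (size_t)j * n;
    double *cds = ds + (size_t)j * n;
    for (int i = 0; i < n; ++i) cds[i] = ca[i] * (cda[i] - dot[i]);
  }
  return dS;
}
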