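#include <Rcpp.h>
using namespace Rcpp;

// Coordinate-descent solver for the box-constrained l1-penalised
// least-squares problem at the heart of the Potential SVM on relational
// data:
//
//   min_{a, b}  0.5 * || X a + b 1 - y ||^2 + eps * ||a||_1
//   subject to  -C <= a_j <= C
//
// X is the (column-standardised) relational matrix, one column per
// reference sample; b is an unpenalised offset. Cyclic coordinate descent
// with soft-thresholding and clipping; converges for this convex objective.

// [[Rcpp::export]]
List psvm_cd(NumericMatrix X, NumericVector y, double eps, double C,
             int max_sweeps = 2000, double tol = 1e-12,
             Nullable<NumericVector> a_init = R_NilValue,
             double b_init = 0.0) {
  const int n = X.nrow(), m = X.ncol();
  NumericVector a(m);
  double b = 0.0;

  std::vector<double> r(n);      // residual y - X a - b
  std::vector<double> xss(m);    // column squared norms
  for (int i = 0; i < n; ++i) r[i] = y[i];
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xss[j] = s;
  }

  if (a_init.isNotNull()) {      // warm start
    NumericVector a0(a_init);
    if (a0.size() == m) {
      for (int j = 0; j < m; ++j) {
        a[j] = a0[j];
        if (a[j] != 0.0)
          for (int i = 0; i < n; ++i) r[i] -= X(i, j) * a[j];
      }
      b = b_init;
      for (int i = 0; i < n; ++i) r[i] -= b;
    }
  }

  // initial offset
  {
    double mb = 0.0;
    for (int i = 0; i < n; ++i) mb += r[i];
    mb /= n;
    b += mb;
    for (int i = 0; i < n; ++i) r[i] -= mb;
  }

  int sweep = 0;
  for (; sweep < max_sweeps; ++sweep) {
    double max_delta = 0.0;
    for (int j = 0; j < m; ++j) {
      if (xss[j] <= 0.0) continue;   // constant column: stays at 0
      double g = 0.0;
      for (int i = 0; i < n; ++i) g += X(i, j) * r[i];
      double z = g + xss[j] * a[j];  // unregularised univariate optimum * xss
      double aj;
      if (z > eps)       aj = (z - eps) / xss[j];
      else if (z < -eps) aj = (z + eps) / xss[j];
      else               aj = 0.0;
      if (aj >  C) aj =  C;
      if (aj < -C) aj = -C;
      double d = aj - a[j];
      if (d != 0.0) {
        for (int i = 0; i < n; ++i) r[i] -= X(i, j) * d;
        a[j] = aj;
        double ad = std::fabs(d);
        if (ad > max_delta) max_delta = ad;
      }
    }
    double mb = 0.0;
    for (int i = 0; i < n; ++i) mb += r[i];
    mb /= n;
    if (std::fabs(mb) > 0.0) {
      b += mb;
      for (int i = 0; i < n; ++i) r[i] -= mb;
      if (std::fabs(mb) > max_delta) max_delta = std::fabs(mb);
    }
    if (max_delta < tol) { ++sweep; break; }
  }

  double obj = 0.0, l1 = 0.0;
  for (int i = 0; i < n; ++i) obj += r[i] * r[i];
  obj *= 0.5;
  for (int j = 0; j < m; ++j) l1 += std::fabs(a[j]);
  obj += eps * l1;

  return List::create(_["alpha"] = a, _["b"] = b, _["objective"] = obj,
                      _["sweeps"] = sweep);
}
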