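#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

//' Dense grid-search reference for the sigmoid least-squares fit
//'
//' Evaluates the sum of squared residuals of the canonical sigmoid model
//' at every point of a 4D lattice of parameter values and returns the best
//' lattice point. This is a brute-force reference used to certify that the
//' Levenberg-Marquardt fit reaches at least the best SSE on the lattice;
//' it is written in C++ because a typical lattice has ~10^8 points.
//'
//' The per-point probability is 1 / (1 + exp(-(g0 + g1 r + g2 c + g3 s))).
//' The exponential factorizes over the four axes, so all exp() calls are
//' precomputed per axis and the inner loop is multiply-add only.
//'
//' @param y Observed goal proportions.
//' @param r,cv,s RROC, curvature and shot-angle feature vectors.
//' @param g0,g1,g2,g3 Lattice values for the four parameters.
//' @return List with `sse` (best lattice SSE) and `par` (the best lattice
//'   point as gamma0..gamma3).
//' @export
// [[Rcpp::export]]
List grid_search_sse(NumericVector y, NumericVector r, NumericVector cv,
                     NumericVector s, NumericVector g0, NumericVector g1,
                     NumericVector g2, NumericVector g3) {
  const int n = y.size();
  if (r.size() != n || cv.size() != n || s.size() != n)
    stop("feature vectors must align with y");
  const int n0 = g0.size(), n1 = g1.size(), n2 = g2.size(), n3 = g3.size();

  std::vector<double> a0(n0);
  for (int j = 0; j < n0; ++j) a0[j] = std::exp(-g0[j]);
  // E[k][j*n + i] = exp(-g_k[j] * x_k[i])
  std::vector<double> E1((size_t)n1 * n), E2((size_t)n2 * n),
      E3((size_t)n3 * n);
  for (int j = 0; j < n1; ++j)
    for (int i = 0; i < n; ++i) E1[(size_t)j * n + i] = std::exp(-g1[j] * r[i]);
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n; ++i) E2[(size_t)j * n + i] = std::exp(-g2[j] * cv[i]);
  for (int j = 0; j < n3; ++j)
    for (int i = 0; i < n; ++i) E3[(size_t)j * n + i] = std::exp(-g3[j] * s[i]);

  double best = R_PosInf;
  int b0 = 0, b1 = 0, b2 = 0, b3 = 0;
  std::vector<double> q(n), t(n);
  for (int j3 = 0; j3 < n3; ++j3) {
    Rcpp::checkUserInterrupt();
    const double *e3 = &E3[(size_t)j3 * n];
    for (int j2 = 0; j2 < n2; ++j2) {
      const double *e2 = &E2[(size_t)j2 * n];
      for (int i = 0; i < n; ++i) q[i] = e2[i] * e3[i];
      for (int j1 = 0; j1 < n1; ++j1) {
        const double *e1 = &E1[(size_t)j1 * n];
        for (int i = 0; i < n; ++i) t[i] = e1[i] * q[i];
        for (int j0 = 0; j0 < n0; ++j0) {
          const double a = a0[j0];
          double sse = 0.0;
          for (int i = 0; i < n; ++i) {
            const double pr = 1.0 / (1.0 + a * t[i]);
            const double d = y[i] - pr;
            sse += d * d;
            if (sse >= best) break;  // cannot improve; abandon this point
          }
          if (sse < best) {
            best = sse;
            b0 = j0; b1 = j1; b2 = j2; b3 = j3;
          }
        }
      }
    }
  }
  return List::create(
      _["sse"] = best,
      _["par"] = NumericVector::create(g0[b0], g1[b1], g2[b2], g3[b3]));
}
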