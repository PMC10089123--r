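#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter with zero initial conditions,
// applied independently to each column of X (samples on rows).
// [[Rcpp::export]]
NumericMatrix iir_filter_mat(NumericVector b, NumericVector a,
                             NumericMatrix X) {
  const int n = X.nrow(), m = X.ncol();
  const int nb = b.size(), na = a.size();
  const int nz = std::max(na, nb) - 1;
  NumericMatrix Y(n, m);
  std::vector<double> bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a[0];
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a[0];
  std::vector<double> z(std::max(nz, 1), 0.0);
  const double *bp = bb.data(), *ap = aa.data();
  double *zp = z.data();
  for (int j = 0; j < m; ++j) {
    const double *x = &X[(R_xlen_t)j * n];
    double *y = &Y[(R_xlen_t)j * n];
    std::fill(z.begin(), z.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      const double xi = x[i];
      const double yi = bp[0] * xi + zp[0];
      for (int k = 0; k + 1 < nz; ++k)
        zp[k] = bp[k + 1] * xi + zp[k + 1] - ap[k + 1] * yi;
      if (nz > 0) zp[nz - 1] = bp[nz] * xi - ap[nz] * yi;
      y[i] = yi;
    }
  }
  return Y;
}
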