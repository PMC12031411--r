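#include <Rcpp.h>
using namespace Rcpp;

// One periodized analysis step of the Mallat algorithm.
// x must have even length; lo/hi are the analysis filter pair (length L).
// Output phase is group-delay compensated:
//   y[k] = sum_m f[m] * x[(2k + L/2 - m) mod n],  k = 0..n/2-1
// [[Rcpp::export(name = ".dwt_step_per")]]
List dwt_step_per(NumericVector x, NumericVector lo, NumericVector hi) {
  const int n = x.size();
  const int L = lo.size();
  const int half = n / 2;
  NumericVector a(half), d(half);
  for (int k = 0; k < half; ++k) {
    double sa = 0.0, sd = 0.0;
    int s = (2 * k + L / 2) % n;  // sample index for m = 0
    for (int m = 0; m < L; ++m) {
      const double xv = x[s];
      sa += lo[m] * xv;
      sd += hi[m] * xv;
      if (--s < 0) s += n;
    }
    a[k] = sa;
    d[k] = sd;
  }
  return List::create(Named("a") = a, Named("d") = d);
}
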