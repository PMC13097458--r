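#include <Rcpp.h>
using namespace Rcpp;

// Exact minimal Euclidean distance from each row of `ref` to any row of
// `comp`, both n x 3 CIELAB matrices. Plain exhaustive scan with an
// early-exit on squared distance; exactness matters more than asymptotics
// here and the scan is cache-friendly at the sizes this package meets.
// [[Rcpp::export]]
NumericVector cpp_min_delta_e(NumericMatrix ref, NumericMatrix comp) {
  const int nr = ref.nrow(), nc = comp.nrow();
  if (ref.ncol() != 3 || comp.ncol() != 3)
    stop("expected 3-column CIELAB matrices");
  if (nc == 0) stop("comparison set is empty");
  NumericVector out(nr);
  std::vector<double> cl(nc), ca(nc), cb(nc);
  for (int j = 0; j < nc; ++j) {
    cl[j] = comp(j, 0); ca[j] = comp(j, 1); cb[j] = comp(j, 2);
  }
  for (int i = 0; i < nr; ++i) {
    const double l = ref(i, 0), a = ref(i, 1), b = ref(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < nc; ++j) {
      const double dl = l - cl[j];
      double d = dl * dl;
      if (d >= best) continue;
      const double da = a - ca[j], db = b - cb[j];
      d += da * da + db * db;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
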