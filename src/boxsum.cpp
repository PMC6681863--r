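#include <Rcpp.h>
using namespace Rcpp;

// Local sum over a (2*ry+1) x (2*rx+1) window with replicate-padded
// borders. O(N) via a summed-area table on the padded matrix.
// [[Rcpp::export(name = ".box_sum_cpp")]]
NumericMatrix box_sum_cpp(NumericMatrix m, int ry, int rx) {
  const int nr = m.nrow(), nc = m.ncol();
  const int pr = nr + 2 * ry, pc = nc + 2 * rx;
  std::vector<double> sat((pr + 1) * (pc + 1), 0.0);
  const int stride = pr + 1;
  for (int j = 0; j < pc; ++j) {
    const int js = std::min(std::max(j - rx, 0), nc - 1);
    for (int i = 0; i < pr; ++i) {
      const int is = std::min(std::max(i - ry, 0), nr - 1);
      const double v = m(is, js);
      sat[(j + 1) * stride + (i + 1)] =
        v + sat[j * stride + (i + 1)] + sat[(j + 1) * stride + i] -
        sat[j * stride + i];
    }
  }
  NumericMatrix out(nr, nc);
  const int h = 2 * ry + 1, w = 2 * rx + 1;
  for (int j = 0; j < nc; ++j) {
    const int j0 = j, j1 = j + w;
    for (int i = 0; i < nr; ++i) {
      const int i0 = i, i1 = i + h;
      out(i, j) = sat[j1 * stride + i1] - sat[j0 * stride + i1] -
                  sat[j1 * stride + i0] + sat[j0 * stride + i0];
    }
  }
  return out;
}
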