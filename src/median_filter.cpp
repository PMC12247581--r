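#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// 3x3x3 median filter with replicated (clamped) borders.
// [[Rcpp::export(name = ".median_filter3_cpp")]]
NumericVector median_filter3_cpp(NumericVector x, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(no_init(x.size()));
  out.attr("dim") = dims;
  std::vector<double> buf(27);
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        int m = 0;
        for (int dk = -1; dk <= 1; ++dk) {
          int kk = std::min(std::max(k + dk, 0), nz - 1);
          for (int dj = -1; dj <= 1; ++dj) {
            int jj = std::min(std::max(j + dj, 0), ny - 1);
            for (int di = -1; di <= 1; ++di) {
              int ii = std::min(std::max(i + di, 0), nx - 1);
              buf[m++] = x[ii + nx * (jj + (R_xlen_t)ny * kk)];
            }
          }
        }
        std::nth_element(buf.begin(), buf.begin() + 13, buf.end());
        out[i + nx * (j + (R_xlen_t)ny * k)] = buf[13];
      }
    }
  }
  return out;
}
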