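#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// median of the first n entries of buf (buf is scratch; reordered in place)
static double buf_median(std::vector<double> &buf, int n) {
  int h = n / 2;
  std::nth_element(buf.begin(), buf.begin() + h, buf.begin() + n);
  double hi = buf[h];
  if (n % 2 == 1) return hi;
  double lo = *std::max_element(buf.begin(), buf.begin() + h);
  return 0.5 * (lo + hi);
}

// 2-D running median with a kh x kw rectangular window.
// Anchoring: window offsets along each axis are [-k/2, k - 1 - k/2], i.e.
// [-5, +4] for k = 10. Borders are handled by edge replication.
// [[Rcpp::export]]
NumericMatrix median_filter_rect(NumericMatrix img, int kh, int kw) {
  int nr = img.nrow(), nc = img.ncol();
  if (kh < 1 || kw < 1)
    stop("kernel dimensions must be >= 1");
  if (kh > nr || kw > nc)
    stop("kernel (%d x %d) larger than image (%d x %d)", kh, kw, nr, nc);
  int rlo = -(kh / 2), rhi = kh - 1 - kh / 2;
  int clo = -(kw / 2), chi = kw - 1 - kw / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf(static_cast<size_t>(kh) * kw);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int n = 0;
      for (int dj = clo; dj <= chi; ++dj) {
        int jj = j + dj;
        if (jj < 0) jj = 0; else if (jj >= nc) jj = nc - 1;
        for (int di = rlo; di <= rhi; ++di) {
          int ii = i + di;
          if (ii < 0) ii = 0; else if (ii >= nr) ii = nr - 1;
          buf[n++] = img(ii, jj);
        }
      }
      out(i, j) = buf_median(buf, n);
    }
  }
  return out;
}

// Per-pixel median across the columns of a (npixel x nframe) matrix.
// [[Rcpp::export]]
NumericVector row_median(NumericMatrix x) {
  int n = x.nrow(), k = x.ncol();
  NumericVector out(n);
  std::vector<double> buf(k);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < k; ++j) buf[j] = x(i, j);
    out[i] = buf_median(buf, k);
  }
  return out;
}
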