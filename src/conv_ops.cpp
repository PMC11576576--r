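#include <Rcpp.h>
using namespace Rcpp;

// im2col for 3x3 convolution with zero padding 1, stride 1.
// x: H x W x C array (column-major, first index fastest).
// Returns (H*W) x (9*C) matrix; column order: (dy, dx, c) with dy fastest.
// [[Rcpp::export(name = ".im2col3")]]
NumericMatrix im2col3(NumericVector x, int H, int W, int C) {
  NumericMatrix out(H * W, 9 * C);
  const double *px = x.begin();
  for (int c = 0; c < C; ++c) {
    const double *plane = px + (size_t)c * H * W;
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        const int col = c * 9 + (dx + 1) * 3 + (dy + 1);
        double *po = &out(0, col);
        for (int w = 0; w < W; ++w) {
          const int ws = w + dx;
          if (ws < 0 || ws >= W) continue;
          const double *src = plane + (size_t)ws * H;
          double *dst = po + (size_t)w * H;
          const int y0 = (dy < 0) ? 1 : 0;
          const int y1 = (dy > 0) ? H - 1 : H;
          for (int h = y0; h < y1; ++h) dst[h] = src[h + dy];
        }
      }
    }
  }
  return out;
}

// col2im: adjoint of im2col3. cols: (H*W) x (9*C); returns H*W*C vector.
// [[Rcpp::export(name = ".col2im3")]]
NumericVector col2im3(NumericMatrix cols, int H, int W, int C) {
  NumericVector out(H * W * C);
  double *po = out.begin();
  for (int c = 0; c < C; ++c) {
    double *plane = po + (size_t)c * H * W;
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        const int col = c * 9 + (dx + 1) * 3 + (dy + 1);
        const double *pc = &cols(0, col);
        for (int w = 0; w < W; ++w) {
          const int ws = w + dx;
          if (ws < 0 || ws >= W) continue;
          double *dst = plane + (size_t)ws * H;
          const double *src = pc + (size_t)w * H;
          const int y0 = (dy < 0) ? 1 : 0;
          const int y1 = (dy > 0) ? H - 1 : H;
          for (int h = y0; h < y1; ++h) dst[h + dy] += src[h];
        }
      }
    }
  }
  return out;
}
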