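#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Ray-driven parallel-beam forward projection of a 2D map.
// img: n x n coefficient map (dimensionless), pixel size px (mm).
// Returns line integrals in cm, [nViews x nDet]; detector spacing fov/nDet.
// [[Rcpp::export(name = ".fpParallel")]]
NumericMatrix fpParallel(NumericMatrix img, double px, int nViews, int nDet,
                         double fov) {
  const int n = img.nrow();
  const double dt = fov / nDet;
  const double half = (n - 1) / 2.0;
  const double L = std::sqrt(2.0) * n * px;
  const double ds = px / 2.0;
  const int nS = (int)std::ceil(L / ds) + 1;
  NumericMatrix out(nViews, nDet);
  for (int v = 0; v < nViews; ++v) {
    const double th = M_PI * v / nViews;
    const double ct = std::cos(th), st = std::sin(th);
    for (int d = 0; d < nDet; ++d) {
      const double t = (d + 0.5 - nDet / 2.0) * dt;
      // ray: p(s) = t*(ct, st) + s*(-st, ct)
      double acc = 0.0;
      const double s0 = -L / 2.0;
      for (int k = 0; k < nS; ++k) {
        const double s = s0 + k * ds;
        const double x = t * ct - s * st;
        const double y = t * st + s * ct;
        const double fx = x / px + half;
        const double fy = y / px + half;
        const int ix = (int)std::floor(fx);
        const int iy = (int)std::floor(fy);
        if (ix < 0 || iy < 0 || ix >= n - 1 || iy >= n - 1) continue;
        const double wx = fx - ix, wy = fy - iy;
        acc += (1 - wx) * (1 - wy) * img(ix, iy) + wx * (1 - wy) * img(ix + 1, iy)
             + (1 - wx) * wy * img(ix, iy + 1) + wx * wy * img(ix + 1, iy + 1);
      }
      out(v, d) = acc * ds / 10.0; // mm -> cm
    }
  }
  return out;
}

// Pixel-driven parallel-beam backprojection of a filtered sinogram.
// filt: [nViews x nDet]; returns nPix x nPix image with pixel size pxr (mm).
// [[Rcpp::export(name = ".bpParallel")]]
NumericMatrix bpParallel(NumericMatrix filt, int nPix, double pxr, double fov) {
  const int nViews = filt.nrow(), nDet = filt.ncol();
  const double dt = fov / nDet;
  const double half = (nPix - 1) / 2.0;
  NumericMatrix out(nPix, nPix);
  std::vector<double> cs(nViews), sn(nViews);
  for (int v = 0; v < nViews; ++v) {
    const double th = M_PI * v / nViews;
    cs[v] = std::cos(th); sn[v] = std::sin(th);
  }
  for (int j = 0; j < nPix; ++j) {
    const double y = (j - half) * pxr;
    for (int i = 0; i < nPix; ++i) {
      const double x = (i - half) * pxr;
      double acc = 0.0;
      for (int v = 0; v < nViews; ++v) {
        const double t = x * cs[v] + y * sn[v];
        const double u = t / dt + nDet / 2.0 - 0.5;
        const int iu = (int)std::floor(u);
        if (iu < 0 || iu >= nDet - 1) continue;
        const double w = u - iu;
        acc += (1 - w) * filt(v, iu) + w * filt(v, iu + 1);
      }
      out(i, j) = acc * M_PI / nViews;
    }
  }
  return out;
}
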