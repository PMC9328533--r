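#include <Rcpp.h>
using namespace Rcpp;

// Column-major spatial layout throughout: an H x W x C array stores
// element (y, x, c) at y + x*H + c*H*W (0-based), matching R arrays.

// Unfold an H x W x C array into a (k*k*C) x (H*W) matrix for "same"
// convolution with zero padding. Row order within a column is
// dy + k*dx + k*k*c so that matrix(weights, k*k*Cin, Cout) with weights
// stored as a (k, k, Cin, Cout) R array lines up without permutation.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int C, int k) {
  int pad = (k - 1) / 2;
  NumericMatrix out(k * k * C, H * W);
  const double* px = x.begin();
  double* po = out.begin();
  int kk = k * k;
  for (int col = 0; col < W; ++col) {
    for (int row = 0; row < H; ++row) {
      int p = row + col * H;
      double* dst = po + (size_t)p * kk * C;
      for (int c = 0; c < C; ++c) {
        const double* plane = px + (size_t)c * H * W;
        for (int dx = 0; dx < k; ++dx) {
          int xx = col + dx - pad;
          bool xin = (xx >= 0 && xx < W);
          for (int dy = 0; dy < k; ++dy) {
            int yy = row + dy - pad;
            double v = 0.0;
            if (xin && yy >= 0 && yy < H) v = plane[yy + xx * H];
            dst[dy + k * dx + kk * c] = v;
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of cpp_im2col: fold a (k*k*C) x (H*W) gradient back into an
// H x W x C array, summing overlapping contributions.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int H, int W, int C, int k) {
  int pad = (k - 1) / 2;
  NumericVector out(H * W * C);
  double* po = out.begin();
  const double* pc = cols.begin();
  int kk = k * k;
  for (int col = 0; col < W; ++col) {
    for (int row = 0; row < H; ++row) {
      int p = row + col * H;
      const double* src = pc + (size_t)p * kk * C;
      for (int c = 0; c < C; ++c) {
        double* plane = po + (size_t)c * H * W;
        for (int dx = 0; dx < k; ++dx) {
          int xx = col + dx - pad;
          if (xx < 0 || xx >= W) continue;
          for (int dy = 0; dy < k; ++dy) {
            int yy = row + dy - pad;
            if (yy < 0 || yy >= H) continue;
            plane[yy + xx * H] += src[dy + k * dx + kk * c];
          }
        }
      }
    }
  }
  return out;
}

// Affine warp by inverse mapping: for each output pixel (x, y) (0-based,
// x = column) the 2x3 matrix m maps output -> input coordinates; the input
// is sampled bilinearly (or nearest for label rasters). Out-of-frame
// samples are fill (default 0).
// [[Rcpp::export]]
NumericVector cpp_warp_affine(NumericVector x, int H, int W, int C,
                              int outH, int outW, NumericMatrix m,
                              bool bilinear, double fill) {
  NumericVector out((size_t)outH * outW * C);
  const double* px = x.begin();
  double* po = out.begin();
  double a = m(0, 0), b = m(0, 1), tx = m(0, 2);
  double c_ = m(1, 0), d = m(1, 1), ty = m(1, 2);
  for (int xo = 0; xo < outW; ++xo) {
    for (int yo = 0; yo < outH; ++yo) {
      double xi = a * xo + b * yo + tx;
      double yi = c_ * xo + d * yo + ty;
      if (bilinear) {
        int x0 = (int)std::floor(xi), y0 = (int)std::floor(yi);
        double fx = xi - x0, fy = yi - y0;
        for (int ch = 0; ch < C; ++ch) {
          const double* plane = px + (size_t)ch * H * W;
          double acc = 0.0, wsum = 0.0;
          for (int dx = 0; dx <= 1; ++dx) {
            for (int dy = 0; dy <= 1; ++dy) {
              int xx = x0 + dx, yy = y0 + dy;
              double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy);
              if (xx >= 0 && xx < W && yy >= 0 && yy < H) {
                acc += w * plane[yy + xx * H];
                wsum += w;
              }
            }
          }
          double v;
          if (wsum <= 1e-12) v = fill;
          else if (wsum >= 1.0 - 1e-9) v = acc;   // avoid 0 * NA
          else v = acc + (1.0 - wsum) * fill;
          po[yo + (size_t)xo * outH + (size_t)ch * outH * outW] = v;
        }
      } else {
        int xx = (int)std::lround(xi), yy = (int)std::lround(yi);
        bool in = (xx >= 0 && xx < W && yy >= 0 && yy < H);
        for (int ch = 0; ch < C; ++ch) {
          double v = in ? px[yy + (size_t)xx * H + (size_t)ch * H * W] : fill;
          po[yo + (size_t)xo * outH + (size_t)ch * outH * outW] = v;
        }
      }
    }
  }
  return out;
}
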