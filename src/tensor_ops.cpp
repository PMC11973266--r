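// Low-level kernels for the CNN engine and image ops.
//
// Tensor layout used throughout: a batch of B feature maps of height H,
// width W and C channels is stored as a (B*H*W) x C double matrix, rows
// ordered sample-major then row-major in space: row = (b*H + y)*W + x
// (0-based).  Channels are columns so convolutions become one dgemm per
// batch after im2col.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// 3x3, stride 1, pad 1 im2col.  Output is (B*H*W) x (9*Cin); column
// (ci*9 + k) holds input channel ci at kernel offset k = ky*3 + kx,
// ky,kx in {0,1,2} meaning dy,dx in {-1,0,1}.  Out-of-image taps are 0.
// [[Rcpp::export]]
arma::mat cpp_im2col(const arma::mat& X, int B, int H, int W) {
  const int Cin = X.n_cols;
  const int HW = H * W;
  arma::mat out(B * HW, 9 * Cin, arma::fill::zeros);
  for (int ci = 0; ci < Cin; ++ci) {
    const double* src = X.colptr(ci);
    for (int k = 0; k < 9; ++k) {
      const int dy = k / 3 - 1, dx = k % 3 - 1;
      double* dst = out.colptr(ci * 9 + k);
      for (int b = 0; b < B; ++b) {
        const int base = b * HW;
        const int ylo = std::max(0, -dy), yhi = std::min(H, H - dy);
        const int xlo = std::max(0, -dx), xhi = std::min(W, W - dx);
        for (int y = ylo; y < yhi; ++y) {
          const double* s = src + base + (y + dy) * W + dx;
          double* d = dst + base + y * W;
          for (int x = xlo; x < xhi; ++x) d[x] = s[x];
        }
      }
    }
  }
  return out;
}

// Adjoint of cpp_im2col: scatter-add columns back onto the image grid.
// [[Rcpp::export]]
arma::mat cpp_col2im(const arma::mat& dCols, int B, int H, int W, int Cin) {
  const int HW = H * W;
  arma::mat dX(B * HW, Cin, arma::fill::zeros);
  for (int ci = 0; ci < Cin; ++ci) {
    double* dst = dX.colptr(ci);
    for (int k = 0; k < 9; ++k) {
      const int dy = k / 3 - 1, dx = k % 3 - 1;
      const double* src = dCols.colptr(ci * 9 + k);
      for (int b = 0; b < B; ++b) {
        const int base = b * HW;
        const int ylo = std::max(0, -dy), yhi = std::min(H, H - dy);
        const int xlo = std::max(0, -dx), xhi = std::min(W, W - dx);
        for (int y = ylo; y < yhi; ++y) {
          double* d = dst + base + (y + dy) * W + dx;
          const double* s = src + base + y * W;
          for (int x = xlo; x < xhi; ++x) d[x] += s[x];
        }
      }
    }
  }
  return dX;
}

// 2x2 max pooling, stride 2.  Returns pooled values and the 1-based row
// index (per channel) of each selected element for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool(const arma::mat& X, int B, int H, int W) {
  const int C = X.n_cols;
  const int Ho = H / 2, Wo = W / 2;
  const int HW = H * W, HWo = Ho * Wo;
  arma::mat Y(B * HWo, C);
  arma::imat idx(B * HWo, C);
  for (int c = 0; c < C; ++c) {
    const double* src = X.colptr(c);
    for (int b = 0; b < B; ++b) {
      for (int py = 0; py < Ho; ++py) {
        for (int px = 0; px < Wo; ++px) {
          const int r00 = b * HW + (2 * py) * W + 2 * px;
          int best = r00;
          double v = src[r00];
          const int cand[3] = {r00 + 1, r00 + W, r00 + W + 1};
          for (int j = 0; j < 3; ++j)
            if (src[cand[j]] > v) { v = src[cand[j]]; best = cand[j]; }
          const int ro = b * HWo + py * Wo + px;
          Y(ro, c) = v;
          idx(ro, c) = best + 1;
        }
      }
    }
  }
  return List::create(_["y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::mat cpp_maxpool_bw(const arma::mat& dY, const arma::imat& idx, int nrow_in) {
  const int C = dY.n_cols;
  arma::mat dX(nrow_in, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* dst = dX.colptr(c);
    const double* s = dY.colptr(c);
    const arma::sword* id = idx.colptr(c);
    for (arma::uword r = 0; r < dY.n_rows; ++r) dst[id[r] - 1] += s[r];
  }
  return dX;
}

// Bilinear resize of a single-channel H x W matrix (half-pixel centers).
// [[Rcpp::export]]
arma::mat cpp_resize_bilinear(const arma::mat& M, int outH, int outW) {
  const int H = M.n_rows, W = M.n_cols;
  arma::mat out(outH, outW);
  const double sy = (double)H / outH, sx = (double)W / outW;
  for (int j = 0; j < outW; ++j) {
    double xs = (j + 0.5) * sx - 0.5;
    int x0 = (int)std::floor(xs);
    double wx = xs - x0;
    int x0c = std::min(std::max(x0, 0), W - 1);
    int x1c = std::min(std::max(x0 + 1, 0), W - 1);
    for (int i = 0; i < outH; ++i) {
      double ys = (i + 0.5) * sy - 0.5;
      int y0 = (int)std::floor(ys);
      double wy = ys - y0;
      int y0c = std::min(std::max(y0, 0), H - 1);
      int y1c = std::min(std::max(y0 + 1, 0), H - 1);
      out(i, j) = (1 - wy) * ((1 - wx) * M(y0c, x0c) + wx * M(y0c, x1c)) +
                  wy * ((1 - wx) * M(y1c, x0c) + wx * M(y1c, x1c));
    }
  }
  return out;
}
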