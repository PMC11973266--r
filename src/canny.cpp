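// Canny edge detector on a single-channel image (values on the 0..255
// scale): Gaussian smoothing, Sobel gradients, non-maximum suppression
// along the quantized gradient direction, double thresholding on the L2
// gradient magnitude, and 8-connected hysteresis from strong pixels.

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat gaussian_blur(const arma::mat& M, double sigma) {
  if (sigma <= 0) return M;
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  arma::vec k(2 * r + 1);
  for (int i = -r; i <= r; ++i) k(i + r) = std::exp(-0.5 * i * i / (sigma * sigma));
  k /= arma::accu(k);
  const int H = M.n_rows, W = M.n_cols;
  arma::mat tmp(H, W), out(H, W);
  // horizontal then vertical pass, replicate borders
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      double s = 0;
      for (int i = -r; i <= r; ++i) {
        int xx = std::min(std::max(x + i, 0), W - 1);
        s += k(i + r) * M(y, xx);
      }
      tmp(y, x) = s;
    }
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      double s = 0;
      for (int i = -r; i <= r; ++i) {
        int yy = std::min(std::max(y + i, 0), H - 1);
        s += k(i + r) * tmp(yy, x);
      }
      out(y, x) = s;
    }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_canny(const arma::mat& gray, double low, double high, double sigma) {
  const int H = gray.n_rows, W = gray.n_cols;
  arma::mat g = gaussian_blur(gray, sigma);
  arma::mat gx(H, W, arma::fill::zeros), gy(H, W, arma::fill::zeros),
      mag(H, W, arma::fill::zeros);
  for (int y = 1; y < H - 1; ++y)
    for (int x = 1; x < W - 1; ++x) {
      double sx = (g(y - 1, x + 1) + 2 * g(y, x + 1) + g(y + 1, x + 1)) -
                  (g(y - 1, x - 1) + 2 * g(y, x - 1) + g(y + 1, x - 1));
      double sy = (g(y + 1, x - 1) + 2 * g(y + 1, x) + g(y + 1, x + 1)) -
                  (g(y - 1, x - 1) + 2 * g(y - 1, x) + g(y - 1, x + 1));
      gx(y, x) = sx;
      gy(y, x) = sy;
      mag(y, x) = std::sqrt(sx * sx + sy * sy);
    }
  // non-maximum suppression into 4 direction bins
  arma::mat nms(H, W, arma::fill::zeros);
  for (int y = 1; y < H - 1; ++y)
    for (int x = 1; x < W - 1; ++x) {
      double m = mag(y, x);
      if (m == 0) continue;
      double ang = std::atan2(gy(y, x), gx(y, x)) * 180.0 / M_PI;
      if (ang < 0) ang += 180.0;
      double a, b;
      if (ang < 22.5 || ang >= 157.5) { a = mag(y, x - 1); b = mag(y, x + 1); }
      else if (ang < 67.5) { a = mag(y - 1, x - 1); b = mag(y + 1, x + 1); }
      else if (ang < 112.5) { a = mag(y - 1, x); b = mag(y + 1, x); }
      else { a = mag(y - 1, x + 1); b = mag(y + 1, x - 1); }
      // strict on one side so symmetric ties thin to a single pixel
      if (m > a && m >= b) nms(y, x) = m;
    }
  // double threshold + hysteresis (BFS from strong pixels)
  arma::mat out(H, W, arma::fill::zeros);
  std::queue<std::pair<int, int> > q;
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x)
      if (nms(y, x) >= high) { out(y, x) = 1; q.push(std::make_pair(y, x)); }
  while (!q.empty()) {
    std::pair<int, int> p = q.front();
    q.pop();
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int yy = p.first + dy, xx = p.second + dx;
        if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
        if (out(yy, xx) == 0 && nms(yy, xx) >= low) {
          out(yy, xx) = 1;
          q.push(std::make_pair(yy, xx));
        }
      }
  }
  return out;
}
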