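#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Pixel filters used by the binarization chain. All filters use
// replicate padding (or, for the non-flat morphology, ignore
// out-of-image offsets, which is equivalent at the border).

struct BallElement {
  std::vector<int> di, dj;
  std::vector<double> h;
};

static BallElement make_ball(double radius) {
  BallElement b;
  int r = (int)std::floor(radius);
  for (int di = -r; di <= r; ++di) {
    for (int dj = -r; dj <= r; ++dj) {
      double d2 = (double)di * di + (double)dj * dj;
      if (d2 <= radius * radius) {
        b.di.push_back(di);
        b.dj.push_back(dj);
        b.h.push_back(std::sqrt(radius * radius - d2));
      }
    }
  }
  return b;
}

// Grayscale rolling-ball background: the image surface is opened by a
// ball-shaped (non-flat) structuring element of the given radius —
// erosion by the ball height profile followed by dilation. The result
// is the background estimate to subtract.
// [[Rcpp::export]]
NumericMatrix rolling_ball_background_cpp(NumericMatrix img, double radius) {
  int H = img.nrow(), W = img.ncol();
  BallElement b = make_ball(radius);
  size_t K = b.h.size();
  NumericMatrix ero(H, W), bg(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double m = R_PosInf;
      for (size_t k = 0; k < K; ++k) {
        int ii = i + b.di[k], jj = j + b.dj[k];
        if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
        double v = img(ii, jj) - b.h[k];
        if (v < m) m = v;
      }
      ero(i, j) = m;
    }
  }
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double m = R_NegInf;
      for (size_t k = 0; k < K; ++k) {
        int ii = i + b.di[k], jj = j + b.dj[k];
        if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
        double v = ero(ii, jj) + b.h[k];
        if (v > m) m = v;
      }
      bg(i, j) = m;
    }
  }
  return bg;
}

static inline int clampi(int x, int lo, int hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Separable Gaussian blur, replicate padding, kernel truncated at 3 sigma.
// [[Rcpp::export]]
NumericMatrix gaussian_blur_cpp(NumericMatrix img, double sigma) {
  int H = img.nrow(), W = img.ncol();
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> kern(2 * r + 1);
  double s = 0.0;
  for (int k = -r; k <= r; ++k) {
    kern[k + r] = std::exp(-0.5 * (double)k * k / (sigma * sigma));
    s += kern[k + r];
  }
  for (double &v : kern) v /= s;
  NumericMatrix tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int k = -r; k <= r; ++k)
        acc += kern[k + r] * img(clampi(i + k, 0, H - 1), j);
      tmp(i, j) = acc;
    }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int k = -r; k <= r; ++k)
        acc += kern[k + r] * tmp(i, clampi(j + k, 0, W - 1));
      out(i, j) = acc;
    }
  return out;
}

// Median filter over a (2r+1) x (2r+1) square neighborhood, replicate padding.
// [[Rcpp::export]]
NumericMatrix median_filter_cpp(NumericMatrix img, int radius) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  int n = (2 * radius + 1) * (2 * radius + 1);
  std::vector<double> buf(n);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      int m = 0;
      for (int di = -radius; di <= radius; ++di)
        for (int dj = -radius; dj <= radius; ++dj)
          buf[m++] = img(clampi(i + di, 0, H - 1), clampi(j + dj, 0, W - 1));
      std::nth_element(buf.begin(), buf.begin() + n / 2, buf.begin() + n);
      double hi = buf[n / 2];
      if (n % 2 == 1) {
        out(i, j) = hi;
      } else {
        double lo = *std::max_element(buf.begin(), buf.begin() + n / 2);
        out(i, j) = 0.5 * (lo + hi);
      }
    }
  }
  return out;
}
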