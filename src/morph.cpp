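#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// Grayscale erosion/dilation with a non-flat spherical-cap structuring
// element: se(dx, dy) = scale * sqrt(r^2 - dx^2 - dy^2) for dx^2+dy^2 <= r^2.
// Offsets falling outside the image are skipped; the centre offset is always
// present, so opening(const) == const at every pixel including borders.
// Loops run offset-outermost with contiguous column access so the O(N r^2)
// sweep stays cache-friendly.

struct BallSE {
  std::vector<int> dx, dy;
  std::vector<double> h;
};

static BallSE make_ball(double radius, double scale) {
  BallSE se;
  int r = (int)std::floor(radius);
  for (int x = -r; x <= r; ++x)
    for (int y = -r; y <= r; ++y) {
      double d2 = (double)x * x + (double)y * y;
      if (d2 <= radius * radius) {
        se.dx.push_back(x);
        se.dy.push_back(y);
        se.h.push_back(scale * std::sqrt(radius * radius - d2));
      }
    }
  return se;
}

// direction +1: erosion (min of img(p + d) - se); -1: dilation
// (max of img(p - d) + se)
static NumericMatrix ball_filter(const NumericMatrix& img, double radius,
                                 double scale, int sign) {
  const int nr = img.nrow(), nc = img.ncol();
  BallSE se = make_ball(radius, scale);
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(),
            sign > 0 ? R_PosInf : R_NegInf);
  const double* src = img.begin();
  double* dst = out.begin();
  for (size_t t = 0; t < se.h.size(); ++t) {
    int dx = sign > 0 ? se.dx[t] : -se.dx[t];
    int dy = sign > 0 ? se.dy[t] : -se.dy[t];
    double h = se.h[t];
    int j0 = std::max(0, -dx), j1 = std::min(nc, nc - dx);
    int i0 = std::max(0, -dy), i1 = std::min(nr, nr - dy);
    for (int j = j0; j < j1; ++j) {
      const double* s = src + (size_t)(j + dx) * nr + (i0 + dy);
      double* d = dst + (size_t)j * nr + i0;
      int len = i1 - i0;
      if (sign > 0) {
        for (int i = 0; i < len; ++i) {
          double v = s[i] - h;
          if (v < d[i]) d[i] = v;
        }
      } else {
        for (int i = 0; i < len; ++i) {
          double v = s[i] + h;
          if (v > d[i]) d[i] = v;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".ball_erode_cpp")]]
NumericMatrix ball_erode_cpp(NumericMatrix img, double radius, double scale) {
  return ball_filter(img, radius, scale, +1);
}

// [[Rcpp::export(name = ".ball_dilate_cpp")]]
NumericMatrix ball_dilate_cpp(NumericMatrix img, double radius, double scale) {
  return ball_filter(img, radius, scale, -1);
}
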