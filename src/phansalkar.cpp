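#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Local Phansalkar threshold over a circular window.
//
// `img` holds intensities already normalized to [0, 1]. For every pixel the
// mean m and population standard deviation s of the in-bounds window pixels
// (dx^2 + dy^2 <= radius^2) are computed and compared against
//   standard form: T = m * (1 + p * exp(-q m) + k * (s / r - 1))
//   printed form:  T = m * (p * exp(-q m) + k * s / r)
// The printed form corresponds to reading the bracket literally as
// "... + k (s/R) - 1". A pixel is foreground when its value exceeds T
// (white objects on a dark background).
// [[Rcpp::export]]
IntegerMatrix phansalkar_mask_cpp(NumericMatrix img, int radius,
                                  double k, double r, double p, double q,
                                  bool printed_form) {
  const int H = img.nrow(), W = img.ncol();
  std::vector<int> dy, dx;
  dy.reserve((2 * radius + 1) * (2 * radius + 1));
  dx.reserve((2 * radius + 1) * (2 * radius + 1));
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b)
      if (a * a + b * b <= radius * radius) {
        dy.push_back(a);
        dx.push_back(b);
      }
  const size_t nOff = dy.size();
  IntegerMatrix out(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double s1 = 0.0, s2 = 0.0;
      int n = 0;
      for (size_t t = 0; t < nOff; ++t) {
        const int y = i + dy[t], x = j + dx[t];
        if (y < 0 || y >= H || x < 0 || x >= W) continue;
        const double v = img(y, x);
        s1 += v;
        s2 += v * v;
        ++n;
      }
      const double m = s1 / n;
      double var = s2 / n - m * m;
      if (var < 0) var = 0;
      const double sd = std::sqrt(var);
      const double T = printed_form
        ? m * (p * std::exp(-q * m) + k * sd / r)
        : m * (1.0 + p * std::exp(-q * m) + k * (sd / r - 1.0));
      out(i, j) = img(i, j) > T ? 1 : 0;
    }
  }
  return out;
}
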