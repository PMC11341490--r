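#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// Matrices are column-major: element (i, j) = row i (y), column j (x).

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// 2-D convolution with replicate (nearest) edge padding.
// [[Rcpp::export]]
NumericMatrix cpp_convolve2d(const NumericMatrix& img, const NumericMatrix& kern) {
  const int nr = img.nrow(), nc = img.ncol();
  const int kr = kern.nrow(), kc = kern.ncol();
  const int hr = kr / 2, hc = kc / 2;
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int dj = -hc; dj <= hc; ++dj) {
        const int jj = clampi(j + dj, 0, nc - 1);
        for (int di = -hr; di <= hr; ++di) {
          const int ii = clampi(i + di, 0, nr - 1);
          acc += img(ii, jj) * kern(hr + di, hc + dj);
        }
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// Sobel gradient; gx is the derivative along columns (x), gy along rows (y).
// Normalised by 1/8 so magnitudes are in gray-levels per pixel. Border
// pixels get zero gradient.
// [[Rcpp::export]]
List cpp_sobel(const NumericMatrix& img) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix gx(nr, nc), gy(nr, nc), mag(nr, nc);
  for (int j = 1; j < nc - 1; ++j) {
    for (int i = 1; i < nr - 1; ++i) {
      const double sx =
        -img(i - 1, j - 1) + img(i - 1, j + 1)
        - 2.0 * img(i, j - 1) + 2.0 * img(i, j + 1)
        - img(i + 1, j - 1) + img(i + 1, j + 1);
      const double sy =
        -img(i - 1, j - 1) - 2.0 * img(i - 1, j) - img(i - 1, j + 1)
        + img(i + 1, j - 1) + 2.0 * img(i + 1, j) + img(i + 1, j + 1);
      gx(i, j) = sx / 8.0;
      gy(i, j) = sy / 8.0;
      mag(i, j) = std::sqrt(gx(i, j) * gx(i, j) + gy(i, j) * gy(i, j));
    }
  }
  return List::create(_["gx"] = gx, _["gy"] = gy, _["mag"] = mag);
}

// Canny edge map: Sobel gradient, non-maximum suppression along the
// quantised gradient direction, then double-threshold hysteresis
// (8-connected) on the surviving maxima. `low` and `high` are gradient
// magnitudes in gray-levels per pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_canny(const NumericMatrix& img, double low, double high) {
  const int nr = img.nrow(), nc = img.ncol();
  List g = cpp_sobel(img);
  NumericMatrix gx = g["gx"], gy = g["gy"], mag = g["mag"];

  // non-maximum suppression with bilinear interpolation of the magnitude
  // at unit distance along the true gradient direction; this localises
  // edges consistently on oblique boundaries where the classic 8-way
  // quantisation flips sides
  IntegerMatrix nms(nr, nc);
  for (int j = 1; j < nc - 1; ++j) {
    for (int i = 1; i < nr - 1; ++i) {
      const double m = mag(i, j);
      if (m <= 0.0) continue;
      const double ux = gx(i, j) / m;   // step along columns (x)
      const double uy = gy(i, j) / m;   // step along rows (y)
      // bilinear sample of mag at (i + s*uy, j + s*ux), s = +/-1
      double n[2];
      for (int s = 0; s < 2; ++s) {
        const double fi = i + (s ? -uy : uy);
        const double fj = j + (s ? -ux : ux);
        const int i0 = (int)std::floor(fi), j0 = (int)std::floor(fj);
        const double wi = fi - i0, wj = fj - j0;
        double acc = 0.0;
        for (int di = 0; di <= 1; ++di)
          for (int dj = 0; dj <= 1; ++dj) {
            const int ii = clampi(i0 + di, 0, nr - 1);
            const int jj = clampi(j0 + dj, 0, nc - 1);
            const double w = (di ? wi : 1.0 - wi) * (dj ? wj : 1.0 - wj);
            acc += w * mag(ii, jj);
          }
        n[s] = acc;
      }
      // strict comparison on one side breaks two-pixel plateaus
      if (m >= n[0] && m > n[1]) nms(i, j) = 1;
    }
  }

  // hysteresis: grow strong edges through weak candidates
  IntegerMatrix out(nr, nc);
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (nms(i, j) && mag(i, j) >= high) {
        out(i, j) = 1;
        q.push(std::make_pair(i, j));
      }
  while (!q.empty()) {
    const int ci = q.front().first, cj = q.front().second;
    q.pop();
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        const int ii = ci + di, jj = cj + dj;
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        if (!out(ii, jj) && nms(ii, jj) && mag(ii, jj) >= low) {
          out(ii, jj) = 1;
          q.push(std::make_pair(ii, jj));
        }
      }
  }
  return out;
}

// Connected-component labelling of a binary matrix (labels 1..k, background
// 0). conn is 4 or 8.
// [[Rcpp::export]]
IntegerMatrix cpp_label(const IntegerMatrix& bin, int conn) {
  const int nr = bin.nrow(), nc = bin.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!bin(i, j) || lab(i, j)) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        const int ci = q.front().first, cj = q.front().second;
        q.pop();
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            if (conn == 4 && di != 0 && dj != 0) continue;
            const int ii = ci + di, jj = cj + dj;
            if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
            if (bin(ii, jj) && !lab(ii, jj)) {
              lab(ii, jj) = next;
              q.push(std::make_pair(ii, jj));
            }
          }
      }
    }
  }
  return lab;
}

// Fill interior holes of a binary mask: background is flood-filled
// 4-connected from the image border; anything not reached is interior.
// 4-connectivity makes an 8-connected closed curve water-tight.
// [[Rcpp::export]]
IntegerMatrix cpp_fill_holes(const IntegerMatrix& bin) {
  const int nr = bin.nrow(), nc = bin.ncol();
  IntegerMatrix reach(nr, nc);
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j) {
    if (!bin(0, j))      { if (!reach(0, j))      { reach(0, j) = 1;      q.push(std::make_pair(0, j)); } }
    if (!bin(nr - 1, j)) { if (!reach(nr - 1, j)) { reach(nr - 1, j) = 1; q.push(std::make_pair(nr - 1, j)); } }
  }
  for (int i = 0; i < nr; ++i) {
    if (!bin(i, 0))      { if (!reach(i, 0))      { reach(i, 0) = 1;      q.push(std::make_pair(i, 0)); } }
    if (!bin(i, nc - 1)) { if (!reach(i, nc - 1)) { reach(i, nc - 1) = 1; q.push(std::make_pair(i, nc - 1)); } }
  }
  const int di4[4] = { 1, -1, 0, 0 };
  const int dj4[4] = { 0, 0, 1, -1 };
  while (!q.empty()) {
    const int ci = q.front().first, cj = q.front().second;
    q.pop();
    for (int k = 0; k < 4; ++k) {
      const int ii = ci + di4[k], jj = cj + dj4[k];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      if (!bin(ii, jj) && !reach(ii, jj)) {
        reach(ii, jj) = 1;
        q.push(std::make_pair(ii, jj));
      }
    }
  }
  IntegerMatrix filled(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      filled(i, j) = reach(i, j) ? 0 : 1;
  return filled;
}
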