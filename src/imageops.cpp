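// Low-level raster operations shared by the preprocessing, augmentation,
// postprocessing and morphometry layers. All matrices are R column-major
// (row r, col c) grayscale images; masks are 0/1.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
#include <algorithm>
using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  // symmetric reflection with edge repeat: -1 -> 0, n -> n-1
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export]]
NumericMatrix cpp_box_mean(const NumericMatrix& m, int window) {
  int H = m.nrow(), W = m.ncol(), r = (window - 1) / 2;
  NumericMatrix tmp(H, W), out(H, W);
  // separable: rows then cols, reflective border
  for (int c = 0; c < W; ++c)
    for (int i = 0; i < H; ++i) {
      double s = 0.0;
      for (int k = -r; k <= r; ++k) s += m(reflect_idx(i + k, H), c);
      tmp(i, c) = s / window;
    }
  for (int i = 0; i < H; ++i)
    for (int c = 0; c < W; ++c) {
      double s = 0.0;
      for (int k = -r; k <= r; ++k) s += tmp(i, reflect_idx(c + k, W));
      out(i, c) = s / window;
    }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_resize(const NumericMatrix& m, int outH, int outW,
                         bool nearest) {
  int H = m.nrow(), W = m.ncol();
  NumericMatrix out(outH, outW);
  double sy = (double)H / outH, sx = (double)W / outW;
  for (int i = 0; i < outH; ++i) {
    double fy = (i + 0.5) * sy - 0.5;
    for (int j = 0; j < outW; ++j) {
      double fx = (j + 0.5) * sx - 0.5;
      if (nearest) {
        int r = (int)std::lround(fy), c = (int)std::lround(fx);
        r = std::min(std::max(r, 0), H - 1);
        c = std::min(std::max(c, 0), W - 1);
        out(i, j) = m(r, c);
      } else {
        double y = std::min(std::max(fy, 0.0), (double)(H - 1));
        double x = std::min(std::max(fx, 0.0), (double)(W - 1));
        int r0 = (int)std::floor(y), c0 = (int)std::floor(x);
        int r1 = std::min(r0 + 1, H - 1), c1 = std::min(c0 + 1, W - 1);
        double wy = y - r0, wx = x - c0;
        out(i, j) = (1 - wy) * ((1 - wx) * m(r0, c0) + wx * m(r0, c1)) +
                    wy * ((1 - wx) * m(r1, c0) + wx * m(r1, c1));
      }
    }
  }
  return out;
}

// Inverse-mapped affine warp about the image center. `inv` is the 2x2
// matrix taking centered output coords (dy, dx) to centered input coords.
// [[Rcpp::export]]
NumericMatrix cpp_affine_warp(const NumericMatrix& m, const NumericMatrix& inv,
                              bool nearest, double fill) {
  int H = m.nrow(), W = m.ncol();
  NumericMatrix out(H, W);
  double cy = (H - 1) / 2.0, cx = (W - 1) / 2.0;
  double a = inv(0, 0), b = inv(0, 1), c2 = inv(1, 0), d = inv(1, 1);
  for (int i = 0; i < H; ++i) {
    double dy = i - cy;
    for (int j = 0; j < W; ++j) {
      double dx = j - cx;
      double sy = a * dy + b * dx + cy;
      double sx = c2 * dy + d * dx + cx;
      if (nearest) {
        int r = (int)std::lround(sy), c = (int)std::lround(sx);
        out(i, j) = (r < 0 || r >= H || c < 0 || c >= W) ? fill : m(r, c);
      } else {
        if (sy < 0 || sy > H - 1 || sx < 0 || sx > W - 1) {
          out(i, j) = fill;
          continue;
        }
        int r0 = (int)std::floor(sy), c0 = (int)std::floor(sx);
        int r1 = std::min(r0 + 1, H - 1), c1 = std::min(c0 + 1, W - 1);
        double wy = sy - r0, wx = sx - c0;
        out(i, j) = (1 - wy) * ((1 - wx) * m(r0, c0) + wx * m(r0, c1)) +
                    wy * ((1 - wx) * m(r1, c0) + wx * m(r1, c1));
      }
    }
  }
  return out;
}

// Fast non-local means: loop over search-window offsets; per offset the
// patchwise squared difference field is box-summed with an integral image,
// giving every pixel's patch distance for that offset in O(HW).
// [[Rcpp::export]]
NumericMatrix cpp_nlm_denoise(const NumericMatrix& m, int patch, int search,
                              double h) {
  int H = m.nrow(), W = m.ncol();
  int p = (patch - 1) / 2, s = (search - 1) / 2, pad = p + s;
  int PH = H + 2 * pad, PW = W + 2 * pad;
  std::vector<double> im((size_t)PH * PW);
  for (int c = 0; c < PW; ++c) {
    int cc = reflect_idx(c - pad, W);
    for (int r = 0; r < PH; ++r)
      im[(size_t)c * PH + r] = m(reflect_idx(r - pad, H), cc);
  }
  std::vector<double> wsum((size_t)H * W, 0.0), vsum((size_t)H * W, 0.0);
  std::vector<double> integ((size_t)(PH + 1) * (PW + 1));
  double h2 = h * h * patch * patch;  // h scales the mean patch distance
  if (h2 <= 0) h2 = 1e-12;
  for (int dy = -s; dy <= s; ++dy) {
    for (int dx = -s; dx <= s; ++dx) {
      // squared difference between image and its (dy,dx)-shift, integral
      for (int c = 0; c <= PW; ++c) integ[(size_t)c * (PH + 1)] = 0.0;
      for (int r = 0; r <= PH; ++r) integ[r] = 0.0;
      for (int c = 1; c <= PW; ++c) {
        double rowsum = 0.0;
        for (int r = 1; r <= PH; ++r) {
          int rr = r - 1, cc = c - 1;
          double d = 0.0;
          int r2 = rr + dy, c2 = cc + dx;
          if (r2 >= 0 && r2 < PH && c2 >= 0 && c2 < PW) {
            double diff = im[(size_t)cc * PH + rr] - im[(size_t)c2 * PH + r2];
            d = diff * diff;
          }
          rowsum += d;
          integ[(size_t)c * (PH + 1) + r] =
              integ[(size_t)(c - 1) * (PH + 1) + r] + rowsum;
        }
      }
      for (int c = 0; c < W; ++c) {
        for (int r = 0; r < H; ++r) {
          int pr = r + pad, pc = c + pad;  // position in padded image
          int r0 = pr - p, r1 = pr + p + 1, c0 = pc - p, c1 = pc + p + 1;
          double d2 = integ[(size_t)c1 * (PH + 1) + r1] -
                      integ[(size_t)c0 * (PH + 1) + r1] -
                      integ[(size_t)c1 * (PH + 1) + r0] +
                      integ[(size_t)c0 * (PH + 1) + r0];
          double w = std::exp(-d2 / h2);
          wsum[(size_t)c * H + r] += w;
          vsum[(size_t)c * H + r] += w * im[(size_t)(pc + dx) * PH + (pr + dy)];
        }
      }
    }
  }
  NumericMatrix out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      out(r, c) = vsum[(size_t)c * H + r] / wsum[(size_t)c * H + r];
  return out;
}

// Contrast-limited adaptive histogram equalization on a [0,1] image.
// Tile mappings are clipped-histogram CDFs, blended bilinearly between
// neighbouring tile centers.
// [[Rcpp::export]]
NumericMatrix cpp_clahe(const NumericMatrix& m, int tiles, double clip,
                        int nbins) {
  int H = m.nrow(), W = m.ncol();
  int th = (H + tiles - 1) / tiles, tw = (W + tiles - 1) / tiles;
  int nty = (H + th - 1) / th, ntx = (W + tw - 1) / tw;
  std::vector<std::vector<double>> maps((size_t)nty * ntx,
                                        std::vector<double>(nbins));
  for (int ty = 0; ty < nty; ++ty) {
    for (int tx = 0; tx < ntx; ++tx) {
      int r0 = ty * th, r1 = std::min(r0 + th, H);
      int c0 = tx * tw, c1 = std::min(c0 + tw, W);
      int npix = (r1 - r0) * (c1 - c0);
      std::vector<double> hist(nbins, 0.0);
      for (int c = c0; c < c1; ++c)
        for (int r = r0; r < r1; ++r) {
          int b = (int)(m(r, c) * (nbins - 1) + 0.5);
          b = std::min(std::max(b, 0), nbins - 1);
          hist[b] += 1.0;
        }
      double lim = std::max(1.0, clip * npix);
      double excess = 0.0;
      for (int b = 0; b < nbins; ++b)
        if (hist[b] > lim) { excess += hist[b] - lim; hist[b] = lim; }
      double add = excess / nbins;
      for (int b = 0; b < nbins; ++b) hist[b] += add;
      double cum = 0.0;
      std::vector<double>& mp = maps[(size_t)ty * ntx + tx];
      for (int b = 0; b < nbins; ++b) {
        cum += hist[b];
        mp[b] = cum / npix;
      }
    }
  }
  NumericMatrix out(H, W);
  for (int c = 0; c < W; ++c) {
    double gx = (c - (tw - 1) / 2.0) / tw;  // tile-center coordinate
    int tx0 = (int)std::floor(gx);
    double wx = gx - tx0;
    int txa = std::min(std::max(tx0, 0), ntx - 1);
    int txb = std::min(std::max(tx0 + 1, 0), ntx - 1);
    for (int r = 0; r < H; ++r) {
      double gy = (r - (th - 1) / 2.0) / th;
      int ty0 = (int)std::floor(gy);
      double wy = gy - ty0;
      int tya = std::min(std::max(ty0, 0), nty - 1);
      int tyb = std::min(std::max(ty0 + 1, 0), nty - 1);
      int b = (int)(m(r, c) * (nbins - 1) + 0.5);
      b = std::min(std::max(b, 0), nbins - 1);
      double v00 = maps[(size_t)tya * ntx + txa][b];
      double v01 = maps[(size_t)tya * ntx + txb][b];
      double v10 = maps[(size_t)tyb * ntx + txa][b];
      double v11 = maps[(size_t)tyb * ntx + txb][b];
      out(r, c) = (1 - wy) * ((1 - wx) * v00 + wx * v01) +
                  wy * ((1 - wx) * v10 + wx * v11);
    }
  }
  return out;
}

// 8-connected component labelling (0 = background, labels 1..K in
// first-encounter order, column-major scan).
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const IntegerMatrix& mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<std::pair<int, int>> stack;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back({r, c});
      lab(r, c) = next;
      while (!stack.empty()) {
        auto [cr, cc] = stack.back();
        stack.pop_back();
        for (int dc = -1; dc <= 1; ++dc)
          for (int dr = -1; dr <= 1; ++dr) {
            int nr = cr + dr, nc = cc + dc;
            if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
            if (mask(nr, nc) != 0 && lab(nr, nc) == 0) {
              lab(nr, nc) = next;
              stack.push_back({nr, nc});
            }
          }
      }
    }
  }
  return lab;
}

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact squared Euclidean distance from every pixel to the nearest zero
// (background) pixel center. A large finite sentinel stands in for
// "no background in this scan line" (Inf would break the parabola
// envelope); an all-foreground mask yields Inf in the output.
// [[Rcpp::export]]
NumericMatrix cpp_edt_sq(const IntegerMatrix& mask) {
  int H = mask.nrow(), W = mask.ncol();
  const double BIG = 1e12;
  NumericMatrix g(H, W);
  std::vector<double> f(std::max(H, W)), d(std::max(H, W));
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) f[r] = mask(r, c) == 0 ? 0.0 : BIG;
    dt1d(f, d, H);
    for (int r = 0; r < H; ++r) g(r, c) = d[r];
  }
  NumericMatrix out(H, W);
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) f[c] = g(r, c);
    dt1d(f, d, W);
    for (int c = 0; c < W; ++c) {
      out(r, c) = d[c] >= BIG ? std::numeric_limits<double>::infinity() : d[c];
    }
  }
  return out;
}

// Zhang-Suen binary thinning; returns the 8-connected skeleton.
// [[Rcpp::export]]
IntegerMatrix cpp_thin(const IntegerMatrix& mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix img(clone(mask));
  auto at = [&](int r, int c) -> int {
    if (r < 0 || r >= H || c < 0 || c >= W) return 0;
    return img(r, c);
  };
  bool changed = true;
  std::vector<std::pair<int, int>> del;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      del.clear();
      for (int c = 0; c < W; ++c)
        for (int r = 0; r < H; ++r) {
          if (img(r, c) == 0) continue;
          int p2 = at(r - 1, c), p3 = at(r - 1, c + 1), p4 = at(r, c + 1),
              p5 = at(r + 1, c + 1), p6 = at(r + 1, c), p7 = at(r + 1, c - 1),
              p8 = at(r, c - 1), p9 = at(r - 1, c - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          del.push_back({r, c});
        }
      for (auto& rc : del) img(rc.first, rc.second) = 0;
      if (!del.empty()) changed = true;
    }
  }
  return img;
}
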