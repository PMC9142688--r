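#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pixel convention: 0-based (x = column, y = row), pixel centers at integer
// coordinates. All transforms map output coordinates to source coordinates
// (inverse mapping): xs = a1*x + a2*y + a3, ys = a4*x + a5*y + a6.

static inline double bilin_sample(const NumericMatrix &img, double ys, double xs) {
  int H = img.nrow(), W = img.ncol();
  int y0 = (int)std::floor(ys);
  int x0 = (int)std::floor(xs);
  if (y0 > H - 2) y0 = H - 2;
  if (x0 > W - 2) x0 = W - 2;
  if (y0 < 0) y0 = 0;
  if (x0 < 0) x0 = 0;
  double fy = ys - y0, fx = xs - x0;
  double v00 = img(y0, x0),     v01 = img(y0, x0 + 1);
  double v10 = img(y0 + 1, x0), v11 = img(y0 + 1, x0 + 1);
  return (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11);
}

// Affine (or Euclidean, expanded to 6 parameters) warp by inverse-mapping
// bilinear interpolation. p = (a1..a6). (ox, oy) shift the sampled source
// coordinate, which lets a patch-local transform sample from the full frame.
// clamp = TRUE replicates edges (support all TRUE); otherwise out-of-bounds
// pixels are 0 with support FALSE.
// [[Rcpp::export]]
List cpp_warp_affine(const NumericMatrix img, const NumericVector p,
                     const int out_h, const int out_w,
                     const double ox, const double oy,
                     const bool clamp, const bool nearest) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(out_h, out_w);
  LogicalMatrix sup(out_h, out_w);
  const double a1 = p[0], a2 = p[1], a3 = p[2], a4 = p[3], a5 = p[4], a6 = p[5];
  for (int c = 0; c < out_w; ++c) {
    const double x = (double)c;
    for (int r = 0; r < out_h; ++r) {
      const double y = (double)r;
      double xs = a1 * x + a2 * y + a3 + ox;
      double ys = a4 * x + a5 * y + a6 + oy;
      bool inb = (xs >= 0.0 && xs <= W - 1.0 && ys >= 0.0 && ys <= H - 1.0);
      if (clamp) {
        if (xs < 0) xs = 0; else if (xs > W - 1.0) xs = W - 1.0;
        if (ys < 0) ys = 0; else if (ys > H - 1.0) ys = H - 1.0;
        inb = true;
      }
      if (inb) {
        if (nearest) {
          int xi = (int)std::lround(xs), yi = (int)std::lround(ys);
          out(r, c) = img(yi, xi);
        } else {
          out(r, c) = bilin_sample(img, ys, xs);
        }
        sup(r, c) = true;
      } else {
        out(r, c) = 0.0;
        sup(r, c) = false;
      }
    }
  }
  return List::create(_["image"] = out, _["support"] = sup);
}

// Sample an image at arbitrary (x, y) coordinates (bilinear).
// [[Rcpp::export]]
List cpp_sample_bilinear(const NumericMatrix img, const NumericVector xs,
                         const NumericVector ys, const bool clamp) {
  const int H = img.nrow(), W = img.ncol();
  const int n = xs.size();
  NumericVector out(n);
  LogicalVector sup(n);
  for (int i = 0; i < n; ++i) {
    double x = xs[i], y = ys[i];
    bool inb = (x >= 0.0 && x <= W - 1.0 && y >= 0.0 && y <= H - 1.0);
    if (clamp) {
      if (x < 0) x = 0; else if (x > W - 1.0) x = W - 1.0;
      if (y < 0) y = 0; else if (y > H - 1.0) y = H - 1.0;
      inb = true;
    }
    if (inb) {
      out[i] = bilin_sample(img, y, x);
      sup[i] = true;
    } else {
      out[i] = 0.0;
      sup[i] = false;
    }
  }
  return List::create(_["values"] = out, _["support"] = sup);
}

// Patchwise warp-and-stitch: each patch (half-open bounds y0,y1,x0,x1,
// 0-based, rows of `bounds`) is resampled from the full frame through its
// own patch-local affine (row of `trans`, a1..a6), and the outputs are
// averaged where patches overlap. Pixels with no valid contributor take the
// value of `fallback`.
// [[Rcpp::export]]
NumericMatrix cpp_warp_patches(const NumericMatrix frame,
                               const IntegerMatrix bounds,
                               const NumericMatrix trans,
                               const NumericMatrix fallback) {
  const int H = frame.nrow(), W = frame.ncol();
  NumericMatrix acc(H, W);
  IntegerMatrix cnt(H, W);
  const int n = bounds.nrow();
  for (int k = 0; k < n; ++k) {
    const int y0 = bounds(k, 0), y1 = bounds(k, 1);
    const int x0 = bounds(k, 2), x1 = bounds(k, 3);
    const double a1 = trans(k, 0), a2 = trans(k, 1), a3 = trans(k, 2);
    const double a4 = trans(k, 3), a5 = trans(k, 4), a6 = trans(k, 5);
    for (int c = x0; c < x1; ++c) {
      const double xl = (double)(c - x0);
      for (int r = y0; r < y1; ++r) {
        const double yl = (double)(r - y0);
        const double xs = a1 * xl + a2 * yl + a3 + x0;
        const double ys = a4 * xl + a5 * yl + a6 + y0;
        if (xs >= 0.0 && xs <= W - 1.0 && ys >= 0.0 && ys <= H - 1.0) {
          acc(r, c) += bilin_sample(frame, ys, xs);
          cnt(r, c) += 1;
        }
      }
    }
  }
  NumericMatrix out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      out(r, c) = cnt(r, c) > 0 ? acc(r, c) / cnt(r, c) : fallback(r, c);
  return out;
}

// Pearson correlation between template and frame displaced by integer
// (sx, sy), on the valid overlap; -Inf when the overlap is below
// min_overlap of the frame area or an operand has zero variance.
// [[Rcpp::export]]
double cpp_shift_corr(const NumericMatrix frame, const NumericMatrix tmpl,
                      const int sx, const int sy, const double min_overlap) {
  const int H = frame.nrow(), W = frame.ncol();
  const int r0 = std::max(0, -sy), r1 = std::min(H, H - sy);
  const int c0 = std::max(0, -sx), c1 = std::min(W, W - sx);
  if (r1 <= r0 || c1 <= c0) return R_NegInf;
  const double n = (double)(r1 - r0) * (double)(c1 - c0);
  if (n < min_overlap * H * W) return R_NegInf;
  double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
  for (int c = c0; c < c1; ++c) {
    for (int r = r0; r < r1; ++r) {
      const double a = tmpl(r, c);
      const double b = frame(r + sy, c + sx);
      sa += a; sb += b; saa += a * a; sbb += b * b; sab += a * b;
    }
  }
  const double va = saa - sa * sa / n, vb = sbb - sb * sb / n;
  if (va <= 0 || vb <= 0) return R_NegInf;
  return (sab - sa * sb / n) / std::sqrt(va * vb);
}

// Nearest-neighbour patchwise transport for label masks: overlapping
// contributors are resolved by majority vote (ties go to the first
// contributing patch in row-major patch order).
// [[Rcpp::export]]
NumericMatrix cpp_warp_patches_nearest(const NumericMatrix mask,
                                       const IntegerMatrix bounds,
                                       const NumericMatrix trans,
                                       const NumericMatrix fallback) {
  const int H = mask.nrow(), W = mask.ncol();
  const int SLOTS = 8;
  std::vector<double> vals((size_t)H * W * SLOTS);
  IntegerMatrix cnt(H, W);
  const int n = bounds.nrow();
  for (int k = 0; k < n; ++k) {
    const int y0 = bounds(k, 0), y1 = bounds(k, 1);
    const int x0 = bounds(k, 2), x1 = bounds(k, 3);
    const double a1 = trans(k, 0), a2 = trans(k, 1), a3 = trans(k, 2);
    const double a4 = trans(k, 3), a5 = trans(k, 4), a6 = trans(k, 5);
    for (int c = x0; c < x1; ++c) {
      const double xl = (double)(c - x0);
      for (int r = y0; r < y1; ++r) {
        const double yl = (double)(r - y0);
        const double xs = a1 * xl + a2 * yl + a3 + x0;
        const double ys = a4 * xl + a5 * yl + a6 + y0;
        const long xi = std::lround(xs), yi = std::lround(ys);
        if (xi >= 0 && xi < W && yi >= 0 && yi < H) {
          int m = cnt(r, c);
          if (m < SLOTS) {
            vals[((size_t)c * H + r) * SLOTS + m] = mask(yi, xi);
            cnt(r, c) = m + 1;
          }
        }
      }
    }
  }
  NumericMatrix out(H, W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      const int m = cnt(r, c);
      if (m == 0) { out(r, c) = fallback(r, c); continue; }
      const double *v = &vals[((size_t)c * H + r) * SLOTS];
      int best = 0, bestn = 0;
      for (int i = 0; i < m; ++i) {
        int ni = 0;
        for (int j = 0; j < m; ++j) if (v[j] == v[i]) ++ni;
        if (ni > bestn) { bestn = ni; best = i; }
      }
      out(r, c) = v[best];
    }
  }
  return out;
}
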