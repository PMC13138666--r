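#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <stack>
using namespace Rcpp;

// symmetric (half-sample) boundary reflection: -1 -> 0, n -> n-1
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export(name = ".cpp_gaussian_blur")]]
NumericMatrix cpp_gaussian_blur(NumericMatrix img, double sigma) {
  if (sigma <= 0) return clone(img);
  int radius = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * radius + 1);
  double s = 0.0;
  for (int i = -radius; i <= radius; ++i) {
    k[i + radius] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + radius];
  }
  for (size_t i = 0; i < k.size(); ++i) k[i] /= s;
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double acc = 0;
      for (int i = -radius; i <= radius; ++i)
        acc += k[i + radius] * img(reflect_idx(r + i, nr), c);
      tmp(r, c) = acc;
    }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double acc = 0;
      for (int i = -radius; i <= radius; ++i)
        acc += k[i + radius] * tmp(r, reflect_idx(c + i, nc));
      out(r, c) = acc;
    }
  return out;
}

// Sobel gradients; gx is the horizontal (column/x) derivative, gy vertical (row/y)
// [[Rcpp::export(name = ".cpp_sobel")]]
List cpp_sobel(NumericMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix gx(nr, nc), gy(nr, nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      double sx = 0, sy = 0;
      for (int dr = -1; dr <= 1; ++dr) {
        for (int dc = -1; dc <= 1; ++dc) {
          double v = img(reflect_idx(r + dr, nr), reflect_idx(c + dc, nc));
          int wx = (dc == 0) ? 0 : dc * ((dr == 0) ? 2 : 1);
          int wy = (dr == 0) ? 0 : dr * ((dc == 0) ? 2 : 1);
          sx += wx * v;
          sy += wy * v;
        }
      }
      gx(r, c) = sx;
      gy(r, c) = sy;
    }
  }
  return List::create(_["gx"] = gx, _["gy"] = gy);
}

// [[Rcpp::export(name = ".cpp_resize_bilinear")]]
NumericMatrix cpp_resize_bilinear(NumericMatrix img, int out_h, int out_w) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(out_h, out_w);
  double sy = (double)nr / out_h, sx = (double)nc / out_w;
  for (int r = 0; r < out_h; ++r) {
    double fy = (r + 0.5) * sy - 0.5;
    int y0 = (int)std::floor(fy);
    double wy = fy - y0;
    int y0c = std::min(std::max(y0, 0), nr - 1);
    int y1c = std::min(std::max(y0 + 1, 0), nr - 1);
    for (int c = 0; c < out_w; ++c) {
      double fx = (c + 0.5) * sx - 0.5;
      int x0 = (int)std::floor(fx);
      double wx = fx - x0;
      int x0c = std::min(std::max(x0, 0), nc - 1);
      int x1c = std::min(std::max(x0 + 1, 0), nc - 1);
      out(r, c) = (1 - wy) * ((1 - wx) * img(y0c, x0c) + wx * img(y0c, x1c)) +
                  wy * ((1 - wx) * img(y1c, x0c) + wx * img(y1c, x1c));
    }
  }
  return out;
}

// grayscale erosion (neighborhood min) / dilation (max) with reflected borders;
// on 0/1 images these reduce to the set-theoretic "S fits F" / "S hits F" rules
// [[Rcpp::export(name = ".cpp_morph")]]
NumericMatrix cpp_morph(NumericMatrix img, LogicalMatrix se, bool dilate) {
  int nr = img.nrow(), nc = img.ncol();
  int kr = se.nrow(), kc = se.ncol();
  int or_ = kr / 2, oc = kc / 2;
  NumericMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      double best = dilate ? R_NegInf : R_PosInf;
      for (int i = 0; i < kr; ++i) {
        for (int j = 0; j < kc; ++j) {
          if (!se(i, j)) continue;
          double v = img(reflect_idx(r + i - or_, nr), reflect_idx(c + j - oc, nc));
          if (dilate) { if (v > best) best = v; }
          else        { if (v < best) best = v; }
        }
      }
      out(r, c) = best;
    }
  }
  return out;
}

// Canny: gaussian blur, Sobel, non-maximum suppression along the quantized
// gradient direction, double-threshold hysteresis (8-connected)
// [[Rcpp::export(name = ".cpp_canny")]]
IntegerMatrix cpp_canny(NumericMatrix img, double low, double high, double sigma) {
  NumericMatrix sm = cpp_gaussian_blur(img, sigma);
  List g = cpp_sobel(sm);
  NumericMatrix gx = g["gx"], gy = g["gy"];
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix mag(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      mag(r, c) = std::sqrt(gx(r, c) * gx(r, c) + gy(r, c) * gy(r, c));

  // 0 = none, 1 = weak, 2 = strong
  IntegerMatrix state(nr, nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      double m = mag(r, c);
      if (m < low) continue;
      double ang = std::atan2(gy(r, c), gx(r, c));
      double deg = ang * 180.0 / M_PI;
      if (deg < 0) deg += 180.0;
      int dr1, dc1;
      if (deg < 22.5 || deg >= 157.5)      { dr1 = 0; dc1 = 1; }   // horizontal gradient
      else if (deg < 67.5)                 { dr1 = 1; dc1 = 1; }
      else if (deg < 112.5)                { dr1 = 1; dc1 = 0; }   // vertical gradient
      else                                 { dr1 = 1; dc1 = -1; }
      double n1 = 0, n2 = 0;
      int ra = r + dr1, ca = c + dc1, rb = r - dr1, cb = c - dc1;
      if (ra >= 0 && ra < nr && ca >= 0 && ca < nc) n1 = mag(ra, ca);
      if (rb >= 0 && rb < nr && cb >= 0 && cb < nc) n2 = mag(rb, cb);
      // >= on one side, > on the other: plateau ties keep a single pixel
      if (m >= n1 && m > n2)
        state(r, c) = (m >= high) ? 2 : 1;
    }
  }
  // hysteresis: promote weak pixels 8-connected to a strong pixel
  IntegerMatrix out(nr, nc);
  std::stack<std::pair<int, int> > st;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      if (state(r, c) == 2) { out(r, c) = 255; st.push(std::make_pair(r, c)); }
  while (!st.empty()) {
    std::pair<int, int> p = st.top(); st.pop();
    for (int dr = -1; dr <= 1; ++dr) {
      for (int dc = -1; dc <= 1; ++dc) {
        int r = p.first + dr, c = p.second + dc;
        if (r < 0 || r >= nr || c < 0 || c >= nc) continue;
        if (state(r, c) == 1 && out(r, c) == 0) {
          out(r, c) = 255;
          st.push(std::make_pair(r, c));
        }
      }
    }
  }
  return out;
}

// Gradient-direction circle voting: every edge pixel casts votes at +-r along
// its (unit) gradient for each candidate radius. Returns the center accumulator.
// [[Rcpp::export(name = ".cpp_hough_vote")]]
IntegerMatrix cpp_hough_vote(IntegerMatrix edges, NumericMatrix gx, NumericMatrix gy,
                             int rmin, int rmax) {
  int nr = edges.nrow(), nc = edges.ncol();
  IntegerMatrix acc(nr, nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (edges(r, c) == 0) continue;
      double g = std::sqrt(gx(r, c) * gx(r, c) + gy(r, c) * gy(r, c));
      if (g < 1e-9) continue;
      double ux = gx(r, c) / g, uy = gy(r, c) / g;
      for (int rad = rmin; rad <= rmax; ++rad) {
        for (int sgn = -1; sgn <= 1; sgn += 2) {
          int cc = (int)std::lround(c + sgn * rad * ux);
          int cr = (int)std::lround(r + sgn * rad * uy);
          if (cr >= 0 && cr < nr && cc >= 0 && cc < nc) acc(cr, cc) += 1;
        }
      }
    }
  }
  return acc;
}

// Most-supported radius for a center: mode of rounded distances of edge pixels
// inside the [rmin-1, rmax+1] annulus; ties resolved toward the smaller radius.
// [[Rcpp::export(name = ".cpp_radius_mode")]]
List cpp_radius_mode(IntegerMatrix edges, double cx, double cy, int rmin, int rmax) {
  int nr = edges.nrow(), nc = edges.ncol();
  std::vector<int> hist(rmax - rmin + 1, 0);
  int r0 = std::max(0, (int)std::floor(cy - rmax - 1));
  int r1 = std::min(nr - 1, (int)std::ceil(cy + rmax + 1));
  int c0 = std::max(0, (int)std::floor(cx - rmax - 1));
  int c1 = std::min(nc - 1, (int)std::ceil(cx + rmax + 1));
  for (int r = r0; r <= r1; ++r) {
    for (int c = c0; c <= c1; ++c) {
      if (edges(r, c) == 0) continue;
      double d = std::sqrt((c - cx) * (c - cx) + (r - cy) * (r - cy));
      int rd = (int)std::lround(d);
      if (rd >= rmin && rd <= rmax) hist[rd - rmin] += 1;
    }
  }
  int best = 0;
  for (size_t i = 1; i < hist.size(); ++i)
    if (hist[i] > hist[best]) best = (int)i;
  // support within +-1 px of the chosen radius (tolerant of rasterization)
  int c3 = hist[best];
  if (best > 0) c3 += hist[best - 1];
  if (best + 1 < (int)hist.size()) c3 += hist[best + 1];
  return List::create(_["radius"] = rmin + best, _["count"] = hist[best],
                      _["bandCount"] = c3);
}

// Fraction of evenly sampled perimeter points having an edge pixel within 1 px
// [[Rcpp::export(name = ".cpp_perimeter_support")]]
double cpp_perimeter_support(IntegerMatrix edges, double cx, double cy, double rad,
                             int n_samples) {
  int nr = edges.nrow(), nc = edges.ncol();
  int hit = 0;
  for (int i = 0; i < n_samples; ++i) {
    double th = 2.0 * M_PI * i / n_samples;
    double px = cx + rad * std::cos(th);
    double py = cy + rad * std::sin(th);
    bool found = false;
    int pr = (int)std::lround(py), pc = (int)std::lround(px);
    for (int dr = -1; dr <= 1 && !found; ++dr)
      for (int dc = -1; dc <= 1 && !found; ++dc) {
        int r = pr + dr, c = pc + dc;
        if (r >= 0 && r < nr && c >= 0 && c < nc && edges(r, c) != 0) found = true;
      }
    if (found) ++hit;
  }
  return (double)hit / n_samples;
}
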