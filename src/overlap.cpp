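#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Scanline x-interval decomposition of a simple polygon at height y.
// Even-odd rule with the half-open convention [ymin, ymax) per edge, so
// vertices on a scanline are counted once. Returns sorted crossing xs.
static void crossings(const NumericVector &px, const NumericVector &py,
                      double y, std::vector<double> &xs) {
  xs.clear();
  int n = px.size();
  for (int i = 0; i < n; ++i) {
    int j = (i + 1) % n;
    double y1 = py[i], y2 = py[j];
    if ((y1 <= y) != (y2 <= y)) {
      double t = (y - y1) / (y2 - y1);
      xs.push_back(px[i] + t * (px[j] - px[i]));
    }
  }
  std::sort(xs.begin(), xs.end());
}

static double merged_length(std::vector<std::pair<double, double> > &iv) {
  if (iv.empty()) return 0.0;
  std::sort(iv.begin(), iv.end());
  double len = 0.0, lo = iv[0].first, hi = iv[0].second;
  for (size_t k = 1; k < iv.size(); ++k) {
    if (iv[k].first > hi) { len += hi - lo; lo = iv[k].first; hi = iv[k].second; }
    else if (iv[k].second > hi) hi = iv[k].second;
  }
  return len + (hi - lo);
}

// Intersection and union areas of two simple polygons by strip integration:
// exact interval arithmetic along x, composite midpoint rule over nstrips
// horizontal strips spanning the union of the y-ranges. Intersection and
// union come from the same strips, so identical polygons give a ratio of
// exactly 1 and disjoint polygons exactly 0.
// [[Rcpp::export]]
NumericVector overlap_areas_cpp(NumericVector ax, NumericVector ay,
                                NumericVector bx, NumericVector by,
                                int nstrips) {
  double ylo = R_PosInf, yhi = R_NegInf;
  for (int i = 0; i < ay.size(); ++i) { ylo = std::min(ylo, ay[i]); yhi = std::max(yhi, ay[i]); }
  for (int i = 0; i < by.size(); ++i) { ylo = std::min(ylo, by[i]); yhi = std::max(yhi, by[i]); }
  if (!(yhi > ylo)) return NumericVector::create(0.0, 0.0);
  double h = (yhi - ylo) / nstrips;
  std::vector<double> xa, xb;
  std::vector<std::pair<double, double> > ia, ib, icap, icup;
  double inter = 0.0, uni = 0.0;
  for (int s = 0; s < nstrips; ++s) {
    double y = ylo + (s + 0.5) * h;
    crossings(ax, ay, y, xa);
    crossings(bx, by, y, xb);
    ia.clear(); ib.clear();
    for (size_t k = 0; k + 1 < xa.size(); k += 2) ia.push_back(std::make_pair(xa[k], xa[k + 1]));
    for (size_t k = 0; k + 1 < xb.size(); k += 2) ib.push_back(std::make_pair(xb[k], xb[k + 1]));
    // intersection: pairwise clip (few intervals per strip)
    icap.clear();
    for (size_t p = 0; p < ia.size(); ++p)
      for (size_t q = 0; q < ib.size(); ++q) {
        double lo = std::max(ia[p].first, ib[q].first);
        double hi = std::min(ia[p].second, ib[q].second);
        if (hi > lo) icap.push_back(std::make_pair(lo, hi));
      }
    icup = ia; icup.insert(icup.end(), ib.begin(), ib.end());
    inter += merged_length(icap) * h;
    uni += merged_length(icup) * h;
  }
  return NumericVector::create(inter, uni);
}

// Self-intersection test for a closed polygon (implicitly closed, first
// vertex not repeated). O(n^2) segment pairs with bounding-box rejection;
// shared endpoints of adjacent edges are not intersections.
// [[Rcpp::export]]
bool polygon_is_simple_cpp(NumericVector x, NumericVector y) {
  int n = x.size();
  if (n < 3) return false;
  for (int i = 0; i < n; ++i) {
    int i2 = (i + 1) % n;
    double ax1 = x[i], ay1 = y[i], ax2 = x[i2], ay2 = y[i2];
    double aminx = std::min(ax1, ax2), amaxx = std::max(ax1, ax2);
    double aminy = std::min(ay1, ay2), amaxy = std::max(ay1, ay2);
    for (int j = i + 2; j < n; ++j) {
      if (i == 0 && j == n - 1) continue;  // adjacent through closure
      int j2 = (j + 1) % n;
      double bx1 = x[j], by1 = y[j], bx2 = x[j2], by2 = y[j2];
      if (std::max(bx1, bx2) < aminx || std::min(bx1, bx2) > amaxx ||
          std::max(by1, by2) < aminy || std::min(by1, by2) > amaxy) continue;
      double d1 = (ax2 - ax1) * (by1 - ay1) - (ay2 - ay1) * (bx1 - ax1);
      double d2 = (ax2 - ax1) * (by2 - ay1) - (ay2 - ay1) * (bx2 - ax1);
      double d3 = (bx2 - bx1) * (ay1 - by1) - (by2 - by1) * (ax1 - bx1);
      double d4 = (bx2 - bx1) * (ay2 - by1) - (by2 - by1) * (ax2 - bx1);
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return false;
      if (d1 == 0 && d2 == 0 && d3 == 0 && d4 == 0) {
        // collinear: overlapping extents mean a degenerate touch
        if (std::max(std::min(bx1, bx2), aminx) <= std::min(std::max(bx1, bx2), amaxx) &&
            std::max(std::min(by1, by2), aminy) <= std::min(std::max(by1, by2), amaxy))
          return false;
      }
    }
  }
  return true;
}

// Scanline rasterization of a filled polygon into a logical row-major mask.
// Pixel (r, c) center is at x = c - 0.5, y = r - 0.5 in pixel units.
// [[Rcpp::export]]
LogicalMatrix fill_polygon_cpp(NumericVector px, NumericVector py,
                               int nrow, int ncol) {
  LogicalMatrix img(nrow, ncol);
  std::vector<double> xs;
  for (int r = 0; r < nrow; ++r) {
    double y = r + 0.5;
    crossings(px, py, y, xs);
    for (size_t k = 0; k + 1 < xs.size(); k += 2) {
      int c0 = std::max(0, (int)std::ceil(xs[k] - 0.5));
      int c1 = std::min(ncol - 1, (int)std::floor(xs[k + 1] - 0.5));
      for (int c = c0; c <= c1; ++c) img(r, c) = true;
    }
  }
  return img;
}
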