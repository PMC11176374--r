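#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Bounded Voronoi tessellation by iterative half-plane clipping.
//
// Each site's cell starts as the bounding rectangle and is clipped by the
// perpendicular bisector against other sites in order of increasing
// distance; clipping stops once the next site is more than twice as far as
// the farthest current cell vertex (no farther site can cut the cell).
// Neighbor ownership of each polygon edge is recovered from the edge
// midpoint (equidistance to the two sites), which is robust to the order of
// clips. Runs in roughly O(n^2 log n) overall; intended for up to a few
// thousand sites per image.

struct Pt {
  double x, y;
};

static inline double sqdist(double ax, double ay, double bx, double by) {
  double dx = ax - bx, dy = ay - by;
  return dx * dx + dy * dy;
}

// Clip convex polygon by half-plane {p : (p - m) . d <= 0}
static void clip_halfplane(std::vector<Pt>& poly, double mx, double my,
                           double dx, double dy) {
  size_t n = poly.size();
  if (n == 0) return;
  std::vector<Pt> out;
  out.reserve(n + 2);
  for (size_t i = 0; i < n; ++i) {
    const Pt& a = poly[i];
    const Pt& b = poly[(i + 1) % n];
    double fa = (a.x - mx) * dx + (a.y - my) * dy;
    double fb = (b.x - mx) * dx + (b.y - my) * dy;
    bool ina = fa <= 0.0, inb = fb <= 0.0;
    if (ina) out.push_back(a);
    if (ina != inb) {
      double t = fa / (fa - fb);
      Pt p;
      p.x = a.x + t * (b.x - a.x);
      p.y = a.y + t * (b.y - a.y);
      out.push_back(p);
    }
  }
  poly.swap(out);
}

// [[Rcpp::export]]
List voronoi_cells_cpp(NumericMatrix centers, double xmin, double ymin,
                       double xmax, double ymax, double min_edge) {
  const int n = centers.nrow();
  std::vector<double> cx(n), cy(n);
  for (int i = 0; i < n; ++i) {
    cx[i] = centers(i, 0);
    cy[i] = centers(i, 1);
  }

  List polys(n);
  std::vector<int> nb_i, nb_j;
  std::vector<double> nb_len;
  LogicalVector on_bounds(n);

  const double btol = 1e-9 * (std::fabs(xmax - xmin) + std::fabs(ymax - ymin));

  // Uniform spatial grid over the site bounding box for local candidate
  // gathering: each site only needs the sites within ~2 cell circumradii.
  double gx0 = cx[0], gx1 = cx[0], gy0 = cy[0], gy1 = cy[0];
  for (int i = 1; i < n; ++i) {
    gx0 = std::min(gx0, cx[i]); gx1 = std::max(gx1, cx[i]);
    gy0 = std::min(gy0, cy[i]); gy1 = std::max(gy1, cy[i]);
  }
  double cell = std::max(std::sqrt(((gx1 - gx0) * (gy1 - gy0) + 1e-12) /
                                   std::max(n, 1)), 1e-9);
  int gnx = (int)((gx1 - gx0) / cell) + 1;
  int gny = (int)((gy1 - gy0) / cell) + 1;
  std::vector<std::vector<int> > buckets((size_t)gnx * gny);
  for (int i = 0; i < n; ++i) {
    int bx = (int)((cx[i] - gx0) / cell);
    int by = (int)((cy[i] - gy0) / cell);
    buckets[(size_t)by * gnx + bx].push_back(i);
  }

  std::vector<std::pair<double, int> > cand;
  cand.reserve(64);

  for (int i = 0; i < n; ++i) {
    std::vector<Pt> poly;
    double r = 3.0 * cell;
    const double rfull = 2.0 * std::sqrt(sqdist(gx0, gy0, gx1, gy1)) +
                         std::sqrt(sqdist(xmin, ymin, xmax, ymax));
    int m = 0;
    for (;;) {
      // gather candidate sites within r of site i, sorted by distance
      cand.clear();
      double r2 = r * r;
      int bx0 = std::max(0, (int)((cx[i] - r - gx0) / cell));
      int bx1 = std::min(gnx - 1, (int)((cx[i] + r - gx0) / cell));
      int by0 = std::max(0, (int)((cy[i] - r - gy0) / cell));
      int by1 = std::min(gny - 1, (int)((cy[i] + r - gy0) / cell));
      for (int by = by0; by <= by1; ++by)
        for (int bx = bx0; bx <= bx1; ++bx)
          for (int j : buckets[(size_t)by * gnx + bx]) {
            if (j == i) continue;
            double dd = sqdist(cx[i], cy[i], cx[j], cy[j]);
            if (dd <= r2) cand.push_back(std::make_pair(dd, j));
          }
      std::sort(cand.begin(), cand.end());
      m = (int)cand.size();

      poly.assign({{xmin, ymin}, {xmax, ymin}, {xmax, ymax}, {xmin, ymax}});
      for (int k = 0; k < m; ++k) {
        int j = cand[k].second;
        double dj2 = cand[k].first;
        // farthest vertex from site i
        double rmax2 = 0.0;
        for (const Pt& v : poly)
          rmax2 = std::max(rmax2, sqdist(v.x, v.y, cx[i], cy[i]));
        if (dj2 > 4.0 * rmax2) break;  // bisector cannot cut the cell
        double mx = 0.5 * (cx[i] + cx[j]), my = 0.5 * (cy[i] + cy[j]);
        clip_halfplane(poly, mx, my, cx[j] - cx[i], cy[j] - cy[i]);
        if (poly.empty()) break;
      }
      if (poly.empty() || r >= rfull) break;
      // the result is final only if no site beyond r could cut the cell or
      // own one of its edges: r must exceed ~2x the cell circumradius
      double rmax2 = 0.0;
      for (const Pt& v : poly)
        rmax2 = std::max(rmax2, sqdist(v.x, v.y, cx[i], cy[i]));
      if (r2 >= 4.41 * rmax2) break;
      r = std::min(2.0 * r, rfull);
    }

    int nv = (int)poly.size();
    NumericMatrix P(nv, 2);
    bool touches = nv < 3;  // degenerate cells count as boundary-touching
    for (int v = 0; v < nv; ++v) {
      P(v, 0) = poly[v].x;
      P(v, 1) = poly[v].y;
      if (poly[v].x < xmin + btol || poly[v].x > xmax - btol ||
          poly[v].y < ymin + btol || poly[v].y > ymax - btol)
        touches = true;
    }
    polys[i] = P;
    on_bounds[i] = touches;

    // Edge ownership: an edge lies on the bisector of (i, j) iff its
    // midpoint is equidistant to both sites. Record j > i only (symmetric).
    for (int v = 0; v < nv; ++v) {
      const Pt& a = poly[v];
      const Pt& b = poly[(v + 1) % nv];
      double elen = std::sqrt(sqdist(a.x, a.y, b.x, b.y));
      if (elen <= min_edge || elen <= btol) continue;
      double qx = 0.5 * (a.x + b.x), qy = 0.5 * (a.y + b.y);
      // skip bounding-box edges
      if (qx < xmin + btol || qx > xmax - btol || qy < ymin + btol ||
          qy > ymax - btol)
        continue;
      double di = std::sqrt(sqdist(qx, qy, cx[i], cy[i]));
      int best = -1;
      double bestgap = 1e-6 * (di + 1.0);
      for (int k = 0; k < m; ++k) {
        int j = cand[k].second;
        // |q - cj| >= |ci - cj| - |q - ci|; candidates are sorted by
        // |ci - cj|, so once that exceeds 2*di + bestgap no later site can
        // be equidistant within the current best gap.
        double dsite = std::sqrt(cand[k].first);
        if (dsite > 2.0 * di + bestgap) break;
        double dj = std::sqrt(sqdist(qx, qy, cx[j], cy[j]));
        double gap = std::fabs(dj - di);
        if (gap < bestgap) {
          bestgap = gap;
          best = j;
        }
      }
      if (best > i) {
        nb_i.push_back(i + 1);
        nb_j.push_back(best + 1);
        nb_len.push_back(elen);
      }
    }
  }

  int ne = (int)nb_i.size();
  IntegerMatrix E(ne, 2);
  NumericVector L(ne);
  for (int e = 0; e < ne; ++e) {
    E(e, 0) = nb_i[e];
    E(e, 1) = nb_j[e];
    L[e] = nb_len[e];
  }
  return List::create(_["polygons"] = polys, _["edges"] = E,
                      _["edge_lengths"] = L, _["on_bounds"] = on_bounds);
}

// Convex hull area of a 2D point set (Andrew's monotone chain + shoelace).
static double hull_area(std::vector<std::pair<double, double> >& p) {
  std::sort(p.begin(), p.end());
  p.erase(std::unique(p.begin(), p.end()), p.end());
  const int m = (int)p.size();
  if (m < 3) return 0.0;
  std::vector<std::pair<double, double> > h(2 * m);
  int k = 0;
  auto cross = [](const std::pair<double, double>& o,
                  const std::pair<double, double>& a,
                  const std::pair<double, double>& b) {
    return (a.first - o.first) * (b.second - o.second) -
           (a.second - o.second) * (b.first - o.first);
  };
  for (int i = 0; i < m; ++i) {
    while (k >= 2 && cross(h[k - 2], h[k - 1], p[i]) <= 0) --k;
    h[k++] = p[i];
  }
  for (int i = m - 2, t = k + 1; i >= 0; --i) {
    while (k >= t && cross(h[k - 2], h[k - 1], p[i]) <= 0) --k;
    h[k++] = p[i];
  }
  h.resize(k - 1);
  double a2 = 0.0;
  for (size_t i = 0; i < h.size(); ++i) {
    const auto& u = h[i];
    const auto& v = h[(i + 1) % h.size()];
    a2 += u.first * v.second - v.first * u.second;
  }
  return 0.5 * std::fabs(a2);
}

// [[Rcpp::export]]
double convex_hull_area_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 3) return 0.0;
  std::vector<std::pair<double, double> > p(n);
  for (int i = 0; i < n; ++i) p[i] = std::make_pair(pts(i, 0), pts(i, 1));
  return hull_area(p);
}

// Batch polygon statistics: shoelace area, perimeter and convex hull area
// for each closed polygon (matrix of vertices, first vertex not repeated).
// [[Rcpp::export]]
NumericMatrix poly_stats_cpp(List polys) {
  const int n = polys.size();
  NumericMatrix out(n, 3);
  colnames(out) = CharacterVector::create("area", "perimeter", "hull_area");
  std::vector<std::pair<double, double> > buf;
  for (int i = 0; i < n; ++i) {
    NumericMatrix p = polys[i];
    const int m = p.nrow();
    double a2 = 0.0, per = 0.0;
    for (int v = 0; v < m; ++v) {
      int w = (v + 1) % m;
      a2 += p(v, 0) * p(w, 1) - p(w, 0) * p(v, 1);
      double dx = p(w, 0) - p(v, 0), dy = p(w, 1) - p(v, 1);
      per += std::sqrt(dx * dx + dy * dy);
    }
    out(i, 0) = 0.5 * std::fabs(a2);
    out(i, 1) = per;
    if (m >= 3) {
      buf.resize(m);
      for (int v = 0; v < m; ++v) buf[v] = std::make_pair(p(v, 0), p(v, 1));
      out(i, 2) = hull_area(buf);
    } else {
      out(i, 2) = 0.0;
    }
  }
  return out;
}

// Row-wise polygon statistics for a batch of equally discretized polygons:
// row i of X/Y holds the vertices of polygon i (closed, first vertex not
// repeated). Returns area, perimeter and convex hull area per row.
// [[Rcpp::export]]
NumericMatrix blob_stats_cpp(NumericMatrix X, NumericMatrix Y) {
  const int n = X.nrow(), m = X.ncol();
  NumericMatrix out(n, 3);
  colnames(out) = CharacterVector::create("area", "perimeter", "hull_area");
  std::vector<std::pair<double, double> > buf(m);
  for (int i = 0; i < n; ++i) {
    double a2 = 0.0, per = 0.0;
    for (int v = 0; v < m; ++v) {
      int w = (v + 1) % m;
      a2 += X(i, v) * Y(i, w) - X(i, w) * Y(i, v);
      double dx = X(i, w) - X(i, v), dy = Y(i, w) - Y(i, v);
      per += std::sqrt(dx * dx + dy * dy);
    }
    out(i, 0) = 0.5 * std::fabs(a2);
    out(i, 1) = per;
    buf.resize(m);
    for (int v = 0; v < m; ++v) buf[v] = std::make_pair(X(i, v), Y(i, v));
    out(i, 2) = hull_area(buf);
  }
  return out;
}

// Nearest and second-nearest site distances (and nearest index) on a pixel
// grid. Pixel centers are at ((c-1)*ps, (r-1)*ps) for 1-based (c, r); the
// returned matrices are nx x ny with dim1 = x, matching the package's image
// convention.
// [[Rcpp::export]]
List grid_nearest2_cpp(int nx, int ny, double ps, NumericMatrix centers) {
  const int n = centers.nrow();
  NumericMatrix d1(nx, ny), d2m(nx, ny);
  IntegerMatrix idx(nx, ny);
  std::vector<double> cx(n), cy(n);
  for (int i = 0; i < n; ++i) {
    cx[i] = centers(i, 0);
    cy[i] = centers(i, 1);
  }
  for (int yy = 0; yy < ny; ++yy) {
    double py = yy * ps;
    for (int xx = 0; xx < nx; ++xx) {
      double px = xx * ps;
      double b1 = R_PosInf, b2 = R_PosInf;
      int bi = 0;
      for (int i = 0; i < n; ++i) {
        double dd = sqdist(px, py, cx[i], cy[i]);
        if (dd < b1) {
          b2 = b1;
          b1 = dd;
          bi = i + 1;
        } else if (dd < b2) {
          b2 = dd;
        }
      }
      d1(xx, yy) = std::sqrt(b1);
      d2m(xx, yy) = std::sqrt(b2);
      idx(xx, yy) = bi;
    }
  }
  return List::create(_["d1"] = d1, _["d2"] = d2m, _["index"] = idx);
}
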