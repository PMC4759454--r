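#include <Rcpp.h>
#include <queue>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// 8-connected labeling of a logical matrix (row-major semantics irrelevant;
// R matrices are column-major, indices handled explicitly).
// Labels are assigned in raster order of first encounter, so the result is
// deterministic.
// [[Rcpp::export(name = ".cc_label2d8")]]
IntegerMatrix cc_label2d8(LogicalMatrix m) {
  int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int,int> > q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!m(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int,int> p = q.front(); q.pop();
        for (int di = -1; di <= 1; ++di) {
          for (int dj = -1; dj <= 1; ++dj) {
            if (di == 0 && dj == 0) continue;
            int ii = p.first + di, jj = p.second + dj;
            if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
            if (m(ii, jj) && lab(ii, jj) == 0) {
              lab(ii, jj) = next;
              q.push(std::make_pair(ii, jj));
            }
          }
        }
      }
    }
  }
  return lab;
}

// Seeded 3-D region growing with 26-connectivity: BFS from every seed voxel,
// accepting neighbours with hu >= tmin.  `hu` and `seeds` share dim (d1,d2,d3).
// [[Rcpp::export(name = ".region_grow3d")]]
LogicalVector region_grow3d(NumericVector hu, LogicalVector seeds, double tmin) {
  IntegerVector dim = hu.attr("dim");
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  R_xlen_t n = hu.size();
  LogicalVector out(n);
  std::queue<R_xlen_t> q;
  for (R_xlen_t k = 0; k < n; ++k) {
    if (seeds[k] && !out[k]) { out[k] = true; q.push(k); }
  }
  while (!q.empty()) {
    R_xlen_t k = q.front(); q.pop();
    int i = k % d1, j = (k / d1) % d2, s = k / ((R_xlen_t)d1 * d2);
    for (int ds = -1; ds <= 1; ++ds) {
      for (int dj = -1; dj <= 1; ++dj) {
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0 && ds == 0) continue;
          int ii = i + di, jj = j + dj, ss = s + ds;
          if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || ss < 0 || ss >= d3) continue;
          R_xlen_t kk = ii + (R_xlen_t)d1 * (jj + (R_xlen_t)d2 * ss);
          if (!out[kk] && hu[kk] >= tmin) { out[kk] = true; q.push(kk); }
        }
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

static void bres_push(int r0, int c0, int r1, int c1,
                      std::vector<int> &rr, std::vector<int> &cc) {
  // Bresenham line from (r0,c0) to (r1,c1), excluding the end point
  // (the next edge supplies it).
  int dr = std::abs(r1 - r0), dc = std::abs(c1 - c0);
  int sr = (r0 < r1) ? 1 : -1, sc = (c0 < c1) ? 1 : -1;
  int err = (dc > dr ? dc : -dr) / 2;
  int r = r0, c = c0;
  while (!(r == r1 && c == c1)) {
    rr.push_back(r); cc.push_back(c);
    int e2 = err;
    if (e2 > -dc) { err -= dr; c += sc; }
    if (e2 <  dr) { err += dc; r += sr; }
  }
}

// Densify a closed polygon of integer (row, col) vertices: every pixel visited
// by a Bresenham walk along each edge (closing edge included) appears once, in
// path order.
// [[Rcpp::export(name = ".densify_path")]]
IntegerMatrix densify_path(IntegerMatrix v) {
  int n = v.nrow();
  std::vector<int> rr, cc;
  for (int k = 0; k < n; ++k) {
    int k2 = (k + 1) % n;
    bres_push(v(k, 0), v(k, 1), v(k2, 0), v(k2, 1), rr, cc);
  }
  IntegerMatrix out(rr.size(), 2);
  for (size_t k = 0; k < rr.size(); ++k) { out(k, 0) = rr[k]; out(k, 1) = cc[k]; }
  return out;
}

// Greedy nearest-neighbour chaining: start at the lexicographically smallest
// (row, col) point; repeatedly hop to the nearest unvisited point (Euclidean;
// ties broken by smaller row, then smaller col).  Returns the 1-based visit
// order.
// [[Rcpp::export(name = ".nn_chain")]]
IntegerVector nn_chain(IntegerMatrix pts) {
  int n = pts.nrow();
  IntegerVector ord(n);
  std::vector<bool> used(n, false);
  int cur = 0;
  for (int k = 1; k < n; ++k) {
    if (pts(k, 0) < pts(cur, 0) ||
        (pts(k, 0) == pts(cur, 0) && pts(k, 1) < pts(cur, 1))) cur = k;
  }
  used[cur] = true; ord[0] = cur + 1;
  for (int step = 1; step < n; ++step) {
    double best = -1.0; int bi = -1;
    for (int k = 0; k < n; ++k) {
      if (used[k]) continue;
      double dr = pts(k, 0) - pts(cur, 0), dc = pts(k, 1) - pts(cur, 1);
      double d2 = dr * dr + dc * dc;
      if (bi < 0 || d2 < best ||
          (d2 == best && (pts(k, 0) < pts(bi, 0) ||
           (pts(k, 0) == pts(bi, 0) && pts(k, 1) < pts(bi, 1))))) {
        best = d2; bi = k;
      }
    }
    used[bi] = true; ord[step] = bi + 1; cur = bi;
  }
  return ord;
}

// Rasterize a closed polygon of integer (row, col) pixel-centre vertices on an
// nr x nc grid with a pixel-centre-in-polygon rule: even-odd scanline parity
// (half-open rule on each edge's row span) for the interior, plus every pixel
// whose centre lies exactly on a polygon edge; boundary pixels count as
// inside.
// [[Rcpp::export(name = ".fill_polygon_px")]]
LogicalMatrix fill_polygon_px(IntegerMatrix v, int nr, int nc) {
  LogicalMatrix out(nr, nc);
  int n = v.nrow();
  if (n < 1) return out;
  int rmin = v(0, 0), rmax = v(0, 0);
  for (int k = 1; k < n; ++k) {
    rmin = std::min(rmin, v(k, 0)); rmax = std::max(rmax, v(k, 0));
  }
  rmin = std::max(rmin, 0); rmax = std::min(rmax, nr - 1);
  std::vector<double> xs;
  for (int r = rmin; r <= rmax; ++r) {
    xs.clear();
    for (int k = 0; k < n; ++k) {
      int k2 = (k + 1) % n;
      double r1 = v(k, 0), c1 = v(k, 1), r2 = v(k2, 0), c2 = v(k2, 1);
      if (r1 == r2) continue;           // horizontal: boundary pass covers it
      double lo = std::min(r1, r2), hi = std::max(r1, r2);
      if (r < lo || r >= hi) continue;  // half-open [lo, hi)
      xs.push_back(c1 + (r - r1) * (c2 - c1) / (r2 - r1));
    }
    std::sort(xs.begin(), xs.end());
    for (size_t p = 0; p + 1 < xs.size(); p += 2) {
      int ca = (int)std::ceil(xs[p]);
      if ((double)ca == xs[p]) ++ca;    // strict interior; boundary added below
      int cb = (int)std::floor(xs[p + 1]);
      if ((double)cb == xs[p + 1]) --cb;
      ca = std::max(ca, 0); cb = std::min(cb, nc - 1);
      for (int c = ca; c <= cb; ++c) out(r, c) = true;
    }
  }
  // boundary: lattice points exactly on an edge (steps of the direction
  // vector divided by its gcd)
  for (int k = 0; k < n; ++k) {
    int k2 = (k + 1) % n;
    int r0 = v(k, 0), c0 = v(k, 1), r1 = v(k2, 0), c1 = v(k2, 1);
    int dr = r1 - r0, dc = c1 - c0;
    int g = std::abs(dr) > std::abs(dc) ? std::abs(dr) : std::abs(dc);
    int ga = std::abs(dr), gb = std::abs(dc);
    while (gb != 0) { int t = ga % gb; ga = gb; gb = t; }
    g = (ga == 0) ? 1 : ga;
    for (int t = 0; t <= g; ++t) {
      int r = r0 + dr / g * t, c = c0 + dc / g * t;
      if (r >= 0 && r < nr && c >= 0 && c < nc) out(r, c) = true;
    }
  }
  return out;
}

static int orient(long ax, long ay, long bx, long by, long cx, long cy) {
  long v = (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
  return (v > 0) - (v < 0);
}

// True if any two non-adjacent edges of the closed polygon properly cross.
// Touching/collinear contacts are not flagged: pixel-dense chains touch
// constantly without being ill-formed.
// [[Rcpp::export(name = ".path_self_intersects")]]
bool path_self_intersects(IntegerMatrix v) {
  int n = v.nrow();
  if (n < 4) return false;
  for (int a = 0; a < n; ++a) {
    int a2 = (a + 1) % n;
    for (int b = a + 1; b < n; ++b) {
      int b2 = (b + 1) % n;
      if (b == a2 || b2 == a || a == b) continue;  // adjacent edges share a vertex
      long p1x = v(a, 1), p1y = v(a, 0), p2x = v(a2, 1), p2y = v(a2, 0);
      long q1x = v(b, 1), q1y = v(b, 0), q2x = v(b2, 1), q2y = v(b2, 0);
      int o1 = orient(p1x, p1y, p2x, p2y, q1x, q1y);
      int o2 = orient(p1x, p1y, p2x, p2y, q2x, q2y);
      int o3 = orient(q1x, q1y, q2x, q2y, p1x, p1y);
      int o4 = orient(q1x, q1y, q2x, q2y, p2x, p2y);
      if (o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0)
        return true;
    }
  }
  return false;
}
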