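// Exact distance queries: point-to-point-set and grid-accelerated
// point-to-triangle projection. Double precision throughout (these back the
// evaluation metrics and must agree with brute-force oracles to ~1e-12).
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
#include <algorithm>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector nearest_point_dist_cpp(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow(), d = A.ncol();
  if (B.ncol() != d) stop("dimension mismatch");
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = std::numeric_limits<double>::infinity();
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double t = A(i, k) - B(j, k);
        s += t * t;
      }
      if (s < best) best = s;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

struct V3 {
  double x, y, z;
  V3() : x(0), y(0), z(0) {}
  V3(double a, double b, double c) : x(a), y(b), z(c) {}
  V3 operator-(const V3 &o) const { return V3(x - o.x, y - o.y, z - o.z); }
  V3 operator+(const V3 &o) const { return V3(x + o.x, y + o.y, z + o.z); }
  V3 operator*(double s) const { return V3(x * s, y * s, z * s); }
};
static inline double dot(const V3 &a, const V3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline double norm2(const V3 &a) { return dot(a, a); }

// Ericson: closest point on triangle abc to point p.
static V3 closest_point_triangle(const V3 &p, const V3 &a, const V3 &b, const V3 &c) {
  V3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return a;
  V3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    return a + ab * v;
  }
  V3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    return a + ac * w;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return b + (c - b) * w;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return a + ab * v + ac * w;
}

// [[Rcpp::export]]
List point_mesh_project_cpp(NumericMatrix P, NumericMatrix V, IntegerMatrix F0) {
  const int np = P.nrow(), nf = F0.nrow();
  std::vector<V3> verts(V.nrow());
  for (int i = 0; i < V.nrow(); ++i) verts[i] = V3(V(i, 0), V(i, 1), V(i, 2));

  // face centroids + max circumscribed radius (bound for grid pruning)
  std::vector<V3> cent(nf);
  double r_extra = 0.0;
  double lo[3] = {1e300, 1e300, 1e300}, hi[3] = {-1e300, -1e300, -1e300};
  for (int f = 0; f < nf; ++f) {
    V3 a = verts[F0(f, 0)], b = verts[F0(f, 1)], c = verts[F0(f, 2)];
    cent[f] = (a + b + c) * (1.0 / 3.0);
    double r = std::sqrt(std::max(norm2(a - cent[f]),
                         std::max(norm2(b - cent[f]), norm2(c - cent[f]))));
    if (r > r_extra) r_extra = r;
    double cc[3] = {cent[f].x, cent[f].y, cent[f].z};
    for (int k = 0; k < 3; ++k) {
      lo[k] = std::min(lo[k], cc[k]);
      hi[k] = std::max(hi[k], cc[k]);
    }
  }
  double ext = std::max({hi[0] - lo[0], hi[1] - lo[1], hi[2] - lo[2], 1e-9});
  double cell = std::max(ext / 64.0, 1e-6);
  int gx = std::max(1, (int)std::floor((hi[0] - lo[0]) / cell) + 1);
  int gy = std::max(1, (int)std::floor((hi[1] - lo[1]) / cell) + 1);
  int gz = std::max(1, (int)std::floor((hi[2] - lo[2]) / cell) + 1);
  std::vector<std::vector<int>> bins((size_t)gx * gy * gz);
  auto cell_of = [&](const V3 &p, int &ix, int &iy, int &iz) {
    ix = std::min(gx - 1, std::max(0, (int)std::floor((p.x - lo[0]) / cell)));
    iy = std::min(gy - 1, std::max(0, (int)std::floor((p.y - lo[1]) / cell)));
    iz = std::min(gz - 1, std::max(0, (int)std::floor((p.z - lo[2]) / cell)));
  };
  for (int f = 0; f < nf; ++f) {
    int ix, iy, iz;
    cell_of(cent[f], ix, iy, iz);
    bins[((size_t)iz * gy + iy) * gx + ix].push_back(f);
  }
  int max_ring = std::max({gx, gy, gz});

  NumericVector dist(np);
  IntegerVector face(np);
  NumericMatrix point(np, 3);
  for (int i = 0; i < np; ++i) {
    V3 p(P(i, 0), P(i, 1), P(i, 2));
    int ix, iy, iz;
    cell_of(p, ix, iy, iz);
    double best = std::numeric_limits<double>::infinity();
    int best_f = 0;
    V3 best_q;
    for (int ring = 0; ring <= max_ring; ++ring) {
      // distances of any face with centroid outside ring-1 shell are at least
      // (ring-1)*cell - r_extra; stop once that bound exceeds the best found
      if (best < std::numeric_limits<double>::infinity() &&
          best <= (double)(ring - 1) * cell - r_extra) break;
      bool any_cell = false;
      for (int dz = -ring; dz <= ring; ++dz) {
        int z = iz + dz;
        if (z < 0 || z >= gz) continue;
        for (int dy = -ring; dy <= ring; ++dy) {
          int y = iy + dy;
          if (y < 0 || y >= gy) continue;
          for (int dx = -ring; dx <= ring; ++dx) {
            if (std::max({std::abs(dx), std::abs(dy), std::abs(dz)}) != ring) continue;
            int x = ix + dx;
            if (x < 0 || x >= gx) continue;
            any_cell = true;
            const std::vector<int> &fs = bins[((size_t)z * gy + y) * gx + x];
            for (int f : fs) {
              V3 q = closest_point_triangle(p, verts[F0(f, 0)], verts[F0(f, 1)],
                                            verts[F0(f, 2)]);
              double d = std::sqrt(norm2(p - q));
              if (d < best || (d == best && f < best_f)) {
                best = d;
                best_f = f;
                best_q = q;
              }
            }
          }
        }
      }
      if (!any_cell && ring > max_ring) break;
    }
    dist[i] = best;
    face[i] = best_f;
    point(i, 0) = best_q.x;
    point(i, 1) = best_q.y;
    point(i, 2) = best_q.z;
  }
  return List::create(_["dist"] = dist, _["face"] = face, _["point"] = point);
}

// adjacent face pairs across shared undirected edges (1-based output)
// [[Rcpp::export]]
IntegerMatrix face_adjacency_cpp(IntegerMatrix F1, int n_vertices) {
  const int nf = F1.nrow();
  std::vector<std::pair<long long, int>> edges;
  edges.reserve((size_t)nf * 3);
  for (int f = 0; f < nf; ++f) {
    int v[3] = {F1(f, 0), F1(f, 1), F1(f, 2)};
    for (int k = 0; k < 3; ++k) {
      int a = v[k], b = v[(k + 1) % 3];
      if (a > b) std::swap(a, b);
      edges.push_back({(long long)a * (n_vertices + 1) + b, f});
    }
  }
  std::sort(edges.begin(), edges.end());
  std::vector<int> from, to;
  size_t i = 0;
  while (i < edges.size()) {
    size_t j = i;
    while (j < edges.size() && edges[j].first == edges[i].first) ++j;
    for (size_t a = i; a < j; ++a) {
      for (size_t b = a + 1; b < j; ++b) {
        from.push_back(edges[a].second + 1);
        to.push_back(edges[b].second + 1);
      }
    }
    i = j;
  }
  IntegerMatrix out((int)from.size(), 2);
  for (size_t k = 0; k < from.size(); ++k) {
    out((int)k, 0) = std::min(from[k], to[k]);
    out((int)k, 1) = std::max(from[k], to[k]);
  }
  return out;
}
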