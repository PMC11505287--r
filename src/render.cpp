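// Orthographic depth/normal renderer. One sample per pixel center; the
// nearest triangle along the view ray defines the pixel — implemented as a
// z-buffer rasterization over camera-space projected triangles, which is
// exactly the per-pixel first-hit ray cast for an orthographic camera.
// Near-ties (< 1e-5 mm along the ray) resolve to the lower face index.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// [[Rcpp::export]]
List render_raster_cpp(NumericMatrix V, IntegerMatrix F0,
                       NumericVector cam_pos, NumericVector cam_x,
                       NumericVector cam_y, NumericVector cam_z,
                       double half_extent, double depth_range,
                       int H, int W) {
  const int nv = V.nrow(), nf = F0.nrow();
  const double tie_eps = 1e-5;

  // camera-space coordinates: (px, py) in the viewport plane, t = distance
  // along the view ray (camera looks along -cam_z)
  std::vector<double> px(nv), py(nv), pt(nv);
  for (int i = 0; i < nv; ++i) {
    double dx = V(i, 0) - cam_pos[0];
    double dy = V(i, 1) - cam_pos[1];
    double dz = V(i, 2) - cam_pos[2];
    px[i] = dx * cam_x[0] + dy * cam_x[1] + dz * cam_x[2];
    py[i] = dx * cam_y[0] + dy * cam_y[1] + dz * cam_y[2];
    pt[i] = -(dx * cam_z[0] + dy * cam_z[1] + dz * cam_z[2]);
  }

  NumericMatrix depth(H, W);
  NumericVector normal(Dimension(H, W, 3));
  IntegerMatrix first_hit(H, W);      // 0 = background, else 1-based face id
  std::vector<double> tbuf((size_t)H * W,
                           std::numeric_limits<double>::infinity());

  const double pix = 2.0 * half_extent / W;
  const double piy = 2.0 * half_extent / H;

  for (int f = 0; f < nf; ++f) {
    int i0 = F0(f, 0), i1 = F0(f, 1), i2 = F0(f, 2);
    double x0 = px[i0], y0 = py[i0], t0 = pt[i0];
    double x1 = px[i1], y1 = py[i1], t1 = pt[i1];
    double x2 = px[i2], y2 = py[i2], t2 = pt[i2];
    double area2 = (x1 - x0) * (y2 - y0) - (x2 - x0) * (y1 - y0);
    if (std::fabs(area2) < 1e-14) continue;   // edge-on triangle, no pixel area

    double xmin = std::min({x0, x1, x2}), xmax = std::max({x0, x1, x2});
    double ymin = std::min({y0, y1, y2}), ymax = std::max({y0, y1, y2});
    // pixel column j center: -he + (j+0.5)*pix ; row i center: he - (i+0.5)*piy
    int j0 = std::max(0, (int)std::ceil((xmin + half_extent) / pix - 0.5));
    int j1 = std::min(W - 1, (int)std::floor((xmax + half_extent) / pix - 0.5));
    int r1 = std::min(H - 1, (int)std::floor((half_extent - ymin) / piy - 0.5));
    int r0 = std::max(0, (int)std::ceil((half_extent - ymax) / piy - 0.5));
    if (j0 > j1 || r0 > r1) continue;

    double inv = 1.0 / area2;
    for (int r = r0; r <= r1; ++r) {
      double yc = half_extent - (r + 0.5) * piy;
      for (int j = j0; j <= j1; ++j) {
        double xc = -half_extent + (j + 0.5) * pix;
        double w0 = ((x1 - xc) * (y2 - yc) - (x2 - xc) * (y1 - yc)) * inv;
        double w1 = ((x2 - xc) * (y0 - yc) - (x0 - xc) * (y2 - yc)) * inv;
        double w2 = 1.0 - w0 - w1;
        if (w0 < 0 || w1 < 0 || w2 < 0) continue;
        double t = w0 * t0 + w1 * t1 + w2 * t2;
        if (t <= 0) continue;                   // behind the camera plane
        size_t idx = (size_t)j * H + r;         // column-major like R
        if (t < tbuf[idx] - tie_eps) {          // strictly nearer wins;
          tbuf[idx] = t;                        // ascending f => ties keep
          first_hit(r, j) = f + 1;              // the lower face index
        }
      }
    }
  }

  // fill depth + camera-space normals for the winning faces
  std::vector<char> seen(nf, 0);
  for (int j = 0; j < W; ++j) {
    for (int r = 0; r < H; ++r) {
      int f1 = first_hit(r, j);
      if (f1 == 0) continue;
      int f = f1 - 1;
      double t = tbuf[(size_t)j * H + r];
      double dval = 1.0 - t / depth_range;
      if (dval > 1.0) dval = 1.0;
      if (dval <= 0.0) dval = 1e-4;             // clipped to (0, 1]
      depth(r, j) = dval;
      int i0 = F0(f, 0), i1 = F0(f, 1), i2 = F0(f, 2);
      double ax = V(i1, 0) - V(i0, 0), ay = V(i1, 1) - V(i0, 1), az = V(i1, 2) - V(i0, 2);
      double bx = V(i2, 0) - V(i0, 0), by = V(i2, 1) - V(i0, 1), bz = V(i2, 2) - V(i0, 2);
      double nx = ay * bz - az * by, ny = az * bx - ax * bz, nz = ax * by - ay * bx;
      double nl = std::sqrt(nx * nx + ny * ny + nz * nz);
      if (nl > 0) { nx /= nl; ny /= nl; nz /= nl; }
      double cx = nx * cam_x[0] + ny * cam_x[1] + nz * cam_x[2];
      double cy = nx * cam_y[0] + ny * cam_y[1] + nz * cam_y[2];
      double cz = nx * cam_z[0] + ny * cam_z[1] + nz * cam_z[2];
      if (cz < 0) { cx = -cx; cy = -cy; cz = -cz; }  // face the camera
      normal[(size_t)r + (size_t)H * j] = cx;
      normal[(size_t)r + (size_t)H * j + (size_t)H * W] = cy;
      normal[(size_t)r + (size_t)H * j + 2 * (size_t)H * W] = cz;
      seen[f] = 1;
    }
  }
  std::vector<int> vis;
  for (int f = 0; f < nf; ++f) if (seen[f]) vis.push_back(f + 1);
  return List::create(_["depth"] = depth, _["normal"] = normal,
                      _["first_hit"] = first_hit,
                      _["visible_faces"] = IntegerVector(vis.begin(), vis.end()));
}
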