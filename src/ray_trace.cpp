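#include <Rcpp.h>
using namespace Rcpp;

// Ray / triangle-mesh first-hit distances (Moller-Trumbore) with per-face
// AABB pruning against the ray segment [0, t_max]. Origins and directions are
// n x 3; V is the proximal mesh vertex matrix, F its 1-based face index
// matrix. Returns NA where a ray misses every face within t_max.
// [[Rcpp::export]]
NumericVector ray_mesh_hits(NumericMatrix origins, NumericMatrix dirs,
                            NumericMatrix V, IntegerMatrix F,
                            double t_max, double t_min = 1e-9) {
  const int n = origins.nrow(), m = F.nrow();
  NumericVector out(n, NA_REAL);

  // face AABBs
  std::vector<double> lo(3 * m), hi(3 * m);
  for (int f = 0; f < m; ++f) {
    int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
    for (int d = 0; d < 3; ++d) {
      double va = V(a, d), vb = V(b, d), vc = V(c, d);
      double mn = va < vb ? va : vb; if (vc < mn) mn = vc;
      double mx = va > vb ? va : vb; if (vc > mx) mx = vc;
      lo[3 * f + d] = mn;
      hi[3 * f + d] = mx;
    }
  }

  const double eps = 1e-12;
  for (int r = 0; r < n; ++r) {
    double ox = origins(r, 0), oy = origins(r, 1), oz = origins(r, 2);
    double dx = dirs(r, 0), dy = dirs(r, 1), dz = dirs(r, 2);
    if (dx == 0.0 && dy == 0.0 && dz == 0.0) continue;  // zero normal
    // ray segment AABB
    double ex = ox + dx * t_max, ey = oy + dy * t_max, ez = oz + dz * t_max;
    double rlo[3] = { ox < ex ? ox : ex, oy < ey ? oy : ey, oz < ez ? oz : ez };
    double rhi[3] = { ox > ex ? ox : ex, oy > ey ? oy : ey, oz > ez ? oz : ez };
    double best = R_PosInf;
    for (int f = 0; f < m; ++f) {
      if (lo[3 * f] > rhi[0] || hi[3 * f] < rlo[0] ||
          lo[3 * f + 1] > rhi[1] || hi[3 * f + 1] < rlo[1] ||
          lo[3 * f + 2] > rhi[2] || hi[3 * f + 2] < rlo[2]) continue;
      int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
      double e1x = V(b, 0) - V(a, 0), e1y = V(b, 1) - V(a, 1), e1z = V(b, 2) - V(a, 2);
      double e2x = V(c, 0) - V(a, 0), e2y = V(c, 1) - V(a, 1), e2z = V(c, 2) - V(a, 2);
      double px = dy * e2z - dz * e2y;
      double py = dz * e2x - dx * e2z;
      double pz = dx * e2y - dy * e2x;
      double det = e1x * px + e1y * py + e1z * pz;
      if (det > -eps && det < eps) continue;
      double inv = 1.0 / det;
      double tx = ox - V(a, 0), ty = oy - V(a, 1), tz = oz - V(a, 2);
      double u = (tx * px + ty * py + tz * pz) * inv;
      if (u < -1e-9 || u > 1.0 + 1e-9) continue;
      double qx = ty * e1z - tz * e1y;
      double qy = tz * e1x - tx * e1z;
      double qz = tx * e1y - ty * e1x;
      double v = (dx * qx + dy * qy + dz * qz) * inv;
      if (v < -1e-9 || u + v > 1.0 + 1e-9) continue;
      double t = (e2x * qx + e2y * qy + e2z * qz) * inv;
      if (t >= t_min && t <= t_max && t < best) best = t;
    }
    if (R_finite(best)) out[r] = best;
  }
  return out;
}
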