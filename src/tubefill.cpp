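#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Rasterization kernel shared by the phantom generator and the surface
// rasterizer: a voxel belongs to a tube when, relative to the NEAREST
// centerline point, its in-plane radial distance is below the angularly
// interpolated boundary radius of that point. Angles are measured in the
// local (normal, binormal) plane; the radius profile is given per centerline
// point on a regular angular grid starting at angle 0 (the normal axis).
//
// Returns candidate voxels (1-based linear indices), their inside margin
// (boundary radius minus radial distance, > 0 means inside) and the distance
// to the nearest centerline point (used for tie-breaking between fibers).

// [[Rcpp::export(name = ".tube_fill_cpp")]]
List tube_fill_cpp(IntegerVector dims, double voxel_size,
                   NumericMatrix pts, NumericMatrix normals,
                   NumericMatrix binormals, NumericMatrix tangents,
                   NumericMatrix radii, double spacing, bool cap_ends) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int n = pts.nrow();
  const int K = radii.ncol();
  if (normals.nrow() != n || binormals.nrow() != n || tangents.nrow() != n ||
      radii.nrow() != n)
    stop("frame/radius row count must match centerline length");

  double max_r = 0.0;
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k)
      if (radii(i, k) > max_r) max_r = radii(i, k);

  // bounding box in voxel indices (0-based), centre convention (i+0.5)*vs
  double pad = max_r + spacing;
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf}, hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i)
    for (int a = 0; a < 3; ++a) {
      if (pts(i, a) < lo[a]) lo[a] = pts(i, a);
      if (pts(i, a) > hi[a]) hi[a] = pts(i, a);
    }
  int i0[3], i1[3];
  const int dmax[3] = {d1, d2, d3};
  for (int a = 0; a < 3; ++a) {
    i0[a] = std::max(0, (int)std::floor((lo[a] - pad) / voxel_size - 0.5));
    i1[a] = std::min(dmax[a] - 1, (int)std::ceil((hi[a] + pad) / voxel_size - 0.5));
  }

  const double astep = 2.0 * M_PI / K;
  std::vector<double> out_idx, out_margin, out_dist;

  for (int z = i0[2]; z <= i1[2]; ++z) {
    double pz = (z + 0.5) * voxel_size;
    for (int y = i0[1]; y <= i1[1]; ++y) {
      double py = (y + 0.5) * voxel_size;
      for (int x = i0[0]; x <= i1[0]; ++x) {
        double px = (x + 0.5) * voxel_size;
        // nearest centerline point
        int best = -1;
        double bestd2 = (max_r + spacing) * (max_r + spacing);
        for (int i = 0; i < n; ++i) {
          double dx = px - pts(i, 0), dy = py - pts(i, 1), dz = pz - pts(i, 2);
          double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 < bestd2) { bestd2 = d2; best = i; }
        }
        if (best < 0) continue;
        double vx = px - pts(best, 0), vy = py - pts(best, 1), vz = pz - pts(best, 2);
        double t = vx * tangents(best, 0) + vy * tangents(best, 1) + vz * tangents(best, 2);
        if (cap_ends && (best == 0 || best == n - 1) && std::fabs(t) > 0.75 * spacing) {
          // beyond the fiber end
          double out = (best == 0) ? -t : t;
          if (out > 0.75 * spacing) continue;
        }
        double u = vx * normals(best, 0) + vy * normals(best, 1) + vz * normals(best, 2);
        double w = vx * binormals(best, 0) + vy * binormals(best, 1) + vz * binormals(best, 2);
        double rad = std::sqrt(u * u + w * w);
        double theta = std::atan2(w, u);
        if (theta < 0) theta += 2.0 * M_PI;
        double pos = theta / astep;
        int k0 = (int)std::floor(pos) % K;
        int k1 = (k0 + 1) % K;
        double f = pos - std::floor(pos);
        double rb = (1.0 - f) * radii(best, k0) + f * radii(best, k1);
        double margin = rb - rad;
        if (margin <= 0) continue;
        out_idx.push_back((double)x + (double)d1 * ((double)y + (double)d2 * z) + 1.0);
        out_margin.push_back(margin);
        out_dist.push_back(std::sqrt(bestd2));
      }
    }
  }
  return List::create(_["idx"] = NumericVector(out_idx.begin(), out_idx.end()),
                      _["margin"] = NumericVector(out_margin.begin(), out_margin.end()),
                      _["dist"] = NumericVector(out_dist.begin(), out_dist.end()));
}
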