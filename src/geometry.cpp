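#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Moller-Trumbore segment/triangle intersection. Segment p0 -> p1 hits the
// triangle if the intersection parameter t lies in [0, 1] (with a small
// epsilon guard against grazing hits at shared vertices).
static bool segment_hits_triangle(const double* p0, const double* d,
                                  const double* a, const double* b,
                                  const double* c) {
  const double eps = 1e-12;
  double e1[3], e2[3], pv[3], tv[3], qv[3];
  for (int k = 0; k < 3; ++k) {
    e1[k] = b[k] - a[k];
    e2[k] = c[k] - a[k];
  }
  pv[0] = d[1] * e2[2] - d[2] * e2[1];
  pv[1] = d[2] * e2[0] - d[0] * e2[2];
  pv[2] = d[0] * e2[1] - d[1] * e2[0];
  double det = e1[0] * pv[0] + e1[1] * pv[1] + e1[2] * pv[2];
  if (std::fabs(det) < eps) return false;
  double inv = 1.0 / det;
  for (int k = 0; k < 3; ++k) tv[k] = p0[k] - a[k];
  double u = (tv[0] * pv[0] + tv[1] * pv[1] + tv[2] * pv[2]) * inv;
  if (u < -1e-10 || u > 1.0 + 1e-10) return false;
  qv[0] = tv[1] * e1[2] - tv[2] * e1[1];
  qv[1] = tv[2] * e1[0] - tv[0] * e1[2];
  qv[2] = tv[0] * e1[1] - tv[1] * e1[0];
  double v = (d[0] * qv[0] + d[1] * qv[1] + d[2] * qv[2]) * inv;
  if (v < -1e-10 || u + v > 1.0 + 1e-10) return false;
  double t = (e2[0] * qv[0] + e2[1] * qv[1] + e2[2] * qv[2]) * inv;
  return (t > 1e-10 && t < 1.0 - 1e-10);
}

// For each segment p0[i] -> p1[i], report whether it crosses any mesh face.
// [[Rcpp::export]]
LogicalVector cpp_segments_hit_mesh(NumericMatrix p0, NumericMatrix p1,
                                    NumericMatrix V, IntegerMatrix F) {
  int n = p0.nrow(), m = F.nrow();
  LogicalVector out(n);
  std::vector<double> vx(V.nrow()), vy(V.nrow()), vz(V.nrow());
  for (int i = 0; i < V.nrow(); ++i) {
    vx[i] = V(i, 0); vy[i] = V(i, 1); vz[i] = V(i, 2);
  }
  for (int i = 0; i < n; ++i) {
    double s[3] = {p0(i, 0), p0(i, 1), p0(i, 2)};
    double d[3] = {p1(i, 0) - s[0], p1(i, 1) - s[1], p1(i, 2) - s[2]};
    bool hit = false;
    for (int j = 0; j < m && !hit; ++j) {
      int ia = F(j, 0) - 1, ib = F(j, 1) - 1, ic = F(j, 2) - 1;
      double a[3] = {vx[ia], vy[ia], vz[ia]};
      double b[3] = {vx[ib], vy[ib], vz[ib]};
      double c[3] = {vx[ic], vy[ic], vz[ic]};
      hit = segment_hits_triangle(s, d, a, b, c);
    }
    out[i] = hit;
  }
  return out;
}

// Ray-parity inside/outside test for a watertight mesh. Rays are cast along
// a fixed irrational-ish direction to avoid edge/vertex degeneracies.
// [[Rcpp::export]]
LogicalVector cpp_points_in_mesh(NumericMatrix P, NumericMatrix V,
                                 IntegerMatrix F) {
  int n = P.nrow(), m = F.nrow();
  LogicalVector out(n);
  double dir[3] = {0.57735026918962573, 0.26726124191242440,
                   0.77151674981045959};
  const double eps = 1e-12;
  for (int i = 0; i < n; ++i) {
    double o[3] = {P(i, 0), P(i, 1), P(i, 2)};
    int crossings = 0;
    for (int j = 0; j < m; ++j) {
      int ia = F(j, 0) - 1, ib = F(j, 1) - 1, ic = F(j, 2) - 1;
      double a[3] = {V(ia, 0), V(ia, 1), V(ia, 2)};
      double b[3] = {V(ib, 0), V(ib, 1), V(ib, 2)};
      double c[3] = {V(ic, 0), V(ic, 1), V(ic, 2)};
      double e1[3], e2[3], pv[3], tv[3], qv[3];
      for (int k = 0; k < 3; ++k) { e1[k] = b[k] - a[k]; e2[k] = c[k] - a[k]; }
      pv[0] = dir[1] * e2[2] - dir[2] * e2[1];
      pv[1] = dir[2] * e2[0] - dir[0] * e2[2];
      pv[2] = dir[0] * e2[1] - dir[1] * e2[0];
      double det = e1[0] * pv[0] + e1[1] * pv[1] + e1[2] * pv[2];
      if (std::fabs(det) < eps) continue;
      double inv = 1.0 / det;
      for (int k = 0; k < 3; ++k) tv[k] = o[k] - a[k];
      double u = (tv[0] * pv[0] + tv[1] * pv[1] + tv[2] * pv[2]) * inv;
      if (u < 0.0 || u > 1.0) continue;
      qv[0] = tv[1] * e1[2] - tv[2] * e1[1];
      qv[1] = tv[2] * e1[0] - tv[0] * e1[2];
      qv[2] = tv[0] * e1[1] - tv[1] * e1[0];
      double v = (dir[0] * qv[0] + dir[1] * qv[1] + dir[2] * qv[2]) * inv;
      if (v < 0.0 || u + v > 1.0) continue;
      double t = (e2[0] * qv[0] + e2[1] * qv[1] + e2[2] * qv[2]) * inv;
      if (t > eps) ++crossings;
    }
    out[i] = (crossings % 2) == 1;
  }
  return out;
}

// Nearest reference point index (1-based) for each query; ties resolved to
// the lowest index by strict comparison.
// [[Rcpp::export]]
IntegerVector cpp_nn1(NumericMatrix query, NumericMatrix ref) {
  int n = query.nrow(), m = ref.nrow(), d = query.ncol();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int bi = 0;
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = query(i, k) - ref(j, k);
        s += diff * diff;
      }
      if (s < best) { best = s; bi = j; }
    }
    out[i] = bi + 1;
  }
  return out;
}

// k nearest reference indices (1-based, ascending distance) per query row.
// [[Rcpp::export]]
IntegerMatrix cpp_knn(NumericMatrix query, NumericMatrix ref, int k) {
  int n = query.nrow(), m = ref.nrow(), d = query.ncol();
  if (k > m) stop("k exceeds number of reference points");
  IntegerMatrix out(n, k);
  std::vector<std::pair<double, int> > dist(m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int kk = 0; kk < d; ++kk) {
        double diff = query(i, kk) - ref(j, kk);
        s += diff * diff;
      }
      dist[j] = std::make_pair(s, j);
    }
    std::partial_sort(dist.begin(), dist.begin() + k, dist.end());
    for (int j = 0; j < k; ++j) out(i, j) = dist[j].second + 1;
  }
  return out;
}

// Count proper intersections of the segment center -> point[i] with the
// polygon boundary, excluding edges whose endpoints both lie within
// excl_radius of point[i] (the contour point's own neighbourhood) and
// truncating the segment just short of the point itself.
// [[Rcpp::export]]
IntegerVector cpp_center_crossings(NumericVector center, NumericMatrix pts,
                                   NumericMatrix poly, double excl_radius) {
  int n = pts.nrow(), m = poly.nrow();
  IntegerVector out(n);
  double cx = center[0], cy = center[1];
  double er2 = excl_radius * excl_radius;
  for (int i = 0; i < n; ++i) {
    double px = pts(i, 0), py = pts(i, 1);
    double dx = px - cx, dy = py - cy;
    double len = std::sqrt(dx * dx + dy * dy);
    if (len < 1e-9) { out[i] = 0; continue; }
    // pull the segment end back towards the center so the point's own
    // boundary location is never counted
    double shrink = std::min(0.75 * excl_radius / len, 0.45);
    double qx = px - shrink * dx, qy = py - shrink * dy;
    double sx = qx - cx, sy = qy - cy;
    int count = 0;
    for (int j = 0; j < m; ++j) {
      int j2 = (j + 1) % m;
      double ax = poly(j, 0), ay = poly(j, 1);
      double bx = poly(j2, 0), by = poly(j2, 1);
      double da = (ax - px) * (ax - px) + (ay - py) * (ay - py);
      double db = (bx - px) * (bx - px) + (by - py) * (by - py);
      if (da <= er2 && db <= er2) continue;
      double ex = bx - ax, ey = by - ay;
      double denom = sx * ey - sy * ex;
      if (std::fabs(denom) < 1e-12) continue;
      double t = ((ax - cx) * ey - (ay - cy) * ex) / denom;
      double u = ((ax - cx) * sy - (ay - cy) * sx) / denom;
      if (t > 1e-9 && t < 1.0 - 1e-9 && u >= 0.0 && u < 1.0) ++count;
    }
    out[i] = count;
  }
  return out;
}

// Section-based value transfer. For each segment pair (a0->a1, b0->b1)
// values are sampled along a by bilinear interpolation and written to the
// nearest pixel along b; each target pixel accumulates at most 'cap'
// contributions. src channels and accumulators are H x W matrices indexed
// (row, col), coordinates are (x = col, y = row), 1-based.
static inline double bilinear(const NumericMatrix& M, double x, double y) {
  int H = M.nrow(), W = M.ncol();
  double fx = x - 1.0, fy = y - 1.0;  // 0-based
  int x0 = (int)std::floor(fx), y0 = (int)std::floor(fy);
  if (x0 < 0) x0 = 0; if (x0 > W - 2) x0 = W - 2;
  if (y0 < 0) y0 = 0; if (y0 > H - 2) y0 = H - 2;
  double tx = fx - x0, ty = fy - y0;
  if (tx < 0) tx = 0; if (tx > 1) tx = 1;
  if (ty < 0) ty = 0; if (ty > 1) ty = 1;
  double v00 = M(y0, x0), v10 = M(y0, x0 + 1);
  double v01 = M(y0 + 1, x0), v11 = M(y0 + 1, x0 + 1);
  return v00 * (1 - tx) * (1 - ty) + v10 * tx * (1 - ty) +
         v01 * (1 - tx) * ty + v11 * tx * ty;
}

// [[Rcpp::export]]
List cpp_map_segments(List src_channels, NumericMatrix a0, NumericMatrix a1,
                      NumericMatrix b0, NumericMatrix b1,
                      IntegerMatrix target_mask, int cap,
                      double oversample) {
  int nc = src_channels.size();
  std::vector<NumericMatrix> src(nc);
  for (int c = 0; c < nc; ++c) src[c] = as<NumericMatrix>(src_channels[c]);
  int H = target_mask.nrow(), W = target_mask.ncol();
  int nseg = a0.nrow();
  List sums(nc);
  std::vector<NumericMatrix> sum(nc);
  for (int c = 0; c < nc; ++c) {
    sum[c] = NumericMatrix(H, W);
    sums[c] = sum[c];
  }
  IntegerMatrix count(H, W);
  for (int s = 0; s < nseg; ++s) {
    double ax0 = a0(s, 0), ay0 = a0(s, 1), ax1 = a1(s, 0), ay1 = a1(s, 1);
    double bx0 = b0(s, 0), by0 = b0(s, 1), bx1 = b1(s, 0), by1 = b1(s, 1);
    double la = std::hypot(ax1 - ax0, ay1 - ay0);
    double lb = std::hypot(bx1 - bx0, by1 - by0);
    double lb2 = lb * lb;
    int nsamp = (int)std::ceil(oversample * std::max(la, lb)) + 1;
    if (nsamp < 2) nsamp = 2;
    int prev_r = -1, prev_c = -1;
    for (int q = 0; q < nsamp; ++q) {
      double t = (double)q / (double)(nsamp - 1);
      double tx = bx0 + t * (bx1 - bx0);
      double ty = by0 + t * (by1 - by0);
      int col = (int)std::lround(tx) - 1;
      int row = (int)std::lround(ty) - 1;
      if (row < 0 || row >= H || col < 0 || col >= W) continue;
      if (row == prev_r && col == prev_c) continue;  // one hit per pixel pass
      prev_r = row; prev_c = col;
      if (target_mask(row, col) == 0) continue;
      if (count(row, col) >= cap) continue;
      // arc-length reparameterization anchored at the pixel actually
      // written: project the pixel center onto the target segment and
      // sample the source segment at the same relative position
      double tp = t;
      if (lb2 > 1e-12) {
        tp = (((double)(col + 1) - bx0) * (bx1 - bx0) +
              ((double)(row + 1) - by0) * (by1 - by0)) / lb2;
        if (tp < 0.0) tp = 0.0;
        if (tp > 1.0) tp = 1.0;
      }
      double sx = ax0 + tp * (ax1 - ax0);
      double sy = ay0 + tp * (ay1 - ay0);
      for (int c = 0; c < nc; ++c)
        sum[c](row, col) += bilinear(src[c], sx, sy);
      count(row, col) += 1;
    }
  }
  return List::create(_["sums"] = sums, _["count"] = count);
}
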