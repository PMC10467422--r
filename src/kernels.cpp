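#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Index helpers: volumes are stored in R's column-major order, dim = (nx, ny, nz).
static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// boundary: 0 = symmetric half-sample reflection, 1 = nearest (replicate), 2 = periodic
static inline int reflect_index(int i, int n, int boundary) {
  if (boundary == 2) {
    i %= n; if (i < 0) i += n;
    return i;
  }
  if (boundary == 1) {
    if (i < 0) return 0;
    if (i >= n) return n - 1;
    return i;
  }
  // symmetric: ... x1 x0 | x0 x1 ... xN-1 | xN-1 ...
  while (i < 0 || i >= n) {
    if (i < 0) i = -1 - i;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// Cross-correlation along one axis: out[n] = sum_k h[k] * x[n - origin + k]
// axis: 0 = x, 1 = y, 2 = z (R's first, second, third array index)
// [[Rcpp::export]]
NumericVector conv_axis_cpp(NumericVector vol, IntegerVector dim,
                            NumericVector kernel, int origin, int axis,
                            int boundary) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int nk = kernel.size();
  NumericVector out(vol.size());
  int n = dim[axis];
  std::vector<double> line(n), res(n);
  int n1, n2; // the two non-filtered axes
  if (axis == 0)      { n1 = ny; n2 = nz; }
  else if (axis == 1) { n1 = nx; n2 = nz; }
  else                { n1 = nx; n2 = ny; }
  for (int b = 0; b < n2; ++b) {
    for (int a = 0; a < n1; ++a) {
      for (int i = 0; i < n; ++i) {
        int id;
        if (axis == 0)      id = idx3(i, a, b, nx, ny);
        else if (axis == 1) id = idx3(a, i, b, nx, ny);
        else                id = idx3(a, b, i, nx, ny);
        line[i] = vol[id];
      }
      int lo = origin, hi = n - (nk - 1 - origin); // interior: no reflection
      if (lo > n) lo = n;
      if (hi < lo) hi = lo;
      for (int i = 0; i < lo; ++i) {
        double s = 0.0;
        for (int k = 0; k < nk; ++k)
          s += kernel[k] * line[reflect_index(i - origin + k, n, boundary)];
        res[i] = s;
      }
      for (int i = lo; i < hi; ++i) {
        double s = 0.0;
        const double *lp = &line[i - origin];
        for (int k = 0; k < nk; ++k) s += kernel[k] * lp[k];
        res[i] = s;
      }
      for (int i = hi; i < n; ++i) {
        double s = 0.0;
        for (int k = 0; k < nk; ++k)
          s += kernel[k] * line[reflect_index(i - origin + k, n, boundary)];
        res[i] = s;
      }
      for (int i = 0; i < n; ++i) {
        int id;
        if (axis == 0)      id = idx3(i, a, b, nx, ny);
        else if (axis == 1) id = idx3(a, i, b, nx, ny);
        else                id = idx3(a, b, i, nx, ny);
        out[id] = res[i];
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// One decimated analysis step along an axis with periodic (circular) boundary:
// out[m] = sum_k h[k] * x[(2m + k) mod n].  n must be even; output axis length n/2.
// [[Rcpp::export]]
NumericVector dwt_axis_cpp(NumericVector vol, IntegerVector dim,
                           NumericVector kernel, int axis) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = dim[axis];
  if (n % 2 != 0) stop("axis length must be even for the decimated transform");
  int m = n / 2, nk = kernel.size();
  IntegerVector odim = clone(dim);
  odim[axis] = m;
  NumericVector out((double)odim[0] * odim[1] * odim[2]);
  int n1, n2;
  if (axis == 0)      { n1 = ny; n2 = nz; }
  else if (axis == 1) { n1 = nx; n2 = nz; }
  else                { n1 = nx; n2 = ny; }
  std::vector<double> line(n);
  for (int b = 0; b < n2; ++b) {
    for (int a = 0; a < n1; ++a) {
      for (int i = 0; i < n; ++i) {
        int id;
        if (axis == 0)      id = idx3(i, a, b, nx, ny);
        else if (axis == 1) id = idx3(a, i, b, nx, ny);
        else                id = idx3(a, b, i, nx, ny);
        line[i] = vol[id];
      }
      for (int o = 0; o < m; ++o) {
        double s = 0.0;
        for (int k = 0; k < nk; ++k) s += kernel[k] * line[(2 * o + k) % n];
        int id;
        if (axis == 0)      id = idx3(o, a, b, odim[0], odim[1]);
        else if (axis == 1) id = idx3(a, o, b, odim[0], odim[1]);
        else                id = idx3(a, b, o, odim[0], odim[1]);
        out[id] = s;
      }
    }
  }
  out.attr("dim") = odim;
  return out;
}

// Gray-level co-occurrence counts. levels: 0 outside the region, 1..ng inside.
// offsets: n_dir x 3 integer matrix. Returns ng x ng x n_dir raw (unsymmetrized) counts.
// [[Rcpp::export]]
NumericVector glcm_cpp(IntegerVector levels, IntegerVector dim,
                       IntegerMatrix offsets, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int nd = offsets.nrow();
  NumericVector out((double)ng * ng * nd);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int l1 = levels[idx3(x, y, z, nx, ny)];
        if (l1 <= 0) continue;
        for (int d = 0; d < nd; ++d) {
          int x2 = x + offsets(d, 0), y2 = y + offsets(d, 1), z2 = z + offsets(d, 2);
          if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz) continue;
          int l2 = levels[idx3(x2, y2, z2, nx, ny)];
          if (l2 <= 0) continue;
          out[(l1 - 1) + ng * ((l2 - 1) + ng * d)] += 1.0;
        }
      }
  out.attr("dim") = IntegerVector::create(ng, ng, nd);
  return out;
}

// Gray-level run-length counts per direction. Returns ng x maxrun x n_dir.
// [[Rcpp::export]]
NumericVector glrlm_cpp(IntegerVector levels, IntegerVector dim,
                        IntegerMatrix offsets, int ng, int maxrun) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int nd = offsets.nrow();
  NumericVector out((double)ng * maxrun * nd);
  for (int d = 0; d < nd; ++d) {
    int ox = offsets(d, 0), oy = offsets(d, 1), oz = offsets(d, 2);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int l = levels[idx3(x, y, z, nx, ny)];
          if (l <= 0) continue;
          // run start: predecessor out of bounds or different level
          int xp = x - ox, yp = y - oy, zp = z - oz;
          bool start = true;
          if (xp >= 0 && xp < nx && yp >= 0 && yp < ny && zp >= 0 && zp < nz)
            if (levels[idx3(xp, yp, zp, nx, ny)] == l) start = false;
          if (!start) continue;
          int len = 1;
          int xn = x + ox, yn = y + oy, zn = z + oz;
          while (xn >= 0 && xn < nx && yn >= 0 && yn < ny && zn >= 0 && zn < nz &&
                 levels[idx3(xn, yn, zn, nx, ny)] == l) {
            ++len; xn += ox; yn += oy; zn += oz;
          }
          if (len > maxrun) len = maxrun;
          out[(l - 1) + ng * ((len - 1) + maxrun * d)] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(ng, maxrun, nd);
  return out;
}

// 26-connected zones of constant gray level. Returns n_zones x 2 (level, size).
// [[Rcpp::export]]
IntegerMatrix glszm_zones_cpp(IntegerVector levels, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> zl, zs, stack;
  for (int start = 0; start < n; ++start) {
    if (seen[start] || levels[start] <= 0) continue;
    int l = levels[start];
    int size = 0;
    stack.clear();
    stack.push_back(start);
    seen[start] = 1;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      ++size;
      int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int x2 = x + dx, y2 = y + dy, z2 = z + dz;
            if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz) continue;
            int w = idx3(x2, y2, z2, nx, ny);
            if (!seen[w] && levels[w] == l) { seen[w] = 1; stack.push_back(w); }
          }
    }
    zl.push_back(l); zs.push_back(size);
  }
  IntegerMatrix out(zl.size(), 2);
  for (size_t i = 0; i < zl.size(); ++i) { out(i, 0) = zl[i]; out(i, 1) = zs[i]; }
  return out;
}

// Gray-level dependence counts: dependence = number of 26-neighbours inside the
// region with |level difference| <= alpha. Returns ng x 27 (dependence 0..26).
// [[Rcpp::export]]
NumericMatrix gldm_cpp(IntegerVector levels, IntegerVector dim, int alpha) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int ng = 0;
  for (int i = 0; i < levels.size(); ++i) if (levels[i] > ng) ng = levels[i];
  NumericMatrix out(ng, 27);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int l = levels[idx3(x, y, z, nx, ny)];
        if (l <= 0) continue;
        int dep = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz) continue;
              int l2 = levels[idx3(x2, y2, z2, nx, ny)];
              if (l2 > 0 && std::abs(l2 - l) <= alpha) ++dep;
            }
        out(l - 1, dep) += 1.0;
      }
  return out;
}

// Neighbourhood gray-tone difference sums: for each level, the voxel count n_i
// and the summed absolute difference s_i from the mean of valid 26-neighbours.
// Voxels without any in-region neighbour contribute to n_i with s contribution 0.
// [[Rcpp::export]]
NumericMatrix ngtdm_cpp(IntegerVector levels, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(ng, 2); // columns: n_i, s_i
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int l = levels[idx3(x, y, z, nx, ny)];
        if (l <= 0) continue;
        double sum = 0.0; int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz) continue;
              int l2 = levels[idx3(x2, y2, z2, nx, ny)];
              if (l2 > 0) { sum += l2; ++cnt; }
            }
        out(l - 1, 0) += 1.0;
        if (cnt > 0) out(l - 1, 1) += std::fabs((double)l - sum / cnt);
      }
  return out;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher), helper.
static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 double step, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -INFINITY; z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      double qq = (double)q * step, vv = (double)v[k] * step;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2 * qq - 2 * vv);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q; z[k] = s; z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qq = (double)q * step;
    while (z[k + 1] < qq) ++k;
    double vv = (double)v[k] * step;
    d[q] = (qq - vv) * (qq - vv) + f[v[k]];
  }
}

// Squared Euclidean distance (in mm) from every voxel to the nearest zero voxel.
// [[Rcpp::export]]
NumericVector edt_sq_cpp(IntegerVector mask, IntegerVector dim,
                         NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  const double BIG = 1e30;
  NumericVector g(n);
  for (int i = 0; i < n; ++i) g[i] = mask[i] ? BIG : 0.0;
  // pass along each axis
  for (int axis = 0; axis < 3; ++axis) {
    int len = dim[axis];
    double step = spacing[axis];
    std::vector<double> f(len), d(len);
    int n1, n2;
    if (axis == 0)      { n1 = ny; n2 = nz; }
    else if (axis == 1) { n1 = nx; n2 = nz; }
    else                { n1 = nx; n2 = ny; }
    for (int b = 0; b < n2; ++b)
      for (int a = 0; a < n1; ++a) {
        for (int i = 0; i < len; ++i) {
          int id;
          if (axis == 0)      id = idx3(i, a, b, nx, ny);
          else if (axis == 1) id = idx3(a, i, b, nx, ny);
          else                id = idx3(a, b, i, nx, ny);
          f[i] = g[id];
        }
        dt1d(f, d, step, len);
        for (int i = 0; i < len; ++i) {
          int id;
          if (axis == 0)      id = idx3(i, a, b, nx, ny);
          else if (axis == 1) id = idx3(a, i, b, nx, ny);
          else                id = idx3(a, b, i, nx, ny);
          g[id] = d[i];
        }
      }
  }
  g.attr("dim") = dim;
  return g;
}

// ---- marching tetrahedra ------------------------------------------------

struct Vec3 { double x, y, z; };
static inline Vec3 vsub(const Vec3 &a, const Vec3 &b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
static inline Vec3 vcross(const Vec3 &a, const Vec3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double vdot(const Vec3 &a, const Vec3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline Vec3 lerp(const Vec3 &a, const Vec3 &b, double fa, double fb, double iso) {
  double t = (iso - fa) / (fb - fa);
  return {a.x + t * (b.x - a.x), a.y + t * (b.y - a.y), a.z + t * (b.z - a.z)};
}

// Accumulate an oriented triangle: normal must point away from the inside
// reference point r (outward). Adds to area and signed-volume accumulators.
static void add_tri(Vec3 p0, Vec3 p1, Vec3 p2, const Vec3 &r,
                    double &area, double &svol) {
  Vec3 n = vcross(vsub(p1, p0), vsub(p2, p0));
  if (vdot(n, vsub(p0, r)) < 0) { Vec3 t = p1; p1 = p2; p2 = t; n = vcross(vsub(p1, p0), vsub(p2, p0)); }
  double a2 = std::sqrt(vdot(n, n));
  area += 0.5 * a2;
  svol += vdot(p0, vcross(p1, p2)) / 6.0;
}

// Surface area (mm^2) and enclosed volume (mm^3) of the iso-surface of a scalar
// field, by marching tetrahedra with linear edge interpolation. The field must
// be below iso on its entire outer border so the surface closes.
// [[Rcpp::export]]
NumericVector mesh_area_volume_cpp(NumericVector field, IntegerVector dim,
                                   NumericVector spacing, double iso) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  // cube corner offsets, bit order chosen so v0-v6 is the shared diagonal
  static const int cx[8] = {0, 1, 1, 0, 0, 1, 1, 0};
  static const int cy[8] = {0, 0, 1, 1, 0, 0, 1, 1};
  static const int cz[8] = {0, 0, 0, 0, 1, 1, 1, 1};
  static const int tets[6][4] = {
    {0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6}, {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}
  };
  double area = 0.0, svol = 0.0;
  double fv[8];
  Vec3 pv[8];
  for (int z = 0; z + 1 < nz; ++z)
    for (int y = 0; y + 1 < ny; ++y)
      for (int x = 0; x + 1 < nx; ++x) {
        bool anyin = false, anyout = false;
        for (int c = 0; c < 8; ++c) {
          fv[c] = field[idx3(x + cx[c], y + cy[c], z + cz[c], nx, ny)];
          pv[c] = {(x + cx[c]) * sx, (y + cy[c]) * sy, (z + cz[c]) * sz};
          if (fv[c] > iso) anyin = true; else anyout = true;
        }
        if (!anyin || !anyout) continue;
        for (int t = 0; t < 6; ++t) {
          int a = tets[t][0], b = tets[t][1], c = tets[t][2], d = tets[t][3];
          int vi[4] = {a, b, c, d};
          int in[4], nin = 0;
          for (int q = 0; q < 4; ++q) if (fv[vi[q]] > iso) in[nin++] = q;
          if (nin == 0 || nin == 4) continue;
          if (nin == 1 || nin == 3) {
            // apex: the lone inside (nin==1) or lone outside (nin==3) vertex
            int lone = -1;
            for (int q = 0; q < 4; ++q) {
              bool isin = fv[vi[q]] > iso;
              if ((nin == 1 && isin) || (nin == 3 && !isin)) lone = q;
            }
            int o[3], no = 0;
            for (int q = 0; q < 4; ++q) if (q != lone) o[no++] = q;
            Vec3 q1 = lerp(pv[vi[lone]], pv[vi[o[0]]], fv[vi[lone]], fv[vi[o[0]]], iso);
            Vec3 q2 = lerp(pv[vi[lone]], pv[vi[o[1]]], fv[vi[lone]], fv[vi[o[1]]], iso);
            Vec3 q3 = lerp(pv[vi[lone]], pv[vi[o[2]]], fv[vi[lone]], fv[vi[o[2]]], iso);
            // reference inside point
            Vec3 r = (nin == 1) ? pv[vi[lone]] : pv[vi[o[0]]];
            add_tri(q1, q2, q3, r, area, svol);
          } else { // nin == 2
            int i1 = in[0], i2 = in[1];
            int o[2], no = 0;
            for (int q = 0; q < 4; ++q) if (q != i1 && q != i2) o[no++] = q;
            Vec3 qA = lerp(pv[vi[i1]], pv[vi[o[0]]], fv[vi[i1]], fv[vi[o[0]]], iso);
            Vec3 qB = lerp(pv[vi[i1]], pv[vi[o[1]]], fv[vi[i1]], fv[vi[o[1]]], iso);
            Vec3 qC = lerp(pv[vi[i2]], pv[vi[o[1]]], fv[vi[i2]], fv[vi[o[1]]], iso);
            Vec3 qD = lerp(pv[vi[i2]], pv[vi[o[0]]], fv[vi[i2]], fv[vi[o[0]]], iso);
            Vec3 r = {(pv[vi[i1]].x + pv[vi[i2]].x) / 2, (pv[vi[i1]].y + pv[vi[i2]].y) / 2,
                      (pv[vi[i1]].z + pv[vi[i2]].z) / 2};
            add_tri(qA, qB, qC, r, area, svol);
            add_tri(qA, qC, qD, r, area, svol);
          }
        }
      }
  return NumericVector::create(area, std::fabs(svol));
}

// Maximum pairwise Euclidean distance among points (rows of an n x 3 matrix).
// [[Rcpp::export]]
double max_pairwise_dist_cpp(NumericMatrix pts) {
  int n = pts.nrow();
  double best = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = pts(i, 0) - pts(j, 0);
      double dy = pts(i, 1) - pts(j, 1);
      double dz = pts(i, 2) - pts(j, 2);
      double d = dx * dx + dy * dy + dz * dz;
      if (d > best) best = d;
    }
  return std::sqrt(best);
}

// --- B-spline axis resampling ---------------------------------------------

static inline int mirror_whole(int i, int n) {
  if (n == 1) return 0;
  int p = 2 * (n - 1);
  i %= p; if (i < 0) i += p;
  return (i >= n) ? p - i : i;
}

static inline double bspline3_w(double x) {
  double ax = std::fabs(x);
  if (ax < 1.0) return 2.0 / 3.0 - ax * ax + ax * ax * ax / 2.0;
  if (ax < 2.0) { double t = 2.0 - ax; return t * t * t / 6.0; }
  return 0.0;
}

// Resample one axis from spacing s_in to s_out. degree 3: cubic B-spline with
// whole-point mirror boundary (prefilter = tridiagonal solve of the folded
// interpolation system); degree 1: linear. Output length preserves the
// physical extent to within one voxel.
// [[Rcpp::export]]
NumericVector resample_axis_cpp(NumericVector vol, IntegerVector dim, int axis,
                                double s_in, double s_out, int degree) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = dim[axis];
  int n_out = (int)std::floor((n - 1) * s_in / s_out + 1e-9) + 1;
  IntegerVector odim = clone(dim);
  odim[axis] = n_out;
  NumericVector out((double)odim[0] * odim[1] * odim[2]);
  int n1, n2;
  if (axis == 0)      { n1 = ny; n2 = nz; }
  else if (axis == 1) { n1 = nx; n2 = nz; }
  else                { n1 = nx; n2 = ny; }
  std::vector<double> line(n), coef(n), cp(n), dp(n);
  // precompute output positions and weights
  std::vector<double> t_out(n_out);
  for (int o = 0; o < n_out; ++o) t_out[o] = o * s_out / s_in;
  for (int b = 0; b < n2; ++b)
    for (int a = 0; a < n1; ++a) {
      for (int i = 0; i < n; ++i) {
        int id;
        if (axis == 0)      id = idx3(i, a, b, nx, ny);
        else if (axis == 1) id = idx3(a, i, b, nx, ny);
        else                id = idx3(a, b, i, nx, ny);
        line[i] = vol[id];
      }
      if (degree == 3 && n > 1) {
        // folded tridiagonal system: interior rows (1/6, 2/3, 1/6),
        // first/last rows (2/3, 1/3) by whole-point mirror
        const double dlo = 1.0 / 6.0, dmid = 2.0 / 3.0;
        // Thomas algorithm
        double b0 = dmid, c0 = (n > 1) ? 2.0 * dlo : 0.0;
        cp[0] = c0 / b0; dp[0] = line[0] / b0;
        for (int i = 1; i < n; ++i) {
          double ai = dlo, bi = dmid, ci = dlo;
          if (i == n - 1) { ai = 2.0 * dlo; ci = 0.0; }
          double mden = bi - ai * cp[i - 1];
          cp[i] = ci / mden;
          dp[i] = (line[i] - ai * dp[i - 1]) / mden;
        }
        coef[n - 1] = dp[n - 1];
        for (int i = n - 2; i >= 0; --i) coef[i] = dp[i] - cp[i] * coef[i + 1];
      } else {
        for (int i = 0; i < n; ++i) coef[i] = line[i];
      }
      for (int o = 0; o < n_out; ++o) {
        double t = t_out[o];
        double s = 0.0;
        if (degree == 3 && n > 1) {
          int base = (int)std::floor(t);
          for (int k = base - 1; k <= base + 2; ++k) {
            double w = bspline3_w(t - k);
            if (w > 0) s += w * coef[mirror_whole(k, n)];
          }
        } else {
          int base = (int)std::floor(t);
          double fr = t - base;
          int i0 = mirror_whole(base, n), i1 = mirror_whole(base + 1, n);
          s = (1 - fr) * coef[i0] + fr * coef[i1];
        }
        int id;
        if (axis == 0)      id = idx3(o, a, b, odim[0], odim[1]);
        else if (axis == 1) id = idx3(a, o, b, odim[0], odim[1]);
        else                id = idx3(a, b, o, odim[0], odim[1]);
        out[id] = s;
      }
    }
  out.attr("dim") = odim;
  return out;
}
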