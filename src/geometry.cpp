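// Voxel-lattice kernels: exact Euclidean distance transforms, trilinear
// field sampling along segments, cylinder rasterization, 6-connected flood
// fill, hemisphere accessibility rays and line-of-sight compactness sums.
// All grids are isotropic, column-major (R array layout), voxel-center world
// convention: world = origin + index * spacing, 0-based indices internally.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// ---- Felzenszwalb–Huttenlocher 1-D squared distance transform ------------
// d[q] = min_p ( (q-p)^2 + f[p] ), exact lower envelope of parabolas.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[k]] == INF) { // no finite parabola yet
      v[k] = q; z[k] = -INF; z[k + 1] = INF; continue;
    }
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    if (f[v[0]] == INF) { d[q] = INF; continue; }
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// squared EDT (voxel units) to the seed set, in place on D
static void edt3d_sq(std::vector<double>& D, int nx, int ny, int nz) {
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      size_t base = (size_t)nx * (j + (size_t)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = D[base + i];
      dt1d(f, d, v, z, nx);
      for (int i = 0; i < nx; ++i) D[base + i] = d[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      size_t base = i + (size_t)nx * (size_t)ny * k;
      for (int j = 0; j < ny; ++j) f[j] = D[base + (size_t)nx * j];
      dt1d(f, d, v, z, ny);
      for (int j = 0; j < ny; ++j) D[base + (size_t)nx * j] = d[j];
    }
  // pass along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      size_t base = i + (size_t)nx * j;
      size_t stride = (size_t)nx * ny;
      for (int k = 0; k < nz; ++k) f[k] = D[base + stride * k];
      dt1d(f, d, v, z, nz);
      for (int k = 0; k < nz; ++k) D[base + stride * k] = d[k];
    }
}

// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector seed, IntegerVector dims, double spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<double> D(n);
  for (size_t i = 0; i < n; ++i) D[i] = seed[i] ? 0.0 : INF;
  edt3d_sq(D, nx, ny, nz);
  NumericVector out(n);
  for (size_t i = 0; i < n; ++i)
    out[i] = (D[i] == INF) ? R_PosInf : spacing * std::sqrt(D[i]);
  return out;
}

// Signed distance field with the half-voxel boundary convention:
//   outside: d(occupied voxels) - spacing/2   (strictly > 0)
//   inside: -(d(background voxels) - spacing/2) (strictly < 0)
// so |sdf| tracks nearest-surface-voxel distance within half a voxel.
// [[Rcpp::export]]
NumericVector cpp_sdf3d(LogicalVector mask, IntegerVector dims, double spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<double> Dout(n), Din(n);
  for (size_t i = 0; i < n; ++i) {
    Dout[i] = mask[i] ? 0.0 : INF;
    Din[i]  = mask[i] ? INF : 0.0;
  }
  edt3d_sq(Dout, nx, ny, nz);
  edt3d_sq(Din, nx, ny, nz);
  NumericVector out(n);
  double h = spacing / 2.0;
  for (size_t i = 0; i < n; ++i) {
    if (mask[i]) out[i] = -(spacing * std::sqrt(Din[i]) - h);
    else         out[i] =   spacing * std::sqrt(Dout[i]) - h;
  }
  return out;
}

// ---- trilinear sampling --------------------------------------------------
static inline double trilin(const double* F, int nx, int ny, int nz,
                            double x, double y, double z) {
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 < 0) i0 = 0; if (j0 < 0) j0 = 0; if (k0 < 0) k0 = 0;
  if (i0 > nx - 2) i0 = nx - 2;
  if (j0 > ny - 2) j0 = ny - 2;
  if (k0 > nz - 2) k0 = nz - 2;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  size_t sxy = (size_t)nx * ny;
  const double* p = F + i0 + (size_t)nx * j0 + sxy * k0;
  double c00 = p[0] * (1 - fx) + p[1] * fx;
  double c10 = p[nx] * (1 - fx) + p[nx + 1] * fx;
  double c01 = p[sxy] * (1 - fx) + p[sxy + 1] * fx;
  double c11 = p[sxy + nx] * (1 - fx) + p[sxy + nx + 1] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

static inline double nearestv(const double* F, int nx, int ny, int nz,
                              double x, double y, double z) {
  int i = (int)std::lround(x), j = (int)std::lround(y), k = (int)std::lround(z);
  if (i < 0) i = 0; if (j < 0) j = 0; if (k < 0) k = 0;
  if (i > nx - 1) i = nx - 1;
  if (j > ny - 1) j = ny - 1;
  if (k > nz - 1) k = nz - 1;
  return F[i + (size_t)nx * j + (size_t)nx * ny * k];
}

// Minimum of the (trilinearly or nearest-voxel) interpolated field over
// samples spaced <= step_mm along each segment [p0_i, p1_i] (world mm).
// Errors if any sample leaves the voxel-center hull.
// [[Rcpp::export]]
NumericVector cpp_segment_min(NumericVector field, IntegerVector dims,
                              NumericVector origin, double spacing,
                              NumericMatrix p0, NumericMatrix p1,
                              double step_mm, bool nearest) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const double* F = REAL(field);
  int m = p0.nrow();
  NumericVector out(m);
  for (int s = 0; s < m; ++s) {
    double ax = p0(s, 0), ay = p0(s, 1), az = p0(s, 2);
    double bx = p1(s, 0), by = p1(s, 1), bz = p1(s, 2);
    double len = std::sqrt((bx - ax) * (bx - ax) + (by - ay) * (by - ay) +
                           (bz - az) * (bz - az));
    int nstep = std::max(1, (int)std::ceil(len / step_mm));
    double best = INF;
    for (int q = 0; q <= nstep; ++q) {
      double u = (double)q / nstep;
      double x = (ax + u * (bx - ax) - origin[0]) / spacing;
      double y = (ay + u * (by - ay) - origin[1]) / spacing;
      double z = (az + u * (bz - az) - origin[2]) / spacing;
      if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
        stop("segment sample outside grid bounds; pad the grid before querying");
      double v = nearest ? nearestv(F, nx, ny, nz, x, y, z)
                         : trilin(F, nx, ny, nz, x, y, z);
      if (v < best) best = v;
    }
    out[s] = best;
  }
  return out;
}

// Open finite cylinder: voxel centers within r of the line through k,t and
// strictly between the end planes (both dot products > 0). 1-based indices.
// [[Rcpp::export]]
IntegerVector cpp_rasterize_cylinder(IntegerVector dims, NumericVector origin,
                                     double spacing, NumericVector k,
                                     NumericVector t, double r) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double kx = k[0], ky = k[1], kz = k[2];
  double tx = t[0], ty = t[1], tz = t[2];
  double ux = tx - kx, uy = ty - ky, uz = tz - kz;
  double L2 = ux * ux + uy * uy + uz * uz;
  // world bounding box of the capsule around the segment
  double pad = r;
  double lo[3] = { std::min(kx, tx) - pad, std::min(ky, ty) - pad, std::min(kz, tz) - pad };
  double hi[3] = { std::max(kx, tx) + pad, std::max(ky, ty) + pad, std::max(kz, tz) + pad };
  int ilo[3], ihi[3];
  for (int a = 0; a < 3; ++a) {
    ilo[a] = std::max(0, (int)std::ceil((lo[a] - origin[a]) / spacing));
    int nmax = (a == 0 ? nx : (a == 1 ? ny : nz)) - 1;
    ihi[a] = std::min(nmax, (int)std::floor((hi[a] - origin[a]) / spacing));
  }
  std::vector<int> idx;
  double r2 = r * r;
  for (int kk = ilo[2]; kk <= ihi[2]; ++kk)
    for (int jj = ilo[1]; jj <= ihi[1]; ++jj)
      for (int ii = ilo[0]; ii <= ihi[0]; ++ii) {
        double sx = origin[0] + ii * spacing;
        double sy = origin[1] + jj * spacing;
        double sz = origin[2] + kk * spacing;
        double wx = sx - kx, wy = sy - ky, wz = sz - kz;
        double dot = wx * ux + wy * uy + wz * uz; // ks . kt
        if (dot <= 0 || dot >= L2) continue;      // ts . tk > 0 <=> dot < L2
        // squared distance to the line
        double cx = wy * uz - wz * uy;
        double cy = wz * ux - wx * uz;
        double cz = wx * uy - wy * ux;
        double d2 = (cx * cx + cy * cy + cz * cz) / L2;
        if (d2 < r2)
          idx.push_back(1 + ii + nx * jj + nx * ny * kk);
      }
  return wrap(idx);
}

// 6-connected BFS through `open` voxels starting from open seed voxels.
// [[Rcpp::export]]
LogicalVector cpp_flood_fill(LogicalVector open, LogicalVector seeds,
                             IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<char> vis(n, 0);
  std::vector<int> stack;
  stack.reserve(n / 8);
  for (size_t i = 0; i < n; ++i)
    if (seeds[i] && open[i] && !vis[i]) { vis[i] = 1; stack.push_back((int)i); }
  size_t sxy = (size_t)nx * ny;
  while (!stack.empty()) {
    int c = stack.back();
    stack.pop_back();
    int k = c / (int)sxy, rem = c % (int)sxy, j = rem / nx, i = rem % nx;
    int nb[6]; int nnb = 0;
    if (i > 0) nb[nnb++] = c - 1;
    if (i < nx - 1) nb[nnb++] = c + 1;
    if (j > 0) nb[nnb++] = c - nx;
    if (j < ny - 1) nb[nnb++] = c + nx;
    if (k > 0) nb[nnb++] = c - (int)sxy;
    if (k < nz - 1) nb[nnb++] = c + (int)sxy;
    for (int q = 0; q < nnb; ++q) {
      int w = nb[q];
      if (!vis[w] && open[w]) { vis[w] = 1; stack.push_back(w); }
    }
  }
  LogicalVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = vis[i] != 0;
  return out;
}

// Fraction of directions per target whose radius-r capsule ray stays inside
// the channel until it leaves the grid. `dist` is the channel inner distance
// field (mm to nearest non-channel voxel, 0 outside the channel). Samples
// closer than eps_mm to the target are exempt (the target's epsilon-ball).
// [[Rcpp::export]]
NumericVector cpp_access_fraction(NumericVector dist, IntegerVector dims,
                                  NumericVector origin, double spacing,
                                  NumericMatrix targets, NumericMatrix dirs,
                                  double r, double eps_mm, double step_mm) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const double* F = REAL(dist);
  int nt = targets.nrow(), nd = dirs.nrow();
  NumericVector out(nt);
  for (int it = 0; it < nt; ++it) {
    double px = targets(it, 0), py = targets(it, 1), pz = targets(it, 2);
    int ok = 0;
    for (int id = 0; id < nd; ++id) {
      double dx = dirs(id, 0), dy = dirs(id, 1), dz = dirs(id, 2);
      // exit parameter from the voxel-center hull
      double tmax = INF;
      double pw[3] = { px, py, pz }, dw[3] = { dx, dy, dz };
      for (int a = 0; a < 3; ++a) {
        double loA = origin[a];
        double hiA = origin[a] + ((a == 0 ? nx : (a == 1 ? ny : nz)) - 1) * spacing;
        if (dw[a] > 1e-12) tmax = std::min(tmax, (hiA - pw[a]) / dw[a]);
        else if (dw[a] < -1e-12) tmax = std::min(tmax, (loA - pw[a]) / dw[a]);
      }
      bool pass = true;
      for (double s = eps_mm; s < tmax; s += step_mm) {
        double x = (px + s * dx - origin[0]) / spacing;
        double y = (py + s * dy - origin[1]) / spacing;
        double z = (pz + s * dz - origin[2]) / spacing;
        if (trilin(F, nx, ny, nz, x, y, z) < r) { pass = false; break; }
      }
      if (pass) ++ok;
    }
    out[it] = (double)ok / nd;
  }
  return out;
}

// Sum of 1/d over mutually visible unordered voxel pairs (times 2 gives the
// ordered-pair sum). idx: 0-based linear voxel indices of the sample points.
// Visibility: nearest voxel at each half-voxel step along the segment must
// be channel.
// [[Rcpp::export]]
List cpp_compactness_sum(LogicalVector channel, IntegerVector dims,
                         double spacing, IntegerVector idx, double step_mm) {
  int nx = dims[0], ny = dims[1];
  size_t sxy = (size_t)nx * ny;
  int m = idx.size();
  std::vector<double> X(m), Y(m), Z(m);
  for (int a = 0; a < m; ++a) {
    int c = idx[a];
    int k = c / (int)sxy, rem = c % (int)sxy, j = rem / nx, i = rem % nx;
    X[a] = i; Y[a] = j; Z[a] = k; // voxel units; world scale applied via spacing
  }
  double sum = 0.0;
  double npairs = 0.0;
  for (int a = 0; a < m; ++a) {
    for (int b = a + 1; b < m; ++b) {
      double dx = X[b] - X[a], dy = Y[b] - Y[a], dz = Z[b] - Z[a];
      double len = std::sqrt(dx * dx + dy * dy + dz * dz); // voxels
      npairs += 1.0;
      if (len == 0.0) continue;
      int nstep = std::max(1, (int)std::ceil(len * spacing / step_mm));
      bool vis = true;
      for (int q = 0; q <= nstep; ++q) {
        double u = (double)q / nstep;
        int i = (int)std::lround(X[a] + u * dx);
        int j = (int)std::lround(Y[a] + u * dy);
        int k = (int)std::lround(Z[a] + u * dz);
        if (!channel[i + (size_t)nx * j + sxy * k]) { vis = false; break; }
      }
      if (vis) sum += 1.0 / (len * spacing);
    }
  }
  return List::create(_["sum_unordered"] = sum, _["n_unordered"] = npairs);
}
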