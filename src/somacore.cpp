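// Voxel-level kernels shared by the phantom generator, the foreground
// extractor and the localizer. All arrays are column-major with
// dim = (nx, ny, nz); linear indices are 0-based here and converted to
// 1-based on the R side. Physical coordinate of voxel (ix, iy, iz)
// (0-based) is origin + (ix*vx, iy*vy, iz*vz), i.e. voxel centres sit on
// integer multiples of the voxel pitch.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <unordered_set>
#include <unordered_map>

using namespace Rcpp;

typedef R_xlen_t xl;

static inline xl LIN(int x, int y, int z, int nx, int ny) {
  return (xl)x + (xl)nx * ((xl)y + (xl)ny * (xl)z);
}

// ---------------------------------------------------------------------------
// Phantom rendering: additive-background scene with max-blended ellipsoids
// (somas) and spheres (neurite tube cross-sections), partial-volume
// anti-aliasing by 2x2x2 octant subsampling, optional Gaussian noise through
// the R RNG, clipping and rounding to integers.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_render_phantom(IntegerVector dims, NumericVector voxsz,
                                 NumericMatrix somas, NumericMatrix spheres,
                                 double background, double somaIntensity,
                                 double neuriteIntensity, double noiseSigma,
                                 double clipLo, double clipHi) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double vx = voxsz[0], vy = voxsz[1], vz = voxsz[2];
  const xl N = (xl)nx * ny * nz;
  std::vector<double> img(N, background);
  const double offs[2] = {-0.25, 0.25};

  // Ellipsoid with semi-axes (a, b) in-plane rotated by theta about z and
  // axial semi-axis c; level is the interior intensity.
  auto paintEllipsoid = [&](double cx, double cy, double cz, double a,
                            double b, double c, double theta, double level) {
    const double rxy = std::max(a, b);
    int x0 = std::max(0, (int)std::floor((cx - rxy) / vx) - 1);
    int x1 = std::min(nx - 1, (int)std::ceil((cx + rxy) / vx) + 1);
    int y0 = std::max(0, (int)std::floor((cy - rxy) / vy) - 1);
    int y1 = std::min(ny - 1, (int)std::ceil((cy + rxy) / vy) + 1);
    int z0 = std::max(0, (int)std::floor((cz - c) / vz) - 1);
    int z1 = std::min(nz - 1, (int)std::ceil((cz + c) / vz) + 1);
    const double ct = std::cos(theta), st = std::sin(theta);
    for (int z = z0; z <= z1; ++z)
      for (int y = y0; y <= y1; ++y)
        for (int x = x0; x <= x1; ++x) {
          int inside = 0;
          for (int sz = 0; sz < 2; ++sz)
            for (int sy = 0; sy < 2; ++sy)
              for (int sx = 0; sx < 2; ++sx) {
                const double px = (x + offs[sx]) * vx - cx;
                const double py = (y + offs[sy]) * vy - cy;
                const double pz = (z + offs[sz]) * vz - cz;
                const double qx = ct * px + st * py;
                const double qy = -st * px + ct * py;
                const double u = (qx / a) * (qx / a) + (qy / b) * (qy / b) +
                                 (pz / c) * (pz / c);
                if (u <= 1.0) ++inside;
              }
          if (inside > 0) {
            const double val = background + (inside / 8.0) * (level - background);
            const xl id = LIN(x, y, z, nx, ny);
            if (val > img[id]) img[id] = val;
          }
        }
  };

  for (int i = 0; i < somas.nrow(); ++i)
    paintEllipsoid(somas(i, 0), somas(i, 1), somas(i, 2), somas(i, 3),
                   somas(i, 4), somas(i, 5), somas(i, 6), somaIntensity);
  for (int i = 0; i < spheres.nrow(); ++i)
    paintEllipsoid(spheres(i, 0), spheres(i, 1), spheres(i, 2), spheres(i, 3),
                   spheres(i, 3), spheres(i, 3), 0.0, neuriteIntensity);

  if (noiseSigma > 0)
    for (xl i = 0; i < N; ++i) img[i] += R::rnorm(0.0, noiseSigma);

  IntegerVector out(N);
  for (xl i = 0; i < N; ++i) {
    double v = img[i];
    if (v < clipLo) v = clipLo;
    if (v > clipHi) v = clipHi;
    out[i] = (int)std::lround(v);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Histogram of intensities into nbins equal-width bins over [lo, hi].
// ---------------------------------------------------------------------------

template <typename V>
static IntegerVector histImpl(const V& img, double lo, double hi, int nbins) {
  IntegerVector counts(nbins);
  const double w = (hi - lo) / nbins;
  const xl n = img.size();
  for (xl i = 0; i < n; ++i) {
    int b = (int)std::floor(((double)img[i] - lo) / w);
    if (b < 0) b = 0;
    if (b >= nbins) b = nbins - 1;
    ++counts[b];
  }
  return counts;
}

// [[Rcpp::export]]
IntegerVector cpp_hist_counts(SEXP img, double lo, double hi, int nbins) {
  if (TYPEOF(img) == REALSXP) return histImpl(NumericVector(img), lo, hi, nbins);
  return histImpl(IntegerVector(img), lo, hi, nbins);
}

// ---------------------------------------------------------------------------
// Binary erosion with the 6-connected (face neighbour) structuring element.
// Voxels outside the array are treated as background. Degenerate axes of
// extent 1 are skipped, so a single-slice array erodes with the 2D
// 4-connected element.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalVector cpp_erode6(LogicalVector mask, IntegerVector dims, int reps) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const xl N = (xl)nx * ny * nz;
  std::vector<char> a(N), b(N);
  for (xl i = 0; i < N; ++i) a[i] = mask[i] != 0;
  for (int r = 0; r < reps; ++r) {
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          const xl id = LIN(x, y, z, nx, ny);
          char v = a[id];
          if (v && nx > 1) {
            if (x == 0 || !a[id - 1]) v = 0;
            else if (x == nx - 1 || !a[id + 1]) v = 0;
          }
          if (v && ny > 1) {
            if (y == 0 || !a[id - nx]) v = 0;
            else if (y == ny - 1 || !a[id + nx]) v = 0;
          }
          if (v && nz > 1) {
            if (z == 0 || !a[id - (xl)nx * ny]) v = 0;
            else if (z == nz - 1 || !a[id + (xl)nx * ny]) v = 0;
          }
          b[id] = v;
        }
    std::swap(a, b);
  }
  LogicalVector out(N);
  for (xl i = 0; i < N; ++i) out[i] = a[i] != 0;
  return out;
}

// ---------------------------------------------------------------------------
// 26-connected component labelling (iterative flood fill).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const xl N = (xl)nx * ny * nz;
  IntegerVector lab(N);
  std::vector<xl> stack;
  int cur = 0;
  for (xl s = 0; s < N; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++cur;
    lab[s] = cur;
    stack.push_back(s);
    while (!stack.empty()) {
      const xl id = stack.back();
      stack.pop_back();
      const int x = (int)(id % nx);
      const int y = (int)((id / nx) % ny);
      const int z = (int)(id / ((xl)nx * ny));
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            const int X = x + dx, Y = y + dy, Z = z + dz;
            if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz)
              continue;
            const xl q = LIN(X, Y, Z, nx, ny);
            if (mask[q] && lab[q] == 0) {
              lab[q] = cur;
              stack.push_back(q);
            }
          }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Exact anisotropic squared Euclidean distance transform (separable
// lower-envelope-of-parabolas algorithm), distances in micrometres. Returns,
// for every foreground voxel, the squared distance to the nearest background
// voxel centre; background voxels get 0.
// ---------------------------------------------------------------------------

static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& zb, int n,
                 double s) {
  const double s2 = s * s;
  int k = 0;
  v[0] = 0;
  zb[0] = -1e30;
  zb[1] = 1e30;
  for (int q = 1; q < n; ++q) {
    const double fq = f[q] + s2 * (double)q * q;
    while (true) {
      const int p = v[k];
      const double sep =
          (fq - (f[p] + s2 * (double)p * p)) / (2.0 * s2 * (q - p));
      if (sep <= zb[k]) {
        --k;
      } else {
        ++k;
        v[k] = q;
        zb[k] = sep;
        zb[k + 1] = 1e30;
        break;
      }
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < (double)q) ++k;
    const int p = v[k];
    const double dq = s * (q - p);
    d[q] = dq * dq + f[p];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dims,
                         NumericVector voxsz) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const xl N = (xl)nx * ny * nz;
  const double INF = 1e30;
  NumericVector d(N);
  for (xl i = 0; i < N; ++i) d[i] = mask[i] ? INF : 0.0;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), g(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);

  // x pass
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      const xl base = LIN(0, y, z, nx, ny);
      for (int x = 0; x < nx; ++x) f[x] = d[base + x];
      dt1d(f, g, v, zb, nx, voxsz[0]);
      for (int x = 0; x < nx; ++x) d[base + x] = g[x];
    }
  // y pass
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      const xl base = LIN(x, 0, z, nx, ny);
      for (int y = 0; y < ny; ++y) f[y] = d[base + (xl)y * nx];
      dt1d(f, g, v, zb, ny, voxsz[1]);
      for (int y = 0; y < ny; ++y) d[base + (xl)y * nx] = g[y];
    }
  // z pass
  const xl plane = (xl)nx * ny;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      const xl base = LIN(x, y, 0, nx, ny);
      for (int z = 0; z < nz; ++z) f[z] = d[base + (xl)z * plane];
      dt1d(f, g, v, zb, nz, voxsz[2]);
      for (int z = 0; z < nz; ++z) d[base + (xl)z * plane] = g[z];
    }
  return d;
}

// ---------------------------------------------------------------------------
// Local maxima of a non-negative field over the 26-neighbourhood (plateau
// voxels included). Returns 0-based linear indices.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_local_maxima(NumericVector val, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<int> out;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const xl id = LIN(x, y, z, nx, ny);
        const double v = val[id];
        if (v <= 0) continue;
        bool ismax = true;
        for (int dz = -1; dz <= 1 && ismax; ++dz)
          for (int dy = -1; dy <= 1 && ismax; ++dy)
            for (int dx = -1; dx <= 1 && ismax; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              const int X = x + dx, Y = y + dy, Z = z + dz;
              if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz)
                continue;
              if (val[LIN(X, Y, Z, nx, ny)] > v) ismax = false;
            }
        if (ismax) out.push_back((int)id);
      }
  return IntegerVector(out.begin(), out.end());
}

// ---------------------------------------------------------------------------
// Single-linkage merging of points closer than `d` (micrometres), via a
// uniform grid hash and union-find. Returns 1-based cluster ids numbered in
// order of first appearance.
// ---------------------------------------------------------------------------

static int ufFind(std::vector<int>& par, int i) {
  while (par[i] != i) {
    par[i] = par[par[i]];
    i = par[i];
  }
  return i;
}

// [[Rcpp::export]]
IntegerVector cpp_merge_points(NumericMatrix pts, double d) {
  const int n = pts.nrow();
  std::vector<int> par(n);
  for (int i = 0; i < n; ++i) par[i] = i;
  if (d > 0 && n > 1) {
    std::unordered_map<long long, std::vector<int> > grid;
    auto key = [&](double x, double y, double z) {
      const long long gx = (long long)std::floor(x / d) + (1LL << 20);
      const long long gy = (long long)std::floor(y / d) + (1LL << 20);
      const long long gz = (long long)std::floor(z / d) + (1LL << 20);
      return (gx << 42) ^ (gy << 21) ^ gz;
    };
    for (int i = 0; i < n; ++i)
      grid[key(pts(i, 0), pts(i, 1), pts(i, 2))].push_back(i);
    const double d2 = d * d;
    for (int i = 0; i < n; ++i) {
      const double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            auto it = grid.find(key(x + dx * d, y + dy * d, z + dz * d));
            if (it == grid.end()) continue;
            for (int j : it->second) {
              if (j <= i) continue;
              const double ddx = x - pts(j, 0), ddy = y - pts(j, 1),
                           ddz = z - pts(j, 2);
              if (ddx * ddx + ddy * ddy + ddz * ddz < d2) {
                const int a = ufFind(par, i), b = ufFind(par, j);
                if (a != b) par[b] = a;
              }
            }
          }
    }
  }
  IntegerVector cl(n);
  std::unordered_map<int, int> renum;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    const int r = ufFind(par, i);
    auto it = renum.find(r);
    if (it == renum.end()) {
      renum[r] = ++next;
      cl[i] = next;
    } else {
      cl[i] = it->second;
    }
  }
  return cl;
}

// ---------------------------------------------------------------------------
// Ball-indicator atoms for the L1 superposition fit: for every candidate
// centre (micrometres, relative to the array origin) and every radius,
// collect the 0-based linear indices of voxels whose centre lies within the
// radius. Atom id (1-based) = candidate_index * n_radii + radius_index.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_ball_atoms(IntegerVector dims, NumericVector voxsz,
                    NumericMatrix centers, NumericVector radii) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double vx = voxsz[0], vy = voxsz[1], vz = voxsz[2];
  const int nc = centers.nrow(), nr = radii.size();
  std::vector<int> vox, atom;
  vox.reserve(1 << 20);
  atom.reserve(1 << 20);
  for (int ci = 0; ci < nc; ++ci) {
    const double cx = centers(ci, 0), cy = centers(ci, 1), cz = centers(ci, 2);
    for (int rj = 0; rj < nr; ++rj) {
      const double r = radii[rj], r2 = r * r;
      const int aid = ci * nr + rj + 1;
      const int x0 = std::max(0, (int)std::ceil((cx - r) / vx));
      const int x1 = std::min(nx - 1, (int)std::floor((cx + r) / vx));
      const int y0 = std::max(0, (int)std::ceil((cy - r) / vy));
      const int y1 = std::min(ny - 1, (int)std::floor((cy + r) / vy));
      const int z0 = std::max(0, (int)std::ceil((cz - r) / vz));
      const int z1 = std::min(nz - 1, (int)std::floor((cz + r) / vz));
      for (int z = z0; z <= z1; ++z) {
        const double pz = z * vz - cz;
        for (int y = y0; y <= y1; ++y) {
          const double py = y * vy - cy;
          for (int x = x0; x <= x1; ++x) {
            const double px = x * vx - cx;
            if (px * px + py * py + pz * pz <= r2) {
              vox.push_back((int)LIN(x, y, z, nx, ny));
              atom.push_back(aid);
            }
          }
        }
      }
    }
  }
  return List::create(_["vox"] = IntegerVector(vox.begin(), vox.end()),
                      _["atom"] = IntegerVector(atom.begin(), atom.end()));
}

// ---------------------------------------------------------------------------
// Intensity region growing (26-connectivity) from a start voxel, admitting
// voxels with intensity >= thr whose centre lies within maxRadiusUm of the
// seed coordinate. Returns sorted 0-based linear indices.
// ---------------------------------------------------------------------------

template <typename V>
static IntegerVector growImpl(const V& img, IntegerVector dims,
                              NumericVector voxsz, IntegerVector startVox,
                              NumericVector centerUm, double thr,
                              double maxRadiusUm) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double vx = voxsz[0], vy = voxsz[1], vz = voxsz[2];
  const double r2 = maxRadiusUm * maxRadiusUm;
  const xl s = LIN(startVox[0], startVox[1], startVox[2], nx, ny);
  std::unordered_set<xl> seen;
  std::vector<xl> stack, keep;
  if ((double)img[s] >= thr) {
    seen.insert(s);
    stack.push_back(s);
  }
  while (!stack.empty()) {
    const xl id = stack.back();
    stack.pop_back();
    keep.push_back(id);
    const int x = (int)(id % nx);
    const int y = (int)((id / nx) % ny);
    const int z = (int)(id / ((xl)nx * ny));
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          const int X = x + dx, Y = y + dy, Z = z + dz;
          if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz)
            continue;
          const xl q = LIN(X, Y, Z, nx, ny);
          if (seen.count(q)) continue;
          if ((double)img[q] < thr) continue;
          const double px = X * vx - centerUm[0];
          const double py = Y * vy - centerUm[1];
          const double pz = Z * vz - centerUm[2];
          if (px * px + py * py + pz * pz > r2) continue;
          seen.insert(q);
          stack.push_back(q);
        }
  }
  std::sort(keep.begin(), keep.end());
  IntegerVector out(keep.size());
  for (size_t i = 0; i < keep.size(); ++i) out[i] = (int)keep[i];
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_region_grow(SEXP img, IntegerVector dims,
                              NumericVector voxsz, IntegerVector startVox,
                              NumericVector centerUm, double thr,
                              double maxRadiusUm) {
  if (TYPEOF(img) == REALSXP)
    return growImpl(NumericVector(img), dims, voxsz, startVox, centerUm, thr,
                    maxRadiusUm);
  return growImpl(IntegerVector(img), dims, voxsz, startVox, centerUm, thr,
                  maxRadiusUm);
}

// ---------------------------------------------------------------------------
// Exposed-face surface area of a voxel set (0-based linear indices): sum of
// the physical areas of faces whose neighbour is outside the set.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_exposed_area(IntegerVector idx0, IntegerVector dims,
                        NumericVector voxsz) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double ax = voxsz[1] * voxsz[2]; // face normal to x
  const double ay = voxsz[0] * voxsz[2];
  const double az = voxsz[0] * voxsz[1];
  std::unordered_set<xl> set;
  set.reserve(idx0.size() * 2);
  for (int i = 0; i < idx0.size(); ++i) set.insert((xl)idx0[i]);
  double area = 0;
  for (int i = 0; i < idx0.size(); ++i) {
    const xl id = (xl)idx0[i];
    const int x = (int)(id % nx);
    const int y = (int)((id / nx) % ny);
    const int z = (int)(id / ((xl)nx * ny));
    if (x == 0 || !set.count(id - 1)) area += ax;
    if (x == nx - 1 || !set.count(id + 1)) area += ax;
    if (y == 0 || !set.count(id - nx)) area += ay;
    if (y == ny - 1 || !set.count(id + nx)) area += ay;
    if (z == 0 || !set.count(id - (xl)nx * ny)) area += az;
    if (z == nz - 1 || !set.count(id + (xl)nx * ny)) area += az;
  }
  return area;
}
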