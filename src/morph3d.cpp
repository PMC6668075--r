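#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Value standing in for "no source voxel on this line" in the distance
// transform; must dominate any in-grid squared distance (grids are << 1e6 wide).
static const double DT_BIG = 1e20;

// -------------------------------------------------------------------------
// Connected component labelling (6/18/26 connectivity).
// Labels are assigned in raster-scan order of each component's first voxel,
// so label 1 is the component containing the lowest linear index: ties among
// equal-sized components are broken deterministically downstream by taking
// the lowest label.
// [[Rcpp::export]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  std::vector<int> ox, oy, oz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int s = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (s == 0) continue;
        if (connectivity == 6 && s > 1) continue;
        if (connectivity == 18 && s > 2) continue;
        ox.push_back(dx); oy.push_back(dy); oz.push_back(dz);
      }

  IntegerVector lab(n);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++cur;
    lab[i] = cur;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t j = stack.back(); stack.pop_back();
      int x = (int)(j % nx);
      int y = (int)((j / nx) % ny);
      int z = (int)(j / ((R_xlen_t)nx * ny));
      for (size_t k = 0; k < ox.size(); ++k) {
        int xx = x + ox[k], yy = y + oy[k], zz = z + oz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        R_xlen_t jj = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[jj] && !lab[jj]) { lab[jj] = cur; stack.push_back(jj); }
      }
    }
  }
  return lab;
}

// -------------------------------------------------------------------------
// 1D squared distance transform (lower envelope of parabolas), Felzenszwalb &
// Huttenlocher. f is the input (0 at sources, DT_BIG elsewhere), d the output.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -DT_BIG; z[1] = DT_BIG;
  for (int q = 1; q < n; ++q) {
    double s = 0.0;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k] && k > 0) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    double val = dq * dq + f[v[k]];
    d[q] = (val > DT_BIG) ? DT_BIG : val;
  }
}

// Squared Euclidean distance to the nearest TRUE voxel (DT_BIG when none).
// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector fg, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (fg.size() != n) stop("mask length does not match dims");
  NumericVector d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = fg[i] ? 0.0 : DT_BIG;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), out(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int zz = 0; zz < nz; ++zz)
    for (int yy = 0; yy < ny; ++yy) {
      R_xlen_t base = (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
      for (int x = 0; x < nx; ++x) f[x] = d[base + x];
      dt1d(f, out, v, z, nx);
      for (int x = 0; x < nx; ++x) d[base + x] = out[x];
    }
  // pass along y
  for (int zz = 0; zz < nz; ++zz)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = x + (R_xlen_t)nx * ny * zz;
      for (int y = 0; y < ny; ++y) f[y] = d[base + (R_xlen_t)nx * y];
      dt1d(f, out, v, z, ny);
      for (int y = 0; y < ny; ++y) d[base + (R_xlen_t)nx * y] = out[y];
    }
  // pass along z
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  for (int yy = 0; yy < ny; ++yy)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = x + (R_xlen_t)nx * yy;
      for (int zz2 = 0; zz2 < nz; ++zz2) f[zz2] = d[base + sz * zz2];
      dt1d(f, out, v, z, nz);
      for (int zz2 = 0; zz2 < nz; ++zz2) d[base + sz * zz2] = out[zz2];
    }
  return d;
}

// -------------------------------------------------------------------------
// Binary median filter over a discrete ball {o : |o|^2 <= radius^2}.
// Voxels outside the grid count as background; output is the strict majority
// vote (ball sizes for integer radii are odd, so no ties arise there).
// [[Rcpp::export]]
LogicalVector ball_median_cpp(LogicalVector mask, IntegerVector dims, double radius) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  const int r = (int)std::floor(radius);
  const double r2 = radius * radius + 1e-9;
  std::vector<int> ox, oy, oz;
  for (int dz = -r; dz <= r; ++dz)
    for (int dy = -r; dy <= r; ++dy)
      for (int dx = -r; dx <= r; ++dx)
        if ((double)dx * dx + (double)dy * dy + (double)dz * dz <= r2) {
          ox.push_back(dx); oy.push_back(dy); oz.push_back(dz);
        }
  const int m = (int)ox.size();
  LogicalVector out(n);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int cnt = 0;
        for (int k = 0; k < m; ++k) {
          int xx = x + ox[k], yy = y + oy[k], zz = z + oz[k];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
          if (mask[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)]) ++cnt;
        }
        out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = (2 * cnt > m);
      }
  return out;
}

// -------------------------------------------------------------------------
// Generic erosion / dilation by an explicit offset list (columns x, y, z).
// Erosion treats out-of-grid voxels as background; dilation reflects the
// structuring element, as required for a true adjunction.
// [[Rcpp::export]]
LogicalVector sweep_erode_cpp(LogicalVector mask, IntegerVector dims, IntegerMatrix offsets) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int m = offsets.nrow();
  LogicalVector out(n);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        if (!mask[i]) { out[i] = false; continue; }
        bool keep = true;
        for (int k = 0; k < m; ++k) {
          int xx = x + offsets(k, 0), yy = y + offsets(k, 1), zz = z + offsets(k, 2);
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz ||
              !mask[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)]) {
            keep = false; break;
          }
        }
        out[i] = keep;
      }
  return out;
}

// [[Rcpp::export]]
LogicalVector sweep_dilate_cpp(LogicalVector mask, IntegerVector dims, IntegerMatrix offsets) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int m = offsets.nrow();
  LogicalVector out(n);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        bool hit = false;
        for (int k = 0; k < m; ++k) {
          int xx = x - offsets(k, 0), yy = y - offsets(k, 1), zz = z - offsets(k, 2);
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
          if (mask[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)]) { hit = true; break; }
        }
        out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = hit;
      }
  return out;
}
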