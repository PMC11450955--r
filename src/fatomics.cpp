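#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

// Volumes are R arrays with dim = (nz, ny, nx): index order (slice, row, col),
// column-major, so linear index = z + nz*(y + ny*x).

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static inline R_xlen_t lin(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)x);
}

// 3x3 median filter applied to each axial slice independently.
// Border handling: nearest-neighbour (clamped) replication.
// [[Rcpp::export]]
NumericVector cpp_median3x3(NumericVector vol, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  NumericVector out(vol.size());
  double buf[9];
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        int k = 0;
        for (int dy = -1; dy <= 1; ++dy) {
          const int yy = clampi(y + dy, 0, ny - 1);
          for (int dx = -1; dx <= 1; ++dx) {
            const int xx = clampi(x + dx, 0, nx - 1);
            buf[k++] = vol[lin(z, yy, xx, nz, ny)];
          }
        }
        std::nth_element(buf, buf + 4, buf + 9);
        out[lin(z, y, x, nz, ny)] = buf[4];
      }
    }
  }
  return out;
}

// 1-D squared Euclidean distance transform (lower envelope of parabolas),
// with sites spaced w millimetres apart.
// Sites with infinite f (no background reachable yet on this line) are
// skipped when building the envelope; if no finite site exists the whole
// line stays infinite.
static void dt1d(std::vector<double> &f, std::vector<double> &d, double w, int n) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (!(f[q] < INF)) continue;
    const double qw = q * w;
    if (k < 0) {
      k = 0;
      v[0] = q;
      z[0] = -INF;
      z[1] = INF;
      continue;
    }
    double s;
    while (true) {
      const double vw = v[k] * w;
      s = ((f[q] + qw * qw) - (f[v[k]] + vw * vw)) / (2.0 * (qw - vw));
      if (k > 0 && s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  if (k < 0) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    const double qw = q * w;
    while (z[k + 1] < qw) ++k;
    const double diff = qw - v[k] * w;
    d[q] = diff * diff + f[v[k]];
  }
}

// Anisotropy-aware squared Euclidean distance transform: for every voxel,
// squared physical distance (mm^2) to the nearest zero (background) voxel
// centre.  Voxels outside the grid are NOT treated as background; masks are
// expected not to touch the grid border.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double dz = spacing[0], dy = spacing[1], dx = spacing[2];
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) out[i] = mask[i] ? INF : 0.0;

  const int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax);

  // pass along z (stride 1)
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) f[z] = out[lin(z, y, x, nz, ny)];
      dt1d(f, d, dz, nz);
      for (int z = 0; z < nz; ++z) out[lin(z, y, x, nz, ny)] = d[z];
    }
  // pass along y
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) f[y] = out[lin(z, y, x, nz, ny)];
      dt1d(f, d, dy, ny);
      for (int y = 0; y < ny; ++y) out[lin(z, y, x, nz, ny)] = d[y];
    }
  // pass along x
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      for (int x = 0; x < nx; ++x) f[x] = out[lin(z, y, x, nz, ny)];
      dt1d(f, d, dx, nx);
      for (int x = 0; x < nx; ++x) out[lin(z, y, x, nz, ny)] = d[x];
    }
  return out;
}

struct RayGrid {
  const int *eat;
  int nz, ny, nx;
  double dz, dy, dx, z0, y0, x0, cz, cy, cx;
  bool in_fat(double uz, double uy, double ux, double r) const {
    const int ix = (int)std::lround((cx + r * ux - x0) / dx);
    const int iy = (int)std::lround((cy + r * uy - y0) / dy);
    const int iz = (int)std::lround((cz + r * uz - z0) / dz);
    if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz) return false;
    return eat[lin(iz, iy, ix, nz, ny)] != 0;
  }
};

// Bisection refinement of a fat-boundary crossing: rin is in fat, rout not.
static double refine_crossing(const RayGrid &g, double uz, double uy, double ux,
                              double rin, double rout) {
  for (int i = 0; i < 25; ++i) {
    const double m = 0.5 * (rin + rout);
    if (g.in_fat(uz, uy, ux, m)) rin = m; else rout = m;
  }
  return 0.5 * (rin + rout);
}

// Ray-cast EAT thickness map.  For each direction on the 1-degree grid
// (polar angle phi = 0..179 deg from +z, azimuth theta = 0..359 deg in the
// xy-plane), march from the centroid outward in steps of `step` mm up to
// `rmax` mm; a sample is "in fat" if its containing voxel (nearest voxel
// centre) is inside the EAT mask.  The entry point of the first intersected
// fat voxel and the exit point of the last one are refined by bisection
// between the bracketing samples, and the thickness is the Euclidean
// distance between them (0 if the ray meets no fat).  Returns a 180 x 360
// matrix (rows = phi, cols = theta).
// [[Rcpp::export]]
NumericMatrix cpp_raycast(LogicalVector eat, IntegerVector dim, NumericVector spacing,
                          NumericVector origin, NumericVector centroid,
                          double step, double rmax) {
  RayGrid g;
  std::vector<int> eatv(eat.size());
  for (R_xlen_t i = 0; i < eat.size(); ++i) eatv[i] = eat[i] ? 1 : 0;
  g.eat = eatv.data();
  g.nz = dim[0]; g.ny = dim[1]; g.nx = dim[2];
  g.dz = spacing[0]; g.dy = spacing[1]; g.dx = spacing[2];
  g.z0 = origin[0]; g.y0 = origin[1]; g.x0 = origin[2];
  g.cz = centroid[0]; g.cy = centroid[1]; g.cx = centroid[2];
  NumericMatrix out(180, 360);
  const int nsteps = (int)std::floor(rmax / step) + 1;
  const double DEG = M_PI / 180.0;
  for (int p = 0; p < 180; ++p) {
    const double sp = std::sin(p * DEG), cp = std::cos(p * DEG);
    for (int t = 0; t < 360; ++t) {
      const double ux = sp * std::cos(t * DEG);
      const double uy = sp * std::sin(t * DEG);
      const double uz = cp;
      double first = -1.0, last = -1.0;
      for (int s = 0; s < nsteps; ++s) {
        const double r = s * step;
        if (g.in_fat(uz, uy, ux, r)) {
          if (first < 0.0) first = r;
          last = r;
        }
      }
      if (first < 0.0) {
        out(p, t) = 0.0;
        continue;
      }
      const double entry = first <= 0.0 ? 0.0
        : refine_crossing(g, uz, uy, ux, first, first - step);
      const double exit = refine_crossing(g, uz, uy, ux, last, last + step);
      out(p, t) = exit - entry;
    }
  }
  return out;
}
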