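// Voxel-level primitives used by the micro-CT and phantom modules:
//  - 3D Euclidean distance transform (Felzenszwalb & Huttenlocher, separable)
//  - 3D/2D topological curve thinning (Malandain-Bertrand simple points,
//    6-subiteration directional schedule, endpoint preservation)
//  - 26-connected component labeling
//  - supersampled partial-volume capsule (tube) rasterizer
//  - separable 3D convolution (Gaussian smoothing of volumes)
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
#include <algorithm>
#include <utility>
using namespace Rcpp;

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// ---------------------------------------------------------------------------
// 1D squared distance transform along a line of sampled function values.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> zz(n + 1);
  int k = 0;
  v[0] = 0;
  zz[0] = -std::numeric_limits<double>::infinity();
  zz[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= zz[k]) {
      k--;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    zz[k] = s;
    zz[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (zz[k + 1] < q) k++;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance of every true voxel to the nearest false voxel.
// Voxels outside the grid count as false (background).
// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  // pad by one background voxel on every side so the outside is background
  int px = nx + 2, py = ny + 2, pz = nz + 2;
  const double INF = 1e18;
  std::vector<double> g((size_t)px * py * pz);
  for (int z = 0; z < pz; z++)
    for (int y = 0; y < py; y++)
      for (int x = 0; x < px; x++) {
        bool fg = false;
        if (x >= 1 && x <= nx && y >= 1 && y <= ny && z >= 1 && z <= nz)
          fg = mask[idx3(x - 1, y - 1, z - 1, nx, ny)];
        g[idx3(x, y, z, px, py)] = fg ? INF : 0.0;
      }
  std::vector<double> f(std::max(px, std::max(py, pz)));
  std::vector<double> d(std::max(px, std::max(py, pz)));
  // along x
  for (int z = 0; z < pz; z++)
    for (int y = 0; y < py; y++) {
      for (int x = 0; x < px; x++) f[x] = g[idx3(x, y, z, px, py)];
      dt1d(f, d, px);
      for (int x = 0; x < px; x++) g[idx3(x, y, z, px, py)] = d[x];
    }
  // along y
  for (int z = 0; z < pz; z++)
    for (int x = 0; x < px; x++) {
      for (int y = 0; y < py; y++) f[y] = g[idx3(x, y, z, px, py)];
      dt1d(f, d, py);
      for (int y = 0; y < py; y++) g[idx3(x, y, z, px, py)] = d[y];
    }
  // along z
  for (int y = 0; y < py; y++)
    for (int x = 0; x < px; x++) {
      for (int z = 0; z < pz; z++) f[z] = g[idx3(x, y, z, px, py)];
      dt1d(f, d, pz);
      for (int z = 0; z < pz; z++) g[idx3(x, y, z, px, py)] = d[z];
    }
  NumericVector out(nx * (R_xlen_t)ny * nz);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++)
        out[idx3(x, y, z, nx, ny)] =
          std::sqrt(g[idx3(x + 1, y + 1, z + 1, px, py)]);
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Simple-point test (Malandain & Bertrand characterization): a foreground
// voxel is simple iff it has exactly one 26-connected foreground component
// in its 26-neighborhood and exactly one 6-connected background component
// in its 18-neighborhood that touches a face neighbor.
namespace {

struct Neigh {
  // occupancy of the 3x3x3 neighborhood, index (dx+1) + 3*(dy+1) + 9*(dz+1)
  bool fg[27];
};

inline int noff(int dx, int dy, int dz) {
  return (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
}

int find_root(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

inline void unite(std::vector<int>& parent, int a, int b) {
  int ra = find_root(parent, a), rb = find_root(parent, b);
  if (ra != rb) parent[ra] = rb;
}

bool is_simple(const Neigh& nb) {
  // C*: 26-connected fg components among the 26 neighbors
  std::vector<int> parent(27);
  for (int i = 0; i < 27; i++) parent[i] = i;
  int center = noff(0, 0, 0);
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        int i = noff(dx, dy, dz);
        if (i == center || !nb.fg[i]) continue;
        for (int ez = -1; ez <= 1; ez++)
          for (int ey = -1; ey <= 1; ey++)
            for (int ex = -1; ex <= 1; ex++) {
              int j = noff(ex, ey, ez);
              if (j == center || j <= i || !nb.fg[j]) continue;
              if (std::abs(ex - dx) <= 1 && std::abs(ey - dy) <= 1 &&
                  std::abs(ez - dz) <= 1)
                unite(parent, i, j);
            }
      }
  int cstar = 0;
  for (int i = 0; i < 27; i++)
    if (i != center && nb.fg[i] && find_root(parent, i) == i) {
      // count roots among fg; roots may have been re-pointed, count canonical
    }
  {
    std::vector<int> roots;
    for (int i = 0; i < 27; i++) {
      if (i == center || !nb.fg[i]) continue;
      int r = find_root(parent, i);
      bool seen = false;
      for (size_t k = 0; k < roots.size(); k++)
        if (roots[k] == r) { seen = true; break; }
      if (!seen) roots.push_back(r);
    }
    cstar = (int)roots.size();
  }
  if (cstar != 1) return false;

  // Cbar: 6-connected bg components within the 18-neighborhood that contain
  // a face neighbor
  for (int i = 0; i < 27; i++) parent[i] = i;
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        int n1 = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (n1 == 0 || n1 > 2) continue;  // 18-neighborhood only
        int i = noff(dx, dy, dz);
        if (nb.fg[i]) continue;  // background only
        for (int ez = -1; ez <= 1; ez++)
          for (int ey = -1; ey <= 1; ey++)
            for (int ex = -1; ex <= 1; ex++) {
              int m1 = std::abs(ex) + std::abs(ey) + std::abs(ez);
              if (m1 == 0 || m1 > 2) continue;
              int j = noff(ex, ey, ez);
              if (j <= i || nb.fg[j]) continue;
              if (std::abs(ex - dx) + std::abs(ey - dy) + std::abs(ez - dz) == 1)
                unite(parent, i, j);
            }
      }
  std::vector<int> roots;
  const int faces[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (int k = 0; k < 6; k++) {
    int i = noff(faces[k][0], faces[k][1], faces[k][2]);
    if (nb.fg[i]) continue;
    int r = find_root(parent, i);
    bool seen = false;
    for (size_t q = 0; q < roots.size(); q++)
      if (roots[q] == r) { seen = true; break; }
    if (!seen) roots.push_back(r);
  }
  return roots.size() == 1;
}

}  // namespace

// Iterative curve thinning. Preserves curve endpoints (voxels with at most
// one foreground 26-neighbor), so tube masks reduce to centerlines.
// [[Rcpp::export]]
LogicalVector cpp_thin3d(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<char> m((size_t)nx * ny * nz);
  for (R_xlen_t i = 0; i < mask.size(); i++) m[i] = mask[i] ? 1 : 0;

  const int dirs[6][3] = {{0,0,-1},{0,0,1},{0,-1,0},{0,1,0},{-1,0,0},{1,0,0}};

  auto get = [&](int x, int y, int z) -> bool {
    if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) return false;
    return m[idx3(x, y, z, nx, ny)] != 0;
  };
  auto gather = [&](int x, int y, int z, Neigh& nb) {
    for (int dz = -1; dz <= 1; dz++)
      for (int dy = -1; dy <= 1; dy++)
        for (int dx = -1; dx <= 1; dx++)
          nb.fg[noff(dx, dy, dz)] = get(x + dx, y + dy, z + dz);
  };
  auto n26 = [&](int x, int y, int z) -> int {
    int c = 0;
    for (int dz = -1; dz <= 1; dz++)
      for (int dy = -1; dy <= 1; dy++)
        for (int dx = -1; dx <= 1; dx++) {
          if (!dx && !dy && !dz) continue;
          if (get(x + dx, y + dy, z + dz)) c++;
        }
    return c;
  };

  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; d++) {
      std::vector<int> cand;
      for (int z = 0; z < nz; z++)
        for (int y = 0; y < ny; y++)
          for (int x = 0; x < nx; x++) {
            if (!get(x, y, z)) continue;
            if (get(x + dirs[d][0], y + dirs[d][1], z + dirs[d][2])) continue;
            int deg = n26(x, y, z);
            if (deg <= 1) continue;  // endpoint or isolated: keep
            Neigh nb;
            gather(x, y, z, nb);
            if (is_simple(nb)) cand.push_back(idx3(x, y, z, nx, ny));
          }
      // sequential re-check so earlier deletions are respected
      for (size_t k = 0; k < cand.size(); k++) {
        int i = cand[k];
        int z = i / (nx * ny), y = (i / nx) % ny, x = i % nx;
        int deg = n26(x, y, z);
        if (deg <= 1) continue;
        Neigh nb;
        gather(x, y, z, nb);
        if (is_simple(nb)) {
          m[i] = 0;
          changed = true;
        }
      }
    }
  }
  LogicalVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); i++) out[i] = m[i] != 0;
  out.attr("dim") = dims;
  return out;
}

// 26-connected component labeling.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  std::vector<int> stack;
  for (R_xlen_t s = 0; s < mask.size(); s++) {
    if (!mask[s] || lab[s] != 0) continue;
    next++;
    stack.clear();
    stack.push_back((int)s);
    lab[s] = next;
    while (!stack.empty()) {
      int i = stack.back();
      stack.pop_back();
      int z = i / (nx * ny), y = (i / nx) % ny, x = i % nx;
      for (int dz = -1; dz <= 1; dz++)
        for (int dy = -1; dy <= 1; dy++)
          for (int dx = -1; dx <= 1; dx++) {
            if (!dx && !dy && !dz) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
              continue;
            int j = idx3(xx, yy, zz, nx, ny);
            if (mask[j] && lab[j] == 0) {
              lab[j] = next;
              stack.push_back(j);
            }
          }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// ---------------------------------------------------------------------------
// Rasterize a capsule (cylinder with hemispherical caps) of given radius
// between p0 and p1 (1-based voxel-center coordinates) into `vol`, writing
// amplitude * (partial-volume fraction) with max-blending.  The fraction is
// estimated by ss^3 subsamples per voxel, so integrated intensity equals the
// capsule volume to rasterization accuracy.
// [[Rcpp::export]]
NumericVector cpp_render_capsule(NumericVector vol, IntegerVector dims,
                                 NumericVector p0, NumericVector p1,
                                 double radius, double amplitude, int ss) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out = clone(vol);
  double ax = p0[0], ay = p0[1], az = p0[2];
  double bx = p1[0], by = p1[1], bz = p1[2];
  double vx = bx - ax, vy = by - ay, vz = bz - az;
  double L2 = vx * vx + vy * vy + vz * vz;
  double pad = radius + 1.0;
  int x0 = std::max(0, (int)std::floor(std::min(ax, bx) - pad) - 1);
  int x1 = std::min(nx - 1, (int)std::ceil(std::max(ax, bx) + pad));
  int y0 = std::max(0, (int)std::floor(std::min(ay, by) - pad) - 1);
  int y1 = std::min(ny - 1, (int)std::ceil(std::max(ay, by) + pad));
  int z0 = std::max(0, (int)std::floor(std::min(az, bz) - pad) - 1);
  int z1 = std::min(nz - 1, (int)std::ceil(std::max(az, bz) + pad));
  double step = 1.0 / ss;
  double off0 = -0.5 + step / 2.0;
  double r2 = radius * radius;
  int nss = ss * ss * ss;
  for (int z = z0; z <= z1; z++)
    for (int y = y0; y <= y1; y++)
      for (int x = x0; x <= x1; x++) {
        // voxel center at (x+1, y+1, z+1) in 1-based coords
        double cx = x + 1, cy = y + 1, cz = z + 1;
        // quick reject: distance of center to segment > radius + half-diagonal
        double t = 0.0;
        if (L2 > 0)
          t = ((cx - ax) * vx + (cy - ay) * vy + (cz - az) * vz) / L2;
        if (t < 0) t = 0;
        if (t > 1) t = 1;
        double qx = ax + t * vx - cx, qy = ay + t * vy - cy,
               qz = az + t * vz - cz;
        double dc2 = qx * qx + qy * qy + qz * qz;
        double lim = radius + 0.87;
        if (dc2 > lim * lim) continue;
        int cnt = 0;
        for (int iz = 0; iz < ss; iz++)
          for (int iy = 0; iy < ss; iy++)
            for (int ix = 0; ix < ss; ix++) {
              double px = cx + off0 + ix * step;
              double py = cy + off0 + iy * step;
              double pz = cz + off0 + iz * step;
              double tt = 0.0;
              if (L2 > 0)
                tt = ((px - ax) * vx + (py - ay) * vy + (pz - az) * vz) / L2;
              if (tt < 0) tt = 0;
              if (tt > 1) tt = 1;
              double dx = ax + tt * vx - px, dy = ay + tt * vy - py,
                     dz = az + tt * vz - pz;
              if (dx * dx + dy * dy + dz * dz <= r2) cnt++;
            }
        if (cnt == 0) continue;
        double val = amplitude * (double)cnt / nss;
        int i = idx3(x, y, z, nx, ny);
        if (val > out[i]) out[i] = val;
      }
  return out;
}

// Separable convolution of a 3D volume with centered 1D kernels applied
// along each axis (zero padding at the borders).  A kernel of length 1 and
// value 1 leaves that axis untouched, so per-plane 2D filtering is the
// special case kz = 1.
// [[Rcpp::export]]
NumericVector cpp_sepconv3d(NumericVector vol, IntegerVector dims,
                            NumericVector kx, NumericVector ky,
                            NumericVector kz) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> a(vol.begin(), vol.end());
  std::vector<double> b(a.size());
  // x
  {
    int kn = kx.size(), kr = kn / 2;
    for (int z = 0; z < nz; z++)
      for (int y = 0; y < ny; y++)
        for (int x = 0; x < nx; x++) {
          double s = 0;
          for (int k = 0; k < kn; k++) {
            int xx = x + k - kr;
            if (xx < 0 || xx >= nx) continue;
            s += kx[k] * a[idx3(xx, y, z, nx, ny)];
          }
          b[idx3(x, y, z, nx, ny)] = s;
        }
    std::swap(a, b);
  }
  // y
  {
    int kn = ky.size(), kr = kn / 2;
    for (int z = 0; z < nz; z++)
      for (int y = 0; y < ny; y++)
        for (int x = 0; x < nx; x++) {
          double s = 0;
          for (int k = 0; k < kn; k++) {
            int yy = y + k - kr;
            if (yy < 0 || yy >= ny) continue;
            s += ky[k] * a[idx3(x, yy, z, nx, ny)];
          }
          b[idx3(x, y, z, nx, ny)] = s;
        }
    std::swap(a, b);
  }
  // z
  {
    int kn = kz.size(), kr = kn / 2;
    for (int z = 0; z < nz; z++)
      for (int y = 0; y < ny; y++)
        for (int x = 0; x < nx; x++) {
          double s = 0;
          for (int k = 0; k < kn; k++) {
            int zz = z + k - kr;
            if (zz < 0 || zz >= nz) continue;
            s += kz[k] * a[idx3(x, y, zz, nx, ny)];
          }
          b[idx3(x, y, z, nx, ny)] = s;
        }
    std::swap(a, b);
  }
  NumericVector out(vol.size());
  for (R_xlen_t i = 0; i < vol.size(); i++) out[i] = a[i];
  out.attr("dim") = dims;
  return out;
}

// Median filter of a single 2D frame over a disk (or square) neighborhood,
// replicating edge pixels at the border.
// [[Rcpp::export]]
NumericMatrix cpp_median2d(NumericMatrix img, int radius, bool disk) {
  int nx = img.nrow(), ny = img.ncol();
  NumericMatrix out(nx, ny);
  std::vector<std::pair<int,int> > offs;
  for (int dy = -radius; dy <= radius; dy++)
    for (int dx = -radius; dx <= radius; dx++) {
      if (disk && dx * dx + dy * dy > radius * radius) continue;
      offs.push_back(std::make_pair(dx, dy));
    }
  std::vector<double> vals;
  vals.reserve(offs.size());
  for (int y = 0; y < ny; y++)
    for (int x = 0; x < nx; x++) {
      vals.clear();
      for (size_t k = 0; k < offs.size(); k++) {
        int xx = x + offs[k].first, yy = y + offs[k].second;
        if (xx < 0) xx = 0;
        if (yy < 0) yy = 0;
        if (xx >= nx) xx = nx - 1;
        if (yy >= ny) yy = ny - 1;
        vals.push_back(img(xx, yy));
      }
      size_t mid = vals.size() / 2;
      std::nth_element(vals.begin(), vals.begin() + mid, vals.end());
      double m = vals[mid];
      if (vals.size() % 2 == 0) {
        std::nth_element(vals.begin(), vals.begin() + mid - 1,
                         vals.begin() + mid);
        m = 0.5 * (m + vals[mid - 1]);
      }
      out(x, y) = m;
    }
  return out;
}
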