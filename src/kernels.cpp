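// Low-level numerical kernels for volume filtering, seed detection,
// template correlation, morphology voxelization and trace merging.
// Volumes are passed as flat numeric vectors in R's column-major array
// layout with dim = c(nx, ny, nz); linear index = x + nx*(y + ny*z).

#include <RcppArmadillo.h>
#include <queue>
#include <algorithm>
#include <cmath>

// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline R_xlen_t lin(int x, int y, int z, int nx, int ny) {
  return (R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * z);
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// ---------------------------------------------------------------------------
// Separable filtering
// ---------------------------------------------------------------------------

// Correlate a centered odd-length kernel along one axis (0=x,1=y,2=z)
// with replicate borders.
// [[Rcpp::export]]
NumericVector convSepAxis(NumericVector vol, IntegerVector dim,
                          NumericVector kernel, int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int klen = kernel.size();
  if (klen % 2 == 0) stop("kernel length must be odd");
  const int kh = klen / 2;
  NumericVector out(vol.size());
  const int n[3] = {nx, ny, nz};
  const int nax = n[axis];

  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double acc = 0.0;
        int c[3] = {x, y, z};
        for (int k = -kh; k <= kh; ++k) {
          int cc[3] = {c[0], c[1], c[2]};
          cc[axis] = clampi(c[axis] + k, 0, nax - 1);
          acc += kernel[k + kh] * vol[lin(cc[0], cc[1], cc[2], nx, ny)];
        }
        out[lin(x, y, z, nx, ny)] = acc;
      }
  return out;
}

// Grayscale erosion (running minimum) with half-width hw along one axis,
// replicate borders.
// [[Rcpp::export]]
NumericVector minFilterAxis(NumericVector vol, IntegerVector dim,
                            int hw, int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(vol.size());
  const int n[3] = {nx, ny, nz};
  const int nax = n[axis];
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int c[3] = {x, y, z};
        double m = R_PosInf;
        for (int k = -hw; k <= hw; ++k) {
          int cc[3] = {c[0], c[1], c[2]};
          cc[axis] = clampi(c[axis] + k, 0, nax - 1);
          double v = vol[lin(cc[0], cc[1], cc[2], nx, ny)];
          if (v < m) m = v;
        }
        out[lin(x, y, z, nx, ny)] = m;
      }
  return out;
}

// ---------------------------------------------------------------------------
// Hessian eigendecomposition
// ---------------------------------------------------------------------------

// Per-voxel symmetric 3x3 eigendecomposition of the Hessian given its six
// unique second-derivative volumes. Eigenvalues are returned sorted by
// absolute value |l1| <= |l2| <= |l3| together with the eigenvector of l1
// (sign-normalized to non-negative z, then y, then x component).
// [[Rcpp::export]]
List hessianEigenCpp(NumericVector dxx, NumericVector dyy, NumericVector dzz,
                     NumericVector dxy, NumericVector dxz, NumericVector dyz) {
  const R_xlen_t nvox = dxx.size();
  NumericVector l1(nvox), l2(nvox), l3(nvox);
  NumericVector v1x(nvox), v1y(nvox), v1z(nvox);
  arma::mat33 H;
  arma::vec3 eval;
  arma::mat33 evec;
  for (R_xlen_t i = 0; i < nvox; ++i) {
    H(0, 0) = dxx[i]; H(1, 1) = dyy[i]; H(2, 2) = dzz[i];
    H(0, 1) = H(1, 0) = dxy[i];
    H(0, 2) = H(2, 0) = dxz[i];
    H(1, 2) = H(2, 1) = dyz[i];
    arma::eig_sym(eval, evec, H);
    // order indices by |eigenvalue|
    int idx[3] = {0, 1, 2};
    std::sort(idx, idx + 3, [&](int a, int b) {
      return std::abs(eval(a)) < std::abs(eval(b));
    });
    l1[i] = eval(idx[0]);
    l2[i] = eval(idx[1]);
    l3[i] = eval(idx[2]);
    double ex = evec(0, idx[0]), ey = evec(1, idx[0]), ez = evec(2, idx[0]);
    double s = 1.0;
    if (ez < 0) s = -1.0;
    else if (ez == 0 && ey < 0) s = -1.0;
    else if (ez == 0 && ey == 0 && ex < 0) s = -1.0;
    v1x[i] = s * ex; v1y[i] = s * ey; v1z[i] = s * ez;
  }
  return List::create(_["l1"] = l1, _["l2"] = l2, _["l3"] = l3,
                      _["v1x"] = v1x, _["v1y"] = v1y, _["v1z"] = v1z);
}

// ---------------------------------------------------------------------------
// 3D maxima finding with noise tolerance (MaximumFinder semantics)
// ---------------------------------------------------------------------------

// Local maxima (26-connectivity) pruned by flooding: processing candidates
// in decreasing value, a candidate is rejected if its flood region (all
// connected voxels with value > v0 - tau) reaches a strictly higher voxel
// or territory already claimed by a higher maximum. Returns 0-based voxel
// coordinates of accepted maxima.
// [[Rcpp::export]]
IntegerMatrix findMaxima3dCpp(NumericVector vol, IntegerVector dim,
                              double tau) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = vol.size();
  double vmin = R_PosInf;
  for (R_xlen_t i = 0; i < nvox; ++i) if (vol[i] < vmin) vmin = vol[i];

  // candidate local maxima (>= all 26 neighbors, strictly above global min)
  std::vector<R_xlen_t> cand;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double v0 = vol[lin(x, y, z, nx, ny)];
        if (v0 <= vmin) continue;
        bool ismax = true;
        for (int dz = -1; dz <= 1 && ismax; ++dz)
          for (int dy = -1; dy <= 1 && ismax; ++dy)
            for (int dx = -1; dx <= 1 && ismax; ++dx) {
              if (!dx && !dy && !dz) continue;
              int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || yy < 0 || zz < 0 ||
                  xx >= nx || yy >= ny || zz >= nz) continue;
              if (vol[lin(xx, yy, zz, nx, ny)] > v0) ismax = false;
            }
        if (ismax) cand.push_back(lin(x, y, z, nx, ny));
      }
  std::stable_sort(cand.begin(), cand.end(), [&](R_xlen_t a, R_xlen_t b) {
    if (vol[a] != vol[b]) return vol[a] > vol[b];
    return a < b;
  });

  std::vector<int> owner(nvox, -1);
  std::vector<R_xlen_t> accepted;
  std::vector<R_xlen_t> region;
  for (size_t ci = 0; ci < cand.size(); ++ci) {
    R_xlen_t c0 = cand[ci];
    if (owner[c0] != -1) continue;  // swallowed by a higher maximum
    const double v0 = vol[c0];
    bool ok = true;
    region.clear();
    std::queue<R_xlen_t> q;
    q.push(c0);
    owner[c0] = (int)ci;
    region.push_back(c0);
    while (!q.empty()) {
      R_xlen_t cur = q.front(); q.pop();
      int x = (int)(cur % nx);
      int y = (int)((cur / nx) % ny);
      int z = (int)(cur / ((R_xlen_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || yy < 0 || zz < 0 ||
                xx >= nx || yy >= ny || zz >= nz) continue;
            R_xlen_t nb = lin(xx, yy, zz, nx, ny);
            double v = vol[nb];
            if (v > v0) { ok = false; continue; }
            if (v <= v0 - tau) continue;
            if (owner[nb] == -1) {
              owner[nb] = (int)ci;
              region.push_back(nb);
              q.push(nb);
            } else if (owner[nb] != (int)ci) {
              ok = false;  // within tau of a higher claimed maximum
            }
          }
    }
    if (ok) accepted.push_back(c0);
    // region stays claimed either way so lower maxima inside it are pruned
  }

  IntegerMatrix out(accepted.size(), 3);
  for (size_t i = 0; i < accepted.size(); ++i) {
    R_xlen_t p = accepted[i];
    out(i, 0) = (int)(p % nx);
    out(i, 1) = (int)((p / nx) % ny);
    out(i, 2) = (int)(p / ((R_xlen_t)nx * ny));
  }
  return out;
}

// ---------------------------------------------------------------------------
// Cylindrical non-maximum suppression
// ---------------------------------------------------------------------------

// Keep candidate i iff its value is the strict maximum of the map over the
// voxels inside its own oriented cylinder (radius 3*sigma, total length
// sigma i.e. half-length sigma/2 along v). Ties go to the lexicographically
// (x,y,z) lower position.
// [[Rcpp::export]]
LogicalVector cylindricalNmsCpp(NumericVector vol, IntegerVector dim,
                                IntegerMatrix pos, NumericMatrix dir,
                                NumericVector sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = pos.nrow();
  LogicalVector keep(n);
  for (int i = 0; i < n; ++i) {
    const int px = pos(i, 0), py = pos(i, 1), pz = pos(i, 2);
    const double vx = dir(i, 0), vy = dir(i, 1), vz = dir(i, 2);
    const double sg = sigma[i];
    const double rad = 3.0 * sg, hl = 0.5 * sg;
    const double v0 = vol[lin(px, py, pz, nx, ny)];
    const int ext = (int)std::ceil(std::sqrt(rad * rad + hl * hl));
    bool best = true;
    for (int dz = -ext; dz <= ext && best; ++dz)
      for (int dy = -ext; dy <= ext && best; ++dy)
        for (int dx = -ext; dx <= ext && best; ++dx) {
          int xx = px + dx, yy = py + dy, zz = pz + dz;
          if (xx < 0 || yy < 0 || zz < 0 ||
              xx >= nx || yy >= ny || zz >= nz) continue;
          if (!dx && !dy && !dz) continue;
          double ax = dx * vx + dy * vy + dz * vz;
          if (std::abs(ax) > hl) continue;
          double r2 = dx * dx + dy * dy + dz * dz - ax * ax;
          if (r2 > rad * rad) continue;
          double v = vol[lin(xx, yy, zz, nx, ny)];
          if (v > v0) best = false;
          else if (v == v0) {
            // lexicographic tie-break on (x, y, z)
            if (xx < px || (xx == px && (yy < py || (yy == py && zz < pz))))
              best = false;
          }
        }
    keep[i] = best;
  }
  return keep;
}

// ---------------------------------------------------------------------------
// Cylindrical-template zero-normalized cross-correlation
// ---------------------------------------------------------------------------

static inline double trilinear(const NumericVector &vol, int nx, int ny,
                               int nz, double x, double y, double z) {
  // border voxels replicated outside the volume
  if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
  if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
  if (z < 0) z = 0; if (z > nz - 1) z = nz - 1;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  int x1 = std::min(x0 + 1, nx - 1);
  int y1 = std::min(y0 + 1, ny - 1);
  int z1 = std::min(z0 + 1, nz - 1);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  double c00 = vol[lin(x0, y0, z0, nx, ny)] * (1 - fx) + vol[lin(x1, y0, z0, nx, ny)] * fx;
  double c10 = vol[lin(x0, y1, z0, nx, ny)] * (1 - fx) + vol[lin(x1, y1, z0, nx, ny)] * fx;
  double c01 = vol[lin(x0, y0, z1, nx, ny)] * (1 - fx) + vol[lin(x1, y0, z1, nx, ny)] * fx;
  double c11 = vol[lin(x0, y1, z1, nx, ny)] * (1 - fx) + vol[lin(x1, y1, z1, nx, ny)] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

static void makeFrame(double vx, double vy, double vz,
                      double *u, double *w) {
  // u = normalize(v x a), w = v x u, with a = z-hat unless |v.z| > 0.9
  double ax = 0, ay = 0, az = 1;
  if (std::abs(vz) > 0.9) { ax = 1; az = 0; }
  double ux = vy * az - vz * ay;
  double uy = vz * ax - vx * az;
  double uz = vx * ay - vy * ax;
  double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= nu; uy /= nu; uz /= nu;
  u[0] = ux; u[1] = uy; u[2] = uz;
  w[0] = vy * uz - vz * uy;
  w[1] = vz * ux - vx * uz;
  w[2] = vx * uy - vy * ux;
}

// ZNCC of the image against a cylindrical Gaussian-profile template of
// scale sigma posed at position p with axis v. Template support:
// floor(-3s) <= k,l <= ceil(3s) across the axis, floor(-s) <= m <= ceil(s)
// along it. Returns 0 for a constant image patch.
// [[Rcpp::export]]
NumericVector znccBatchCpp(NumericVector vol, IntegerVector dim,
                           NumericMatrix p, NumericMatrix v,
                           NumericVector sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = p.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double vx = v(i, 0), vy = v(i, 1), vz = v(i, 2);
    double nv = std::sqrt(vx * vx + vy * vy + vz * vz);
    vx /= nv; vy /= nv; vz /= nv;
    double u[3], w[3];
    makeFrame(vx, vy, vz, u, w);
    const double sg = sigma[i];
    const int klo = (int)std::floor(-3.0 * sg), khi = (int)std::ceil(3.0 * sg);
    const int mlo = (int)std::floor(-sg), mhi = (int)std::ceil(sg);
    const double px = p(i, 0), py = p(i, 1), pz = p(i, 2);
    double sI = 0, sI2 = 0, sG = 0, sG2 = 0, sIG = 0;
    long cnt = 0;
    for (int m = mlo; m <= mhi; ++m)
      for (int l = klo; l <= khi; ++l)
        for (int k = klo; k <= khi; ++k) {
          double g = std::exp(-(k * (double)k + l * (double)l) /
                              (2.0 * sg * sg));
          double x = px + k * u[0] + l * w[0] + m * vx;
          double y = py + k * u[1] + l * w[1] + m * vy;
          double z = pz + k * u[2] + l * w[2] + m * vz;
          double val = trilinear(vol, nx, ny, nz, x, y, z);
          sI += val; sI2 += val * val;
          sG += g; sG2 += g * g; sIG += val * g;
          ++cnt;
        }
    double varI = sI2 - sI * sI / cnt;
    double varG = sG2 - sG * sG / cnt;
    double cov = sIG - sI * sG / cnt;
    out[i] = (varI <= 1e-12 || varG <= 1e-12) ? 0.0
                                              : cov / std::sqrt(varI * varG);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Partial-volume voxelization of tapered capsules
// ---------------------------------------------------------------------------

static inline bool inCapsule(double qx, double qy, double qz,
                             const double *e) {
  // e = {x0,y0,z0,r0, x1,y1,z1,r1}; cone frustum with spherical caps
  const double dx = e[4] - e[0], dy = e[5] - e[1], dz = e[6] - e[2];
  const double a2 = dx * dx + dy * dy + dz * dz;
  const double wx = qx - e[0], wy = qy - e[1], wz = qz - e[2];
  // spherical caps
  double d0 = wx * wx + wy * wy + wz * wz;
  if (d0 <= e[3] * e[3]) return true;
  double w1x = qx - e[4], w1y = qy - e[5], w1z = qz - e[6];
  double d1 = w1x * w1x + w1y * w1y + w1z * w1z;
  if (d1 <= e[7] * e[7]) return true;
  if (a2 <= 1e-24) return false;  // degenerate edge: caps only
  double t = (wx * dx + wy * dy + wz * dz) / a2;
  if (t < 0 || t > 1) return false;
  double rt = e[3] + t * (e[7] - e[3]);
  double cx = e[0] + t * dx, cy = e[1] + t * dy, cz = e[2] + t * dz;
  double rx = qx - cx, ry = qy - cy, rz = qz - cz;
  return rx * rx + ry * ry + rz * rz <= rt * rt;
}

// Fraction of each voxel's volume inside the union of tapered capsules,
// estimated on a supersample^3 subgrid. Node coordinates are voxel-center
// coordinates (0-based). edges: n x 8 (x0,y0,z0,r0,x1,y1,z1,r1).
// [[Rcpp::export]]
NumericVector voxelizeCapsulesCpp(IntegerVector dim, NumericMatrix edges,
                                  int supersample) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int ne = edges.nrow();
  NumericVector occ((R_xlen_t)nx * ny * nz);
  if (ne == 0 || supersample < 1) return occ;
  const int s = supersample;
  const double nsub = (double)s * s * s;
  const double margin = 0.8660254037844386;  // voxel center-corner distance

  std::vector<std::array<double, 8>> E(ne);
  for (int i = 0; i < ne; ++i)
    for (int j = 0; j < 8; ++j) E[i][j] = edges(i, j);

  // global bounding box of the morphology
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < ne; ++i) {
    double rmax = std::max(E[i][3], E[i][7]);
    for (int ax = 0; ax < 3; ++ax) {
      lo[ax] = std::min(lo[ax], std::min(E[i][ax], E[i][4 + ax]) - rmax);
      hi[ax] = std::max(hi[ax], std::max(E[i][ax], E[i][4 + ax]) + rmax);
    }
  }
  int x0 = clampi((int)std::floor(lo[0] - 1), 0, nx - 1);
  int x1 = clampi((int)std::ceil(hi[0] + 1), 0, nx - 1);
  int y0 = clampi((int)std::floor(lo[1] - 1), 0, ny - 1);
  int y1 = clampi((int)std::ceil(hi[1] + 1), 0, ny - 1);
  int z0 = clampi((int)std::floor(lo[2] - 1), 0, nz - 1);
  int z1 = clampi((int)std::ceil(hi[2] + 1), 0, nz - 1);

  std::vector<int> near;
  for (int z = z0; z <= z1; ++z)
    for (int y = y0; y <= y1; ++y)
      for (int x = x0; x <= x1; ++x) {
        // candidate edges: dilated capsule containing the voxel center
        near.clear();
        for (int i = 0; i < ne; ++i) {
          std::array<double, 8> d = E[i];
          d[3] += margin; d[7] += margin;
          if (inCapsule((double)x, (double)y, (double)z, d.data()))
            near.push_back(i);
        }
        if (near.empty()) continue;
        int inside = 0;
        for (int sz = 0; sz < s; ++sz)
          for (int sy = 0; sy < s; ++sy)
            for (int sx = 0; sx < s; ++sx) {
              double qx = x + (sx + 0.5) / s - 0.5;
              double qy = y + (sy + 0.5) / s - 0.5;
              double qz = z + (sz + 0.5) / s - 0.5;
              for (size_t j = 0; j < near.size(); ++j)
                if (inCapsule(qx, qy, qz, E[near[j]].data())) {
                  ++inside;
                  break;
                }
            }
        occ[lin(x, y, z, nx, ny)] = inside / nsub;
      }
  return occ;
}

// ---------------------------------------------------------------------------
// Connected components (binary, 26-connectivity)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector labelComponentsCpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = mask.size();
  IntegerVector lab(nvox);
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t i = 0; i < nvox; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    lab[i] = next;
    q.push(i);
    while (!q.empty()) {
      R_xlen_t cur = q.front(); q.pop();
      int x = (int)(cur % nx);
      int y = (int)((cur / nx) % ny);
      int z = (int)(cur / ((R_xlen_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || yy < 0 || zz < 0 ||
                xx >= nx || yy >= ny || zz >= nz) continue;
            R_xlen_t nb = lin(xx, yy, zz, nx, ny);
            if (mask[nb] && !lab[nb]) {
              lab[nb] = next;
              q.push(nb);
            }
          }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Spatial binning helper for mean-shift / grouping / nearest neighbors
// ---------------------------------------------------------------------------

struct Grid3 {
  double cell;
  double ox, oy, oz;
  int gx, gy, gz;
  std::vector<std::vector<int>> bins;
  Grid3(const NumericMatrix &pos, const double *asp, double cellSize) {
    cell = std::max(cellSize, 1e-6);
    const int n = pos.nrow();
    double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
    double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int i = 0; i < n; ++i)
      for (int a = 0; a < 3; ++a) {
        double v = pos(i, a) * asp[a];
        lo[a] = std::min(lo[a], v);
        hi[a] = std::max(hi[a], v);
      }
    ox = lo[0]; oy = lo[1]; oz = lo[2];
    gx = std::max(1, (int)((hi[0] - lo[0]) / cell) + 1);
    gy = std::max(1, (int)((hi[1] - lo[1]) / cell) + 1);
    gz = std::max(1, (int)((hi[2] - lo[2]) / cell) + 1);
    bins.resize((size_t)gx * gy * gz);
    for (int i = 0; i < n; ++i) {
      int bxi = (int)((pos(i, 0) * asp[0] - ox) / cell);
      int byi = (int)((pos(i, 1) * asp[1] - oy) / cell);
      int bzi = (int)((pos(i, 2) * asp[2] - oz) / cell);
      bins[(size_t)bxi + (size_t)gx * (byi + (size_t)gy * bzi)].push_back(i);
    }
  }
  template <typename F>
  void forNeighborhood(double x, double y, double z, double radius, F f) const {
    int bx0 = clampi((int)((x - ox - radius) / cell), 0, gx - 1);
    int bx1 = clampi((int)((x - ox + radius) / cell), 0, gx - 1);
    int by0 = clampi((int)((y - oy - radius) / cell), 0, gy - 1);
    int by1 = clampi((int)((y - oy + radius) / cell), 0, gy - 1);
    int bz0 = clampi((int)((z - oz - radius) / cell), 0, gz - 1);
    int bz1 = clampi((int)((z - oz + radius) / cell), 0, gz - 1);
    for (int bz = bz0; bz <= bz1; ++bz)
      for (int by = by0; by <= by1; ++by)
        for (int bx = bx0; bx <= bx1; ++bx) {
          const std::vector<int> &b =
              bins[(size_t)bx + (size_t)gx * (by + (size_t)gy * bz)];
          for (size_t j = 0; j < b.size(); ++j) f(b[j]);
        }
  }
};

// ---------------------------------------------------------------------------
// Mean-shift refinement (flat kernel, synchronous updates)
// ---------------------------------------------------------------------------

// Each node's (p, r, c) moves to the unweighted mean over nodes within its
// own *initial* radius (anisotropy-aware distance); links are untouched by
// construction (the caller keeps them).
// [[Rcpp::export]]
List meanShiftCpp(NumericMatrix pos, NumericVector r, NumericVector c,
                  int iterations, NumericVector aspect) {
  const int n = pos.nrow();
  const double asp[3] = {aspect[0], aspect[1], aspect[2]};
  NumericMatrix curP(clone(pos));
  NumericVector curR(clone(r)), curC(clone(c));
  NumericVector r0(clone(r));  // kernel size fixed at the initial radius
  double rmax = 0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, r0[i]);

  for (int it = 0; it < iterations; ++it) {
    Grid3 grid(curP, asp, std::max(rmax, 1.0));
    NumericMatrix newP(n, 3);
    NumericVector newR(n), newC(n);
    for (int i = 0; i < n; ++i) {
      double xi = curP(i, 0) * asp[0];
      double yi = curP(i, 1) * asp[1];
      double zi = curP(i, 2) * asp[2];
      double rad = r0[i];
      double sx = 0, sy = 0, sz = 0, sr = 0, sc = 0;
      int cnt = 0;
      grid.forNeighborhood(xi, yi, zi, rad, [&](int j) {
        double dx = curP(j, 0) * asp[0] - xi;
        double dy = curP(j, 1) * asp[1] - yi;
        double dz = curP(j, 2) * asp[2] - zi;
        if (dx * dx + dy * dy + dz * dz <= rad * rad) {
          sx += curP(j, 0); sy += curP(j, 1); sz += curP(j, 2);
          sr += curR[j]; sc += curC[j];
          ++cnt;
        }
      });
      newP(i, 0) = sx / cnt; newP(i, 1) = sy / cnt; newP(i, 2) = sz / cnt;
      newR[i] = sr / cnt; newC[i] = sc / cnt;
    }
    curP = newP; curR = newR; curC = newC;
  }
  return List::create(_["pos"] = curP, _["r"] = curR, _["c"] = curC);
}

// ---------------------------------------------------------------------------
// Greedy node grouping
// ---------------------------------------------------------------------------

// order: 0-based indices sorted by decreasing correlation (ties: lower
// index first). Returns 1-based group membership per node.
// [[Rcpp::export]]
IntegerVector groupNodesCpp(NumericMatrix pos, IntegerVector order,
                            double rg, NumericVector aspect) {
  const int n = pos.nrow();
  const double asp[3] = {aspect[0], aspect[1], aspect[2]};
  IntegerVector group(n);
  Grid3 grid(pos, asp, std::max(rg, 1.0));
  int next = 0;
  for (int oi = 0; oi < n; ++oi) {
    int i = order[oi];
    if (group[i]) continue;
    ++next;
    double xi = pos(i, 0) * asp[0];
    double yi = pos(i, 1) * asp[1];
    double zi = pos(i, 2) * asp[2];
    grid.forNeighborhood(xi, yi, zi, rg, [&](int j) {
      if (group[j]) return;
      double dx = pos(j, 0) * asp[0] - xi;
      double dy = pos(j, 1) * asp[1] - yi;
      double dz = pos(j, 2) * asp[2] - zi;
      if (dx * dx + dy * dy + dz * dz <= rg * rg) group[j] = next;
    });
    group[i] = next;
  }
  return group;
}

// ---------------------------------------------------------------------------
// Nearest-neighbor distances between point sets
// ---------------------------------------------------------------------------

// For each row of a, the distance to the closest row of b (anisotropy-aware).
// [[Rcpp::export]]
NumericVector nnDistCpp(NumericMatrix a, NumericMatrix b,
                        NumericVector aspect) {
  const int na = a.nrow(), nb = b.nrow();
  const double asp[3] = {aspect[0], aspect[1], aspect[2]};
  NumericVector out(na);
  // bin b once; search outward in rings until a neighbor is found
  Grid3 grid(b, asp, 4.0);
  for (int i = 0; i < na; ++i) {
    double xi = a(i, 0) * asp[0];
    double yi = a(i, 1) * asp[1];
    double zi = a(i, 2) * asp[2];
    double best = R_PosInf;
    double radius = 4.0;
    for (int tries = 0; tries < 64; ++tries) {
      grid.forNeighborhood(xi, yi, zi, radius, [&](int j) {
        double dx = b(j, 0) * asp[0] - xi;
        double dy = b(j, 1) * asp[1] - yi;
        double dz = b(j, 2) * asp[2] - zi;
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < best) best = d2;
      });
      if (std::sqrt(best) <= radius) break;
      radius *= 2.0;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
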