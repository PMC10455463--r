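// Geometry kernels shared by the phantom, segmentation, reconstruction and
// implant-design stages.  All coordinates are in mm.  Solids are represented
// either as triangle meshes (V: n x 3, F: m x 3 1-based) or as scalar fields
// sampled on regular node grids (negative inside, positive outside), meshed
// back to triangles by marching tetrahedra on the Kuhn 6-tet cube split --
// the same decomposition the FE mesher uses, so surface and volume meshes
// are mutually consistent.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <functional>
#include <unordered_map>
#include <algorithm>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};
inline Vec3 v3(double x, double y, double z) { return Vec3{x, y, z}; }
inline Vec3 operator-(const Vec3 &a, const Vec3 &b) { return v3(a.x - b.x, a.y - b.y, a.z - b.z); }
inline Vec3 operator+(const Vec3 &a, const Vec3 &b) { return v3(a.x + b.x, a.y + b.y, a.z + b.z); }
inline Vec3 operator*(double s, const Vec3 &a) { return v3(s * a.x, s * a.y, s * a.z); }
inline double dot(const Vec3 &a, const Vec3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return v3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
inline double norm(const Vec3 &a) { return std::sqrt(dot(a, a)); }

// Ericson, Real-Time Collision Detection: closest point on triangle abc to p.
Vec3 closestPointTriangle(const Vec3 &p, const Vec3 &a, const Vec3 &b, const Vec3 &c) {
  Vec3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return a;
  Vec3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    return a + v * ab;
  }
  Vec3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    return a + w * ac;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return b + w * (c - b);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return a + v * ab + w * ac;
}

struct MeshRef {
  const double *V; // column-major n x 3
  const int *F;    // column-major m x 3, 1-based
  int nV, nF;
  Vec3 vert(int i) const { return v3(V[i], V[i + nV], V[i + 2 * nV]); }
  void tri(int f, Vec3 &a, Vec3 &b, Vec3 &c) const {
    a = vert(F[f] - 1);
    b = vert(F[f + nF] - 1);
    c = vert(F[f + 2 * nF] - 1);
  }
};

// ---- 2-D (y,z) row buckets for x-ray parity tests -------------------------

// Deterministic sub-micron ray jitter so rays never hit mesh edges/vertices
// of meshes aligned to the grid.
const double JIT_Y = 0.6180339887e-6;
const double JIT_Z = 0.7548776662e-6;

struct RowBuckets {
  // CSR layout: for each (j,k) row the triangle ids whose yz-bbox covers it.
  int ny, nz;
  double y0, z0, sy, sz;
  std::vector<int> start;
  std::vector<int> items;
};

void buildRowBuckets(const MeshRef &M, double y0, double sy, int ny, double z0,
                     double sz, int nz, RowBuckets &B) {
  B.ny = ny; B.nz = nz; B.y0 = y0; B.z0 = z0; B.sy = sy; B.sz = sz;
  std::vector<int> cnt((size_t)ny * nz, 0);
  std::vector<int> j0f(M.nF), j1f(M.nF), k0f(M.nF), k1f(M.nF);
  for (int f = 0; f < M.nF; ++f) {
    Vec3 a, b, c;
    M.tri(f, a, b, c);
    double ymin = std::min({a.y, b.y, c.y}), ymax = std::max({a.y, b.y, c.y});
    double zmin = std::min({a.z, b.z, c.z}), zmax = std::max({a.z, b.z, c.z});
    int j0 = (int)std::ceil((ymin - y0 - 1e-9) / sy - JIT_Y);
    int j1 = (int)std::floor((ymax - y0 + 1e-9) / sy - JIT_Y);
    int k0 = (int)std::ceil((zmin - z0 - 1e-9) / sz - JIT_Z);
    int k1 = (int)std::floor((zmax - z0 + 1e-9) / sz - JIT_Z);
    j0 = std::max(j0, 0); j1 = std::min(j1, ny - 1);
    k0 = std::max(k0, 0); k1 = std::min(k1, nz - 1);
    j0f[f] = j0; j1f[f] = j1; k0f[f] = k0; k1f[f] = k1;
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j) cnt[(size_t)k * ny + j]++;
  }
  B.start.assign((size_t)ny * nz + 1, 0);
  for (size_t i = 0; i < cnt.size(); ++i) B.start[i + 1] = B.start[i] + cnt[i];
  B.items.resize(B.start.back());
  std::vector<int> pos(B.start.begin(), B.start.end() - 1);
  for (int f = 0; f < M.nF; ++f)
    for (int k = k0f[f]; k <= k1f[f]; ++k)
      for (int j = j0f[f]; j <= j1f[f]; ++j)
        B.items[pos[(size_t)k * ny + j]++] = f;
}

// Interval-coverage buckets: triangle listed in every cell its yz-bbox
// overlaps (for arbitrary query points rather than grid rays).
void buildCellBuckets(const MeshRef &M, double y0, double sy, int ny, double z0,
                      double sz, int nz, RowBuckets &B) {
  B.ny = ny; B.nz = nz; B.y0 = y0; B.z0 = z0; B.sy = sy; B.sz = sz;
  std::vector<int> cnt((size_t)ny * nz, 0);
  std::vector<int> j0f(M.nF), j1f(M.nF), k0f(M.nF), k1f(M.nF);
  for (int f = 0; f < M.nF; ++f) {
    Vec3 a, b, c;
    M.tri(f, a, b, c);
    int j0 = std::max(0, (int)((std::min({a.y, b.y, c.y}) - y0) / sy));
    int j1 = std::min(ny - 1, (int)((std::max({a.y, b.y, c.y}) - y0) / sy));
    int k0 = std::max(0, (int)((std::min({a.z, b.z, c.z}) - z0) / sz));
    int k1 = std::min(nz - 1, (int)((std::max({a.z, b.z, c.z}) - z0) / sz));
    j0f[f] = j0; j1f[f] = j1; k0f[f] = k0; k1f[f] = k1;
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j) cnt[(size_t)k * ny + j]++;
  }
  B.start.assign((size_t)ny * nz + 1, 0);
  for (size_t i = 0; i < cnt.size(); ++i) B.start[i + 1] = B.start[i] + cnt[i];
  B.items.resize(B.start.back());
  std::vector<int> pos(B.start.begin(), B.start.end() - 1);
  for (int f = 0; f < M.nF; ++f)
    for (int k = k0f[f]; k <= k1f[f]; ++k)
      for (int j = j0f[f]; j <= j1f[f]; ++j)
        B.items[pos[(size_t)k * ny + j]++] = f;
}

// Crossing x-coordinates of the ray (y,z) = const with the mesh.
void rayCrossings(const MeshRef &M, const RowBuckets &B, int j, int k,
                  std::vector<double> &xs) {
  xs.clear();
  double yr = B.y0 + (j + JIT_Y) * B.sy;
  double zr = B.z0 + (k + JIT_Z) * B.sz;
  size_t row = (size_t)k * B.ny + j;
  for (int idx = B.start[row]; idx < B.start[row + 1]; ++idx) {
    int f = B.items[idx];
    Vec3 a, b, c;
    M.tri(f, a, b, c);
    double d11 = b.y - a.y, d12 = c.y - a.y;
    double d21 = b.z - a.z, d22 = c.z - a.z;
    double det = d11 * d22 - d12 * d21;
    if (std::fabs(det) < 1e-14) continue; // triangle parallel to the ray
    double py = yr - a.y, pz = zr - a.z;
    double u = (py * d22 - pz * d12) / det;
    double v = (d11 * pz - d21 * py) / det;
    if (u < 0.0 || v < 0.0 || u + v > 1.0) continue;
    xs.push_back(a.x + u * (b.x - a.x) + v * (c.x - a.x));
  }
  std::sort(xs.begin(), xs.end());
}

// ---- 3-D triangle buckets for distance queries ----------------------------

struct TriBuckets {
  int nx, ny, nz;
  double ox, oy, oz, cell;
  std::vector<int> start;
  std::vector<int> items;
  size_t idx(int i, int j, int k) const {
    return ((size_t)k * ny + j) * nx + i;
  }
};

void buildTriBuckets(const MeshRef &M, double cell, TriBuckets &B) {
  double xmin = R_PosInf, ymin = R_PosInf, zmin = R_PosInf;
  double xmax = R_NegInf, ymax = R_NegInf, zmax = R_NegInf;
  for (int i = 0; i < M.nV; ++i) {
    Vec3 p = M.vert(i);
    xmin = std::min(xmin, p.x); xmax = std::max(xmax, p.x);
    ymin = std::min(ymin, p.y); ymax = std::max(ymax, p.y);
    zmin = std::min(zmin, p.z); zmax = std::max(zmax, p.z);
  }
  B.cell = cell;
  B.ox = xmin - 0.5 * cell; B.oy = ymin - 0.5 * cell; B.oz = zmin - 0.5 * cell;
  B.nx = std::max(1, (int)std::ceil((xmax - B.ox) / cell) + 1);
  B.ny = std::max(1, (int)std::ceil((ymax - B.oy) / cell) + 1);
  B.nz = std::max(1, (int)std::ceil((zmax - B.oz) / cell) + 1);
  std::vector<int> cnt((size_t)B.nx * B.ny * B.nz, 0);
  std::vector<std::array<int, 6>> rng(M.nF);
  for (int f = 0; f < M.nF; ++f) {
    Vec3 a, b, c;
    M.tri(f, a, b, c);
    int i0 = std::max(0, (int)((std::min({a.x, b.x, c.x}) - B.ox) / cell));
    int i1 = std::min(B.nx - 1, (int)((std::max({a.x, b.x, c.x}) - B.ox) / cell));
    int j0 = std::max(0, (int)((std::min({a.y, b.y, c.y}) - B.oy) / cell));
    int j1 = std::min(B.ny - 1, (int)((std::max({a.y, b.y, c.y}) - B.oy) / cell));
    int k0 = std::max(0, (int)((std::min({a.z, b.z, c.z}) - B.oz) / cell));
    int k1 = std::min(B.nz - 1, (int)((std::max({a.z, b.z, c.z}) - B.oz) / cell));
    rng[f] = {i0, i1, j0, j1, k0, k1};
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i) cnt[B.idx(i, j, k)]++;
  }
  B.start.assign((size_t)B.nx * B.ny * B.nz + 1, 0);
  for (size_t i = 0; i < cnt.size(); ++i) B.start[i + 1] = B.start[i] + cnt[i];
  B.items.resize(B.start.back());
  std::vector<int> pos(B.start.begin(), B.start.end() - 1);
  for (int f = 0; f < M.nF; ++f)
    for (int k = rng[f][4]; k <= rng[f][5]; ++k)
      for (int j = rng[f][2]; j <= rng[f][3]; ++j)
        for (int i = rng[f][0]; i <= rng[f][1]; ++i)
          B.items[pos[B.idx(i, j, k)]++] = f;
}

// Nearest triangle within the 27-cell neighbourhood (covers radius >= cell).
// Returns squared distance or +Inf if nothing within range.
double nearestInNeighbourhood(const MeshRef &M, const TriBuckets &B, const Vec3 &p,
                              int &bestFace, Vec3 &bestPoint) {
  int ci = std::min(B.nx - 1, std::max(0, (int)((p.x - B.ox) / B.cell)));
  int cj = std::min(B.ny - 1, std::max(0, (int)((p.y - B.oy) / B.cell)));
  int ck = std::min(B.nz - 1, std::max(0, (int)((p.z - B.oz) / B.cell)));
  double best = R_PosInf;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        int i = ci + di, j = cj + dj, k = ck + dk;
        if (i < 0 || j < 0 || k < 0 || i >= B.nx || j >= B.ny || k >= B.nz) continue;
        size_t cell = B.idx(i, j, k);
        for (int t = B.start[cell]; t < B.start[cell + 1]; ++t) {
          int f = B.items[t];
          Vec3 a, b, c;
          M.tri(f, a, b, c);
          Vec3 q = closestPointTriangle(p, a, b, c);
          double d2 = dot(p - q, p - q);
          if (d2 < best) { best = d2; bestFace = f; bestPoint = q; }
        }
      }
  return best;
}

// Nearest query with expanding shells; `maxShellCap` (< 0 = unlimited)
// bounds the search for narrow-band callers that accept a miss.
double nearestExpanding(const MeshRef &M, const TriBuckets &B, const Vec3 &p,
                        int &bestFace, Vec3 &bestPoint, int maxShellCap = -1) {
  int ci = std::min(B.nx - 1, std::max(0, (int)((p.x - B.ox) / B.cell)));
  int cj = std::min(B.ny - 1, std::max(0, (int)((p.y - B.oy) / B.cell)));
  int ck = std::min(B.nz - 1, std::max(0, (int)((p.z - B.oz) / B.cell)));
  double best = R_PosInf;
  int maxShell = std::max({B.nx, B.ny, B.nz});
  if (maxShellCap >= 0) maxShell = std::min(maxShell, maxShellCap);
  for (int s = 0; s <= maxShell; ++s) {
    // once a candidate is known, stop when the next shell cannot beat it
    if (best < R_PosInf) {
      double lower = (s - 1) * B.cell; // conservative shell lower bound
      if (lower > 0 && lower * lower > best) break;
    }
    bool any = false;
    for (int dk = -s; dk <= s; ++dk)
      for (int dj = -s; dj <= s; ++dj)
        for (int di = -s; di <= s; ++di) {
          if (std::max({std::abs(di), std::abs(dj), std::abs(dk)}) != s) continue;
          int i = ci + di, j = cj + dj, k = ck + dk;
          if (i < 0 || j < 0 || k < 0 || i >= B.nx || j >= B.ny || k >= B.nz) continue;
          any = true;
          size_t cell = B.idx(i, j, k);
          for (int t = B.start[cell]; t < B.start[cell + 1]; ++t) {
            int f = B.items[t];
            Vec3 a, b, c;
            M.tri(f, a, b, c);
            Vec3 q = closestPointTriangle(p, a, b, c);
            double d2 = dot(p - q, p - q);
            if (d2 < best) { best = d2; bestFace = f; bestPoint = q; }
          }
        }
    if (!any && s > 0 && best < R_PosInf) break;
  }
  return best;
}

} // namespace

// [[Rcpp::export]]
LogicalVector cpp_points_in_mesh(NumericMatrix V, IntegerMatrix F, NumericMatrix P) {
  MeshRef M{REAL(V), INTEGER(F), (int)V.nrow(), (int)F.nrow()};
  int n = P.nrow();
  LogicalVector inside(n);
  // bucket query points into rows of a grid matched to typical point spacing
  double ymin = R_PosInf, ymax = R_NegInf, zmin = R_PosInf, zmax = R_NegInf;
  for (int i = 0; i < M.nV; ++i) {
    Vec3 p = M.vert(i);
    ymin = std::min(ymin, p.y); ymax = std::max(ymax, p.y);
    zmin = std::min(zmin, p.z); zmax = std::max(zmax, p.z);
  }
  // per-point rays (no shared rows): reuse the row-bucket structure with a
  // moderately fine pitch and recompute crossings per unique row cell
  double pitch = std::max({(ymax - ymin) / 256.0, (zmax - zmin) / 256.0, 1e-6});
  int ny = (int)std::floor((ymax - ymin) / pitch) + 2;
  int nz = (int)std::floor((zmax - zmin) / pitch) + 2;
  RowBuckets B;
  buildCellBuckets(M, ymin, pitch, ny, zmin, pitch, nz, B);
  std::vector<double> xs;
  for (int q = 0; q < n; ++q) {
    double px = P(q, 0), py = P(q, 1), pz = P(q, 2);
    if (py < ymin || py > ymax || pz < zmin || pz > zmax) { inside[q] = false; continue; }
    int j = std::min(ny - 1, std::max(0, (int)((py - ymin) / pitch)));
    int k = std::min(nz - 1, std::max(0, (int)((pz - zmin) / pitch)));
    // ray at the query's own (y,z), nudged off any lattice-aligned edges
    double yr = py + 1.1e-9, zr = pz + 1.7e-9;
    size_t row = (size_t)k * B.ny + j;
    int crossBelow = 0;
    for (int idx = B.start[row]; idx < B.start[row + 1]; ++idx) {
      int f = B.items[idx];
      Vec3 a, b, c;
      M.tri(f, a, b, c);
      double d11 = b.y - a.y, d12 = c.y - a.y;
      double d21 = b.z - a.z, d22 = c.z - a.z;
      double det = d11 * d22 - d12 * d21;
      if (std::fabs(det) < 1e-14) continue;
      double qy = yr - a.y, qz = zr - a.z;
      double u = (qy * d22 - qz * d12) / det;
      double v = (d11 * qz - d21 * qy) / det;
      if (u < 0.0 || v < 0.0 || u + v > 1.0) continue;
      double xc = a.x + u * (b.x - a.x) + v * (c.x - a.x);
      if (xc < px) crossBelow++;
    }
    inside[q] = (crossBelow % 2) == 1;
    (void)xs;
  }
  return inside;
}

// ---- persistent inside-test handle ----------------------------------------

struct InsideQuery {
  std::vector<double> V;
  std::vector<int> F;
  int nV, nF;
  RowBuckets B;
  double ymin, ymax, zmin, zmax, pitch;
  MeshRef ref() const { return MeshRef{V.data(), F.data(), nV, nF}; }
};

// [[Rcpp::export]]
SEXP cpp_inside_query_build(NumericMatrix V, IntegerMatrix F) {
  InsideQuery *q = new InsideQuery();
  q->nV = V.nrow();
  q->nF = F.nrow();
  q->V.assign(REAL(V), REAL(V) + (size_t)q->nV * 3);
  q->F.assign(INTEGER(F), INTEGER(F) + (size_t)q->nF * 3);
  MeshRef M = q->ref();
  double ymin = R_PosInf, ymax = R_NegInf, zmin = R_PosInf, zmax = R_NegInf;
  for (int i = 0; i < M.nV; ++i) {
    Vec3 p = M.vert(i);
    ymin = std::min(ymin, p.y); ymax = std::max(ymax, p.y);
    zmin = std::min(zmin, p.z); zmax = std::max(zmax, p.z);
  }
  q->ymin = ymin; q->ymax = ymax; q->zmin = zmin; q->zmax = zmax;
  q->pitch = std::max({(ymax - ymin) / 256.0, (zmax - zmin) / 256.0, 1e-6});
  int ny = (int)std::floor((ymax - ymin) / q->pitch) + 2;
  int nz = (int)std::floor((zmax - zmin) / q->pitch) + 2;
  buildCellBuckets(M, ymin, q->pitch, ny, zmin, q->pitch, nz, q->B);
  Rcpp::XPtr<InsideQuery> ptr(q, true);
  return ptr;
}

// [[Rcpp::export]]
LogicalVector cpp_inside_query(SEXP handle, NumericMatrix P) {
  Rcpp::XPtr<InsideQuery> q(handle);
  MeshRef M = q->ref();
  int n = P.nrow();
  LogicalVector inside(n);
  for (int i = 0; i < n; ++i) {
    double px = P(i, 0), py = P(i, 1), pz = P(i, 2);
    if (py < q->ymin || py > q->ymax || pz < q->zmin || pz > q->zmax) {
      inside[i] = false;
      continue;
    }
    int j = std::min(q->B.ny - 1, std::max(0, (int)((py - q->ymin) / q->pitch)));
    int k = std::min(q->B.nz - 1, std::max(0, (int)((pz - q->zmin) / q->pitch)));
    double yr = py + 1.1e-9, zr = pz + 1.7e-9;
    size_t row = (size_t)k * q->B.ny + j;
    int crossBelow = 0;
    for (int idx = q->B.start[row]; idx < q->B.start[row + 1]; ++idx) {
      int f = q->B.items[idx];
      Vec3 a, b, c;
      M.tri(f, a, b, c);
      double d11 = b.y - a.y, d12 = c.y - a.y;
      double d21 = b.z - a.z, d22 = c.z - a.z;
      double det = d11 * d22 - d12 * d21;
      if (std::fabs(det) < 1e-14) continue;
      double qy = yr - a.y, qz = zr - a.z;
      double u = (qy * d22 - qz * d12) / det;
      double v = (d11 * qz - d21 * qy) / det;
      if (u < 0.0 || v < 0.0 || u + v > 1.0) continue;
      double xc = a.x + u * (b.x - a.x) + v * (c.x - a.x);
      if (xc < px) crossBelow++;
    }
    inside[i] = (crossBelow % 2) == 1;
  }
  return inside;
}

// Signed distance field sampled at nodes world = origin + index * spacing.
// Exact distance within `band` of the surface, clamped to +/- band elsewhere;
// sign from x-ray parity (negative inside).
// [[Rcpp::export]]
NumericVector cpp_sdf_grid(NumericMatrix V, IntegerMatrix F, NumericVector origin,
                           NumericVector spacing, IntegerVector dims, double band) {
  MeshRef M{REAL(V), INTEGER(F), (int)V.nrow(), (int)F.nrow()};
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t N = (size_t)nx * ny * nz;
  NumericVector out(N);
  double ox = origin[0], oy = origin[1], oz = origin[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];

  RowBuckets B;
  buildRowBuckets(M, oy, sy, ny, oz, sz, nz, B);
  std::vector<signed char> sgn(N, 1);
  std::vector<double> xs;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      rayCrossings(M, B, j, k, xs);
      if (xs.empty()) continue;
      size_t base = ((size_t)k * ny + j) * (size_t)1; // row offset handled below
      size_t ptr = 0;
      for (int i = 0; i < nx; ++i) {
        double x = ox + i * sx;
        while (ptr < xs.size() && xs[ptr] < x) ++ptr;
        if (ptr % 2 == 1) sgn[((size_t)k * ny + j) * nx + i] = -1;
      }
      (void)base;
    }
  }

  // frontier: nodes adjacent to a sign change, dilated to cover the band
  std::vector<uint8_t> mark(N, 0);
  auto id = [&](int i, int j, int k) { return ((size_t)k * ny + j) * nx + i; };
  std::vector<size_t> frontier;
  auto markNode = [&](size_t c) {
    if (!mark[c]) { mark[c] = 1; frontier.push_back(c); }
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t c = id(i, j, k);
        signed char s = sgn[c];
        if (i + 1 < nx && sgn[id(i + 1, j, k)] != s) { markNode(c); markNode(id(i + 1, j, k)); }
        if (j + 1 < ny && sgn[id(i, j + 1, k)] != s) { markNode(c); markNode(id(i, j + 1, k)); }
        if (k + 1 < nz && sgn[id(i, j, k + 1)] != s) { markNode(c); markNode(id(i, j, k + 1)); }
      }
  double minsp = std::min({sx, sy, sz});
  int layers = std::max(1, (int)std::ceil(band / minsp));
  std::vector<size_t> cur = frontier;
  for (int L = 1; L < layers; ++L) {
    std::vector<size_t> nxt;
    for (size_t c : cur) {
      int i = (int)(c % nx), j = (int)((c / nx) % ny), k = (int)(c / ((size_t)nx * ny));
      const int d[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (auto &dd : d) {
        int ii = i + dd[0], jj = j + dd[1], kk = k + dd[2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        size_t cc = id(ii, jj, kk);
        if (!mark[cc]) { mark[cc] = 1; nxt.push_back(cc); frontier.push_back(cc); }
      }
    }
    cur.swap(nxt);
  }

  // fine buckets + bounded expanding search: frontier nodes lie within a
  // voxel or two of the surface, so queries stay local
  TriBuckets TB;
  double area2 = 0;
  for (int f = 0; f < M.nF; ++f) {
    Vec3 a, b, c;
    M.tri(f, a, b, c);
    area2 += norm(cross(b - a, c - a));
  }
  double meanTri = std::sqrt(std::max(1e-12, area2 / (2.0 * std::max(1, M.nF))));
  double cell = std::max({minsp, 2.0 * meanTri, 1e-6});
  buildTriBuckets(M, cell, TB);
  int shellCap = (int)std::ceil(band / cell) + 1;
  for (size_t q = 0; q < N; ++q) out[q] = sgn[q] * band;
  for (size_t c : frontier) {
    int i = (int)(c % nx), j = (int)((c / nx) % ny), k = (int)(c / ((size_t)nx * ny));
    Vec3 p = v3(ox + i * sx, oy + j * sy, oz + k * sz);
    int bf = -1;
    Vec3 bp;
    double d2 = nearestExpanding(M, TB, p, bf, bp, shellCap);
    double d = (d2 < R_PosInf) ? std::sqrt(d2) : band;
    if (d > band) d = band;
    out[c] = sgn[c] * d;
  }
  return out;
}

// Occupancy (inside test) at nodes world = origin + index * spacing.
// [[Rcpp::export]]
LogicalVector cpp_inside_grid(NumericMatrix V, IntegerMatrix F, NumericVector origin,
                              NumericVector spacing, IntegerVector dims) {
  MeshRef M{REAL(V), INTEGER(F), (int)V.nrow(), (int)F.nrow()};
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t N = (size_t)nx * ny * nz;
  LogicalVector out(N);
  RowBuckets B;
  buildRowBuckets(M, origin[1], spacing[1], ny, origin[2], spacing[2], nz, B);
  std::vector<double> xs;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      rayCrossings(M, B, j, k, xs);
      if (xs.empty()) continue;
      size_t ptr = 0;
      for (int i = 0; i < nx; ++i) {
        double x = origin[0] + i * spacing[0];
        while (ptr < xs.size() && xs[ptr] < x) ++ptr;
        if (ptr % 2 == 1) out[((size_t)k * ny + j) * nx + i] = true;
      }
    }
  return out;
}

// Closest-point query: distance, face index (1-based) and closest point for
// each query point.
// [[Rcpp::export]]
List cpp_points_to_mesh(NumericMatrix V, IntegerMatrix F, NumericMatrix P) {
  MeshRef M{REAL(V), INTEGER(F), (int)V.nrow(), (int)F.nrow()};
  // bucket cell ~ few median triangle sizes keeps lists short but queries local
  double area2 = 0;
  for (int f = 0; f < M.nF; ++f) {
    Vec3 a, b, c;
    M.tri(f, a, b, c);
    area2 += norm(cross(b - a, c - a));
  }
  double meanTri = std::sqrt(std::max(1e-12, area2 / (2.0 * M.nF)));
  TriBuckets B;
  buildTriBuckets(M, std::max(meanTri * 4.0, 1e-6), B);
  int n = P.nrow();
  NumericVector dist(n);
  IntegerVector face(n);
  NumericMatrix cp(n, 3);
  for (int q = 0; q < n; ++q) {
    Vec3 p = v3(P(q, 0), P(q, 1), P(q, 2));
    int bf = -1;
    Vec3 bp = p;
    double d2 = nearestExpanding(M, B, p, bf, bp);
    dist[q] = std::sqrt(d2);
    face[q] = bf + 1;
    cp(q, 0) = bp.x; cp(q, 1) = bp.y; cp(q, 2) = bp.z;
  }
  return List::create(_["distance"] = dist, _["face"] = face, _["point"] = cp);
}

// ---- persistent mesh query handle -----------------------------------------

struct MeshQuery {
  std::vector<double> V;
  std::vector<int> F;
  int nV, nF;
  TriBuckets B;
  MeshRef ref() const { return MeshRef{V.data(), F.data(), nV, nF}; }
};

// Build a reusable closest-point query structure (spatial buckets are built
// once; repeated queries -- ICP iterations -- stay cheap).
// [[Rcpp::export]]
SEXP cpp_mesh_query_build(NumericMatrix V, IntegerMatrix F) {
  MeshQuery *q = new MeshQuery();
  q->nV = V.nrow();
  q->nF = F.nrow();
  q->V.assign(REAL(V), REAL(V) + (size_t)q->nV * 3);
  q->F.assign(INTEGER(F), INTEGER(F) + (size_t)q->nF * 3);
  MeshRef M = q->ref();
  double area2 = 0;
  for (int f = 0; f < M.nF; ++f) {
    Vec3 a, b, c;
    M.tri(f, a, b, c);
    area2 += norm(cross(b - a, c - a));
  }
  double meanTri = std::sqrt(std::max(1e-12, area2 / (2.0 * std::max(1, M.nF))));
  buildTriBuckets(M, std::max(meanTri * 4.0, 1e-6), q->B);
  Rcpp::XPtr<MeshQuery> ptr(q, true);
  return ptr;
}

// [[Rcpp::export]]
List cpp_mesh_query(SEXP handle, NumericMatrix P) {
  Rcpp::XPtr<MeshQuery> q(handle);
  MeshRef M = q->ref();
  int n = P.nrow();
  NumericVector dist(n);
  IntegerVector face(n);
  NumericMatrix cp(n, 3);
  for (int i = 0; i < n; ++i) {
    Vec3 p = v3(P(i, 0), P(i, 1), P(i, 2));
    int bf = -1;
    Vec3 bp = p;
    double d2 = nearestExpanding(M, q->B, p, bf, bp);
    dist[i] = std::sqrt(d2);
    face[i] = bf + 1;
    cp(i, 0) = bp.x; cp(i, 1) = bp.y; cp(i, 2) = bp.z;
  }
  return List::create(_["distance"] = dist, _["face"] = face, _["point"] = cp);
}

// Divergence-theorem signed volume (positive for outward orientation).
// [[Rcpp::export]]
double cpp_mesh_volume(NumericMatrix V, IntegerMatrix F) {
  MeshRef M{REAL(V), INTEGER(F), (int)V.nrow(), (int)F.nrow()};
  double vol = 0;
  for (int f = 0; f < M.nF; ++f) {
    Vec3 a, b, c;
    M.tri(f, a, b, c);
    vol += dot(a, cross(b, c));
  }
  return vol / 6.0;
}

// [[Rcpp::export]]
double cpp_mesh_area(NumericMatrix V, IntegerMatrix F) {
  MeshRef M{REAL(V), INTEGER(F), (int)V.nrow(), (int)F.nrow()};
  double area = 0;
  for (int f = 0; f < M.nF; ++f) {
    Vec3 a, b, c;
    M.tri(f, a, b, c);
    area += 0.5 * norm(cross(b - a, c - a));
  }
  return area;
}

// Edge audit: closed (every edge in exactly two faces) and consistently
// oriented (the two incident faces traverse the edge in opposite directions).
// [[Rcpp::export]]
List cpp_edge_audit(IntegerMatrix F) {
  int m = F.nrow();
  std::unordered_map<uint64_t, int> net, tot;
  net.reserve((size_t)m * 3);
  tot.reserve((size_t)m * 3);
  for (int f = 0; f < m; ++f) {
    int v[3] = {F(f, 0), F(f, 1), F(f, 2)};
    for (int e = 0; e < 3; ++e) {
      int a = v[e], b = v[(e + 1) % 3];
      uint64_t key = (uint64_t)std::min(a, b) * 0x100000000ULL + std::max(a, b);
      tot[key] += 1;
      net[key] += (a < b) ? 1 : -1;
    }
  }
  int nBoundary = 0, nNonManifold = 0, nMisoriented = 0;
  for (auto &kv : tot) {
    if (kv.second == 1) nBoundary++;
    else if (kv.second > 2) nNonManifold++;
    else if (net[kv.first] != 0) nMisoriented++;
  }
  return List::create(_["closed"] = (nBoundary == 0 && nNonManifold == 0),
                      _["oriented"] = (nMisoriented == 0),
                      _["n_boundary_edges"] = nBoundary,
                      _["n_nonmanifold_edges"] = nNonManifold);
}

// ---- marching tetrahedra ---------------------------------------------------

// Kuhn 6-tet split of each grid cell (all tets share the 0-7 diagonal);
// translation-invariant, hence face-to-face conforming across cells.
static const int KUHN[6][4] = {
  {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
  {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};

// [[Rcpp::export]]
List cpp_marching_tets(NumericVector field, IntegerVector dims, NumericVector origin,
                       NumericVector spacing, double level) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *f = REAL(field);
  auto id = [&](int i, int j, int k) { return ((size_t)k * ny + j) * nx + i; };
  std::vector<double> vx, vy, vz;
  std::vector<int> tris;
  std::unordered_map<uint64_t, int> edgeMap;
  edgeMap.reserve(1 << 16);
  double ox = origin[0], oy = origin[1], oz = origin[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];

  auto nodePos = [&](size_t c, Vec3 &p) {
    int i = (int)(c % nx), j = (int)((c / nx) % ny), k = (int)(c / ((size_t)nx * ny));
    p = v3(ox + i * sx, oy + j * sy, oz + k * sz);
  };
  std::unordered_map<uint64_t, int> nodeVert; // crossings that land on a node
  auto nodePoint = [&](size_t a) -> int {
    auto it = nodeVert.find((uint64_t)a);
    if (it != nodeVert.end()) return it->second;
    Vec3 p;
    nodePos(a, p);
    int idx = (int)vx.size();
    vx.push_back(p.x); vy.push_back(p.y); vz.push_back(p.z);
    nodeVert[(uint64_t)a] = idx;
    return idx;
  };
  auto edgePoint = [&](size_t a, size_t b) -> int {
    if (a > b) std::swap(a, b);
    double fa = f[a], fb = f[b];
    double t = (level - fa) / (fb - fa);
    // crossings at (or numerically at) a grid node are shared by all edges
    // through that node; keying them by the node avoids zero-area slivers
    if (t <= 1e-9) return nodePoint(a);
    if (t >= 1.0 - 1e-9) return nodePoint(b);
    uint64_t key = (uint64_t)a * 0x200000000ULL + b; // grids stay < 2^33 nodes
    auto it = edgeMap.find(key);
    if (it != edgeMap.end()) return it->second;
    Vec3 pa, pb;
    nodePos(a, pa);
    nodePos(b, pb);
    Vec3 p = pa + t * (pb - pa);
    int idx = (int)vx.size();
    vx.push_back(p.x); vy.push_back(p.y); vz.push_back(p.z);
    edgeMap[key] = idx;
    return idx;
  };
  // Within a tet the interpolant is linear, so its level set is a plane
  // perpendicular to the (constant) gradient; orienting by the gradient is
  // exact even for sliver triangles.
  auto pushTri = [&](int p0, int p1, int p2, const Vec3 &grad) {
    if (p0 == p1 || p1 == p2 || p0 == p2) return; // degenerate sliver
    Vec3 a = v3(vx[p0], vy[p0], vz[p0]);
    Vec3 b = v3(vx[p1], vy[p1], vz[p1]);
    Vec3 c = v3(vx[p2], vy[p2], vz[p2]);
    Vec3 n = cross(b - a, c - a);
    if (dot(n, grad) >= 0) {
      tris.push_back(p0); tris.push_back(p1); tris.push_back(p2);
    } else {
      tris.push_back(p0); tris.push_back(p2); tris.push_back(p1);
    }
  };
  // gradient of the linear interpolant on a tet
  auto tetGradient = [&](const size_t nd[4]) -> Vec3 {
    Vec3 p0, p1, p2, p3;
    nodePos(nd[0], p0); nodePos(nd[1], p1);
    nodePos(nd[2], p2); nodePos(nd[3], p3);
    Vec3 e1 = p1 - p0, e2 = p2 - p0, e3 = p3 - p0;
    double det = dot(e1, cross(e2, e3));
    Vec3 g1 = (1.0 / det) * cross(e2, e3);
    Vec3 g2 = (1.0 / det) * cross(e3, e1);
    Vec3 g3 = (1.0 / det) * cross(e1, e2);
    double d1 = f[nd[1]] - f[nd[0]], d2 = f[nd[2]] - f[nd[0]], d3 = f[nd[3]] - f[nd[0]];
    return v3(d1 * g1.x + d2 * g2.x + d3 * g3.x,
              d1 * g1.y + d2 * g2.y + d3 * g3.y,
              d1 * g1.z + d2 * g2.z + d3 * g3.z);
  };

  size_t corner[8];
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        corner[0] = id(i, j, k);       corner[1] = id(i + 1, j, k);
        corner[2] = id(i, j + 1, k);   corner[3] = id(i + 1, j + 1, k);
        corner[4] = id(i, j, k + 1);   corner[5] = id(i + 1, j, k + 1);
        corner[6] = id(i, j + 1, k + 1); corner[7] = id(i + 1, j + 1, k + 1);
        int nin = 0;
        for (int c = 0; c < 8; ++c) nin += (f[corner[c]] < level);
        if (nin == 0 || nin == 8) continue;
        for (int t = 0; t < 6; ++t) {
          size_t n0 = corner[KUHN[t][0]], n1 = corner[KUHN[t][1]];
          size_t n2 = corner[KUHN[t][2]], n3 = corner[KUHN[t][3]];
          size_t nd[4] = {n0, n1, n2, n3};
          bool in[4];
          int cnt = 0;
          for (int c = 0; c < 4; ++c) { in[c] = f[nd[c]] < level; cnt += in[c]; }
          if (cnt == 0 || cnt == 4) continue;
          Vec3 grad = tetGradient(nd);
          if (cnt == 1 || cnt == 3) {
            int pivot = -1;
            for (int c = 0; c < 4; ++c)
              if (in[c] == (cnt == 1)) pivot = c;
            int e[3], m = 0;
            for (int c = 0; c < 4; ++c)
              if (c != pivot) e[m++] = edgePoint(nd[pivot], nd[c]);
            pushTri(e[0], e[1], e[2], grad);
          } else {
            int ia[2], ob[2], na = 0, nb = 0;
            for (int c = 0; c < 4; ++c) (in[c] ? ia[na++] : ob[nb++]) = c;
            int pac = edgePoint(nd[ia[0]], nd[ob[0]]);
            int pad = edgePoint(nd[ia[0]], nd[ob[1]]);
            int pbc = edgePoint(nd[ia[1]], nd[ob[0]]);
            int pbd = edgePoint(nd[ia[1]], nd[ob[1]]);
            pushTri(pac, pad, pbd, grad);
            pushTri(pac, pbd, pbc, grad);
          }
        }
      }

  // compact: drop vertices left unreferenced by degenerate-triangle culling
  int nVAll = (int)vx.size(), nT = (int)tris.size() / 3;
  std::vector<int> remap(nVAll, -1);
  int nV = 0;
  for (size_t q = 0; q < tris.size(); ++q)
    if (remap[tris[q]] < 0) remap[tris[q]] = nV++;
  NumericMatrix V(nV, 3);
  IntegerMatrix F(nT, 3);
  for (int i = 0; i < nVAll; ++i)
    if (remap[i] >= 0) {
      V(remap[i], 0) = vx[i]; V(remap[i], 1) = vy[i]; V(remap[i], 2) = vz[i];
    }
  for (int t = 0; t < nT; ++t) {
    F(t, 0) = remap[tris[3 * t]] + 1;
    F(t, 1) = remap[tris[3 * t + 1]] + 1;
    F(t, 2) = remap[tris[3 * t + 2]] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// ---- segment distance fields (lattice struts) ------------------------------

static inline double segDist2(const Vec3 &p, const Vec3 &a, const Vec3 &b) {
  Vec3 ab = b - a;
  double t = dot(p - a, ab) / std::max(1e-30, dot(ab, ab));
  t = std::max(0.0, std::min(1.0, t));
  Vec3 q = a + t * ab;
  return dot(p - q, p - q);
}

// Min distance from each grid node to a set of segments, clamped at `clamp`.
// [[Rcpp::export]]
NumericVector cpp_segments_dist_grid(NumericMatrix segs, NumericVector origin,
                                     NumericVector spacing, IntegerVector dims,
                                     double clamp) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t N = (size_t)nx * ny * nz;
  NumericVector out(N, clamp);
  int ns = segs.nrow();
  double ox = origin[0], oy = origin[1], oz = origin[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  // scatter: for each segment, update nodes within clamp of its bbox
  for (int s = 0; s < ns; ++s) {
    Vec3 a = v3(segs(s, 0), segs(s, 1), segs(s, 2));
    Vec3 b = v3(segs(s, 3), segs(s, 4), segs(s, 5));
    int i0 = std::max(0, (int)std::ceil((std::min(a.x, b.x) - clamp - ox) / sx));
    int i1 = std::min(nx - 1, (int)std::floor((std::max(a.x, b.x) + clamp - ox) / sx));
    int j0 = std::max(0, (int)std::ceil((std::min(a.y, b.y) - clamp - oy) / sy));
    int j1 = std::min(ny - 1, (int)std::floor((std::max(a.y, b.y) + clamp - oy) / sy));
    int k0 = std::max(0, (int)std::ceil((std::min(a.z, b.z) - clamp - oz) / sz));
    int k1 = std::min(nz - 1, (int)std::floor((std::max(a.z, b.z) + clamp - oz) / sz));
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j) {
        size_t rowBase = ((size_t)k * ny + j) * nx;
        for (int i = i0; i <= i1; ++i) {
          Vec3 p = v3(ox + i * sx, oy + j * sy, oz + k * sz);
          double d = std::sqrt(segDist2(p, a, b));
          if (d < out[rowBase + i]) out[rowBase + i] = d;
        }
      }
  }
  return out;
}

// Unsigned distance from grid nodes to an (open) triangle soup, clamped;
// scatter formulation like the segment version.
// [[Rcpp::export]]
NumericVector cpp_tris_dist_grid(NumericMatrix V, IntegerMatrix F, NumericVector origin,
                                 NumericVector spacing, IntegerVector dims, double clamp) {
  MeshRef M{REAL(V), INTEGER(F), (int)V.nrow(), (int)F.nrow()};
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t N = (size_t)nx * ny * nz;
  NumericVector out(N, clamp);
  double ox = origin[0], oy = origin[1], oz = origin[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  for (int fidx = 0; fidx < M.nF; ++fidx) {
    Vec3 a, b, c;
    M.tri(fidx, a, b, c);
    int i0 = std::max(0, (int)std::ceil((std::min({a.x, b.x, c.x}) - clamp - ox) / sx));
    int i1 = std::min(nx - 1, (int)std::floor((std::max({a.x, b.x, c.x}) + clamp - ox) / sx));
    int j0 = std::max(0, (int)std::ceil((std::min({a.y, b.y, c.y}) - clamp - oy) / sy));
    int j1 = std::min(ny - 1, (int)std::floor((std::max({a.y, b.y, c.y}) + clamp - oy) / sy));
    int k0 = std::max(0, (int)std::ceil((std::min({a.z, b.z, c.z}) - clamp - oz) / sz));
    int k1 = std::min(nz - 1, (int)std::floor((std::max({a.z, b.z, c.z}) + clamp - oz) / sz));
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j) {
        size_t rowBase = ((size_t)k * ny + j) * nx;
        for (int i = i0; i <= i1; ++i) {
          Vec3 p = v3(ox + i * sx, oy + j * sy, oz + k * sz);
          Vec3 q = closestPointTriangle(p, a, b, c);
          double d = norm(p - q);
          if (d < out[rowBase + i]) out[rowBase + i] = d;
        }
      }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_points_segments_dist(NumericMatrix P, NumericMatrix segs) {
  int n = P.nrow(), ns = segs.nrow();
  NumericVector out(n, R_PosInf);
  for (int q = 0; q < n; ++q) {
    Vec3 p = v3(P(q, 0), P(q, 1), P(q, 2));
    double best = R_PosInf;
    for (int s = 0; s < ns; ++s) {
      Vec3 a = v3(segs(s, 0), segs(s, 1), segs(s, 2));
      Vec3 b = v3(segs(s, 3), segs(s, 4), segs(s, 5));
      best = std::min(best, segDist2(p, a, b));
    }
    out[q] = std::sqrt(best);
  }
  return out;
}

// ---- grayscale morphology (box structuring element) ------------------------

// Separable running min (op = 0) or max (op = 1) over a box of radius r
// voxels; used for the wrap stage's morphological closing on distance fields.
// [[Rcpp::export]]
NumericVector cpp_box_morph(NumericVector field, IntegerVector dims, int r, int op) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t N = (size_t)nx * ny * nz;
  std::vector<double> a(REAL(field), REAL(field) + N), b(N);
  auto pass = [&](int axis) {
    int n[3] = {nx, ny, nz};
    size_t stride[3] = {1, (size_t)nx, (size_t)nx * ny};
    int len = n[axis];
    size_t st = stride[axis];
    int o1 = (axis == 0) ? 1 : 0, o2 = (axis == 2) ? 1 : 2;
    for (int u = 0; u < n[o1]; ++u)
      for (int v = 0; v < n[o2]; ++v) {
        size_t base = (size_t)u * stride[o1] + (size_t)v * stride[o2];
        for (int i = 0; i < len; ++i) {
          double best = a[base + (size_t)i * st];
          for (int d = 1; d <= r; ++d) {
            if (i - d >= 0) {
              double val = a[base + (size_t)(i - d) * st];
              best = op ? std::max(best, val) : std::min(best, val);
            }
            if (i + d < len) {
              double val = a[base + (size_t)(i + d) * st];
              best = op ? std::max(best, val) : std::min(best, val);
            }
          }
          b[base + (size_t)i * st] = best;
        }
        for (int i = 0; i < len; ++i) a[base + (size_t)i * st] = b[base + (size_t)i * st];
      }
  };
  pass(0); pass(1); pass(2);
  NumericVector out(N);
  std::copy(a.begin(), a.end(), REAL(out));
  return out;
}

// Resample a field through an affine map: out(x) = f(A x + b) by trilinear
// interpolation on the same grid; positions outside the grid get `fill`.
// Used to mirror a solid's field across the midsagittal plane without
// re-extracting and re-sampling its surface.
// [[Rcpp::export]]
NumericVector cpp_resample_affine(NumericVector field, IntegerVector dims,
                                  NumericVector origin, NumericVector spacing,
                                  NumericMatrix A, NumericVector b, double fill) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t N = (size_t)nx * ny * nz;
  NumericVector out(N);
  const double *f = REAL(field);
  double a00 = A(0, 0), a01 = A(0, 1), a02 = A(0, 2);
  double a10 = A(1, 0), a11 = A(1, 1), a12 = A(1, 2);
  double a20 = A(2, 0), a21 = A(2, 1), a22 = A(2, 2);
  double ox = origin[0], oy = origin[1], oz = origin[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  auto id = [&](int i, int j, int k) { return ((size_t)k * ny + j) * nx + i; };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double x = ox + i * sx, y = oy + j * sy, z = oz + k * sz;
        double px = a00 * x + a01 * y + a02 * z + b[0];
        double py = a10 * x + a11 * y + a12 * z + b[1];
        double pz = a20 * x + a21 * y + a22 * z + b[2];
        double u = (px - ox) / sx, v = (py - oy) / sy, w = (pz - oz) / sz;
        int i0 = (int)std::floor(u), j0 = (int)std::floor(v), k0 = (int)std::floor(w);
        if (i0 < 0 || j0 < 0 || k0 < 0 || i0 + 1 >= nx || j0 + 1 >= ny || k0 + 1 >= nz) {
          out[id(i, j, k)] = fill;
          continue;
        }
        double du = u - i0, dv = v - j0, dw = w - k0;
        double c00 = f[id(i0, j0, k0)] * (1 - du) + f[id(i0 + 1, j0, k0)] * du;
        double c10 = f[id(i0, j0 + 1, k0)] * (1 - du) + f[id(i0 + 1, j0 + 1, k0)] * du;
        double c01 = f[id(i0, j0, k0 + 1)] * (1 - du) + f[id(i0 + 1, j0, k0 + 1)] * du;
        double c11 = f[id(i0, j0 + 1, k0 + 1)] * (1 - du) + f[id(i0 + 1, j0 + 1, k0 + 1)] * du;
        double c0 = c00 * (1 - dv) + c10 * dv;
        double c1 = c01 * (1 - dv) + c11 * dv;
        out[id(i, j, k)] = c0 * (1 - dw) + c1 * dw;
      }
  return out;
}

// ---- connected components --------------------------------------------------

// Label connected components of a voxel mask (26- or 6-connectivity),
// labels 1..n in decreasing component size order.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t N = (size_t)nx * ny * nz;
  IntegerVector labels(N, 0);
  const int *m = LOGICAL(mask);
  std::vector<std::array<int, 3>> offs;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        int man = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (connectivity == 6 && man > 1) continue;
        offs.push_back({di, dj, dk});
      }
  std::vector<size_t> stack;
  int next = 0;
  std::vector<std::pair<size_t, int>> sizes; // (size, label)
  for (size_t seed = 0; seed < N; ++seed) {
    if (!m[seed] || labels[seed]) continue;
    ++next;
    size_t count = 0;
    stack.clear();
    stack.push_back(seed);
    labels[seed] = next;
    while (!stack.empty()) {
      size_t c = stack.back();
      stack.pop_back();
      ++count;
      int i = (int)(c % nx), j = (int)((c / nx) % ny), k = (int)(c / ((size_t)nx * ny));
      for (auto &o : offs) {
        int ii = i + o[0], jj = j + o[1], kk = k + o[2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        size_t cc = ((size_t)kk * ny + jj) * nx + ii;
        if (m[cc] && !labels[cc]) { labels[cc] = next; stack.push_back(cc); }
      }
    }
    sizes.push_back({count, next});
  }
  // relabel so label 1 is the largest component
  std::sort(sizes.begin(), sizes.end(),
            [](const std::pair<size_t, int> &a, const std::pair<size_t, int> &b) {
              return a.first > b.first;
            });
  std::vector<int> remap(next + 1, 0);
  for (size_t r = 0; r < sizes.size(); ++r) remap[sizes[r].second] = (int)r + 1;
  for (size_t c = 0; c < N; ++c)
    if (labels[c]) labels[c] = remap[labels[c]];
  return labels;
}

// Mesh connected components over shared vertices; returns per-face component
// id (1-based, largest first).
// [[Rcpp::export]]
IntegerVector cpp_mesh_components(IntegerMatrix F, int nV) {
  int m = F.nrow();
  // union-find over vertices
  std::vector<int> parent(nV + 1);
  for (int i = 0; i <= nV; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  for (int f = 0; f < m; ++f) {
    int a = find(F(f, 0)), b = find(F(f, 1)), c = find(F(f, 2));
    parent[b] = a;
    parent[find(c)] = find(a);
  }
  std::unordered_map<int, int> sizes;
  std::vector<int> root(m);
  for (int f = 0; f < m; ++f) {
    root[f] = find(F(f, 0));
    sizes[root[f]]++;
  }
  std::vector<std::pair<int, int>> order; // (size, root)
  for (auto &kv : sizes) order.push_back({kv.second, kv.first});
  std::sort(order.begin(), order.end(),
            [](const std::pair<int, int> &a, const std::pair<int, int> &b) {
              return a.first > b.first;
            });
  std::unordered_map<int, int> relabel;
  for (size_t r = 0; r < order.size(); ++r) relabel[order[r].second] = (int)r + 1;
  IntegerVector out(m);
  for (int f = 0; f < m; ++f) out[f] = relabel[root[f]];
  return out;
}
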