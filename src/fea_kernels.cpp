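// Linear tetrahedral (tet4, constant-strain) finite-element kernels.
// Units: mm - N - MPa.  The volume mesher splits every occupied voxel of a
// labelled grid into the same 6 Kuhn tetrahedra used by the isosurfacer, so
// regions meshed on a common grid share interface nodes exactly (bonded
// contact by construction).

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <algorithm>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

static const int KUHN[6][4] = {
  {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
  {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};

// shape-function gradient setup for one tet; returns 6*volume, grads[4][3]
double tetGrads(const double *x, const double *y, const double *z, double g[4][3]) {
  double a[3] = {x[1] - x[0], y[1] - y[0], z[1] - z[0]};
  double b[3] = {x[2] - x[0], y[2] - y[0], z[2] - z[0]};
  double c[3] = {x[3] - x[0], y[3] - y[0], z[3] - z[0]};
  double det = a[0] * (b[1] * c[2] - b[2] * c[1]) -
               a[1] * (b[0] * c[2] - b[2] * c[0]) +
               a[2] * (b[0] * c[1] - b[1] * c[0]);
  // gradients of barycentric coords: rows of inverse Jacobian
  double inv[3][3];
  inv[0][0] = (b[1] * c[2] - b[2] * c[1]) / det;
  inv[0][1] = (b[2] * c[0] - b[0] * c[2]) / det;
  inv[0][2] = (b[0] * c[1] - b[1] * c[0]) / det;
  inv[1][0] = (c[1] * a[2] - c[2] * a[1]) / det;
  inv[1][1] = (c[2] * a[0] - c[0] * a[2]) / det;
  inv[1][2] = (c[0] * a[1] - c[1] * a[0]) / det;
  inv[2][0] = (a[1] * b[2] - a[2] * b[1]) / det;
  inv[2][1] = (a[2] * b[0] - a[0] * b[2]) / det;
  inv[2][2] = (a[0] * b[1] - a[1] * b[0]) / det;
  for (int d = 0; d < 3; ++d) {
    g[1][d] = inv[0][d];
    g[2][d] = inv[1][d];
    g[3][d] = inv[2][d];
    g[0][d] = -inv[0][d] - inv[1][d] - inv[2][d];
  }
  return det; // = 6 V
}

void isotropicD(double E, double nu, double D[6][6]) {
  double lam = E * nu / ((1 + nu) * (1 - 2 * nu));
  double mu = E / (2 * (1 + nu));
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 6; ++j) D[i][j] = 0;
  for (int i = 0; i < 3; ++i) {
    for (int j = 0; j < 3; ++j) D[i][j] = lam;
    D[i][i] = lam + 2 * mu;
    D[i + 3][i + 3] = mu;
  }
}

// B matrix (6 x 12): strain order xx, yy, zz, xy, yz, zx (engineering shear)
void buildB(const double g[4][3], double B[6][12]) {
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 12; ++j) B[i][j] = 0;
  for (int a = 0; a < 4; ++a) {
    int c = 3 * a;
    B[0][c] = g[a][0];
    B[1][c + 1] = g[a][1];
    B[2][c + 2] = g[a][2];
    B[3][c] = g[a][1]; B[3][c + 1] = g[a][0];
    B[4][c + 1] = g[a][2]; B[4][c + 2] = g[a][1];
    B[5][c] = g[a][2]; B[5][c + 2] = g[a][0];
  }
}

} // namespace

// Mesh every voxel with region > 0 into 6 tets.  region: voxel grid
// (nx*ny*nz, column-major i fastest).  Returns compacted node coordinates,
// elements (1-based into nodes) and per-element region labels.
// [[Rcpp::export]]
List cpp_grid_tets(IntegerVector region, IntegerVector dims, NumericVector origin,
                   NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int gx = nx + 1, gy = ny + 1;
  size_t nGridNodes = (size_t)gx * gy * (nz + 1);
  std::vector<int> nodeMap(nGridNodes, -1);
  std::vector<int> elemNodes;
  std::vector<int> elemRegion;
  std::vector<size_t> usedNodes;
  const int *reg = INTEGER(region);

  // orientation audit on the reference cube: swap last two nodes if negative
  bool swapTet[6];
  {
    double cx[8], cy[8], cz[8];
    for (int c = 0; c < 8; ++c) {
      cx[c] = (c & 1) ? 1 : 0;
      cy[c] = (c & 2) ? 1 : 0;
      cz[c] = (c & 4) ? 1 : 0;
    }
    for (int t = 0; t < 6; ++t) {
      double x[4], y[4], z[4], g[4][3];
      for (int a = 0; a < 4; ++a) {
        x[a] = cx[KUHN[t][a]]; y[a] = cy[KUHN[t][a]]; z[a] = cz[KUHN[t][a]];
      }
      swapTet[t] = tetGrads(x, y, z, g) < 0;
    }
  }

  auto gnode = [&](int i, int j, int k) { return ((size_t)k * gy + j) * gx + i; };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int r = reg[((size_t)k * ny + j) * nx + i];
        if (r <= 0) continue;
        size_t corner[8];
        for (int c = 0; c < 8; ++c)
          corner[c] = gnode(i + ((c & 1) ? 1 : 0), j + ((c & 2) ? 1 : 0),
                            k + ((c & 4) ? 1 : 0));
        int local[8];
        for (int c = 0; c < 8; ++c) {
          if (nodeMap[corner[c]] < 0) {
            nodeMap[corner[c]] = (int)usedNodes.size();
            usedNodes.push_back(corner[c]);
          }
          local[c] = nodeMap[corner[c]];
        }
        for (int t = 0; t < 6; ++t) {
          int n0 = local[KUHN[t][0]], n1 = local[KUHN[t][1]];
          int n2 = local[KUHN[t][2]], n3 = local[KUHN[t][3]];
          if (swapTet[t]) std::swap(n2, n3);
          elemNodes.push_back(n0 + 1);
          elemNodes.push_back(n1 + 1);
          elemNodes.push_back(n2 + 1);
          elemNodes.push_back(n3 + 1);
          elemRegion.push_back(r);
        }
      }

  int nn = (int)usedNodes.size();
  int ne = (int)elemRegion.size();
  NumericMatrix nodes(nn, 3);
  for (int q = 0; q < nn; ++q) {
    size_t g = usedNodes[q];
    int i = (int)(g % gx), j = (int)((g / gx) % gy), k = (int)(g / ((size_t)gx * gy));
    nodes(q, 0) = origin[0] + i * spacing[0];
    nodes(q, 1) = origin[1] + j * spacing[1];
    nodes(q, 2) = origin[2] + k * spacing[2];
  }
  IntegerMatrix elems(ne, 4);
  for (int e = 0; e < ne; ++e)
    for (int a = 0; a < 4; ++a) elems(e, a) = elemNodes[4 * e + a];
  return List::create(_["nodes"] = nodes, _["elements"] = elems,
                      _["region"] = wrap(elemRegion));
}

// [[Rcpp::export]]
NumericVector cpp_tet_volumes(NumericMatrix nodes, IntegerMatrix elems) {
  int ne = elems.nrow();
  NumericVector vol(ne);
  for (int e = 0; e < ne; ++e) {
    double x[4], y[4], z[4], g[4][3];
    for (int a = 0; a < 4; ++a) {
      int n = elems(e, a) - 1;
      x[a] = nodes(n, 0); y[a] = nodes(n, 1); z[a] = nodes(n, 2);
    }
    vol[e] = tetGrads(x, y, z, g) / 6.0;
  }
  return vol;
}

// Assemble the upper triangle of the reduced stiffness T' K T as triplets.
// The dof expansion T is given in CSR form over global dofs (3*node + comp,
// 0-based rows): expStart (length 3n+1, 0-based offsets), expIdx (1-based
// reduced dof targets), expW (weights).  A fixed dof has an empty row; a
// regular free dof maps to itself with weight 1; a hanging dof maps to its
// master dofs (weight 1/2 each for mid-edge constraints).
// [[Rcpp::export]]
List cpp_tet_assemble(NumericMatrix nodes, IntegerMatrix elems, NumericVector E,
                      NumericVector nu, IntegerVector expStart,
                      IntegerVector expIdx, NumericVector expW) {
  int ne = elems.nrow();
  std::vector<int> ti, tj;
  std::vector<double> tx;
  ti.reserve((size_t)ne * 80);
  tj.reserve((size_t)ne * 80);
  tx.reserve((size_t)ne * 80);
  double D[6][6], B[6][12], DB[6][12], Ke[12][12];
  for (int e = 0; e < ne; ++e) {
    double x[4], y[4], z[4], g[4][3];
    int nd[4];
    for (int a = 0; a < 4; ++a) {
      nd[a] = elems(e, a) - 1;
      x[a] = nodes(nd[a], 0); y[a] = nodes(nd[a], 1); z[a] = nodes(nd[a], 2);
    }
    double det = tetGrads(x, y, z, g);
    double V = det / 6.0;
    if (V <= 0) stop("element %d has non-positive volume", e + 1);
    isotropicD(E[e], nu[e], D);
    buildB(g, B);
    for (int i = 0; i < 6; ++i)
      for (int j = 0; j < 12; ++j) {
        double s = 0;
        for (int k = 0; k < 6; ++k) s += D[i][k] * B[k][j];
        DB[i][j] = s;
      }
    for (int i = 0; i < 12; ++i)
      for (int j = i; j < 12; ++j) {
        double s = 0;
        for (int k = 0; k < 6; ++k) s += B[k][i] * DB[k][j];
        Ke[i][j] = s * V;
        Ke[j][i] = Ke[i][j];
      }
    int gdof[12];
    for (int a = 0; a < 4; ++a)
      for (int d = 0; d < 3; ++d) gdof[3 * a + d] = 3 * nd[a] + d;
    // full ordered double loop; keep only targets with ti <= tj (the
    // mirrored ordered pair supplies the transposed entry)
    for (int i = 0; i < 12; ++i) {
      int si = expStart[gdof[i]], eiEnd = expStart[gdof[i] + 1];
      if (si == eiEnd) continue;
      for (int j = 0; j < 12; ++j) {
        int sj = expStart[gdof[j]], ejEnd = expStart[gdof[j] + 1];
        if (sj == ejEnd) continue;
        double kij = Ke[i][j];
        for (int a = si; a < eiEnd; ++a)
          for (int b = sj; b < ejEnd; ++b) {
            int ta = expIdx[a], tb = expIdx[b];
            if (ta > tb) continue;
            ti.push_back(ta);
            tj.push_back(tb);
            tx.push_back(expW[a] * expW[b] * kij);
          }
      }
    }
  }
  return List::create(_["i"] = wrap(ti), _["j"] = wrap(tj), _["x"] = wrap(tx));
}

// Per-element constant stress (xx, yy, zz, xy, yz, zx) and von Mises.
// [[Rcpp::export]]
List cpp_tet_stress(NumericMatrix nodes, IntegerMatrix elems, NumericVector E,
                    NumericVector nu, NumericMatrix U) {
  int ne = elems.nrow();
  NumericMatrix stress(ne, 6);
  NumericVector vm(ne);
  double D[6][6], B[6][12];
  for (int e = 0; e < ne; ++e) {
    double x[4], y[4], z[4], g[4][3], ue[12];
    int nd[4];
    for (int a = 0; a < 4; ++a) {
      nd[a] = elems(e, a) - 1;
      x[a] = nodes(nd[a], 0); y[a] = nodes(nd[a], 1); z[a] = nodes(nd[a], 2);
      for (int d = 0; d < 3; ++d) ue[3 * a + d] = U(nd[a], d);
    }
    tetGrads(x, y, z, g);
    isotropicD(E[e], nu[e], D);
    buildB(g, B);
    double eps[6], sig[6];
    for (int i = 0; i < 6; ++i) {
      double s = 0;
      for (int j = 0; j < 12; ++j) s += B[i][j] * ue[j];
      eps[i] = s;
    }
    for (int i = 0; i < 6; ++i) {
      double s = 0;
      for (int j = 0; j < 6; ++j) s += D[i][j] * eps[j];
      sig[i] = s;
      stress(e, i) = s;
    }
    double a1 = sig[0] - sig[1], a2 = sig[1] - sig[2], a3 = sig[2] - sig[0];
    vm[e] = std::sqrt(0.5 * (a1 * a1 + a2 * a2 + a3 * a3) +
                      3.0 * (sig[3] * sig[3] + sig[4] * sig[4] + sig[5] * sig[5]));
  }
  return List::create(_["stress"] = stress, _["von_mises"] = vm);
}

// Nodal internal forces K u accumulated per node (for reaction audits).
// [[Rcpp::export]]
NumericMatrix cpp_internal_forces(NumericMatrix nodes, IntegerMatrix elems,
                                  NumericVector E, NumericVector nu, NumericMatrix U) {
  int ne = elems.nrow(), nn = nodes.nrow();
  NumericMatrix Fint(nn, 3);
  double D[6][6], B[6][12];
  for (int e = 0; e < ne; ++e) {
    double x[4], y[4], z[4], g[4][3], ue[12];
    int nd[4];
    for (int a = 0; a < 4; ++a) {
      nd[a] = elems(e, a) - 1;
      x[a] = nodes(nd[a], 0); y[a] = nodes(nd[a], 1); z[a] = nodes(nd[a], 2);
      for (int d = 0; d < 3; ++d) ue[3 * a + d] = U(nd[a], d);
    }
    double V = tetGrads(x, y, z, g) / 6.0;
    isotropicD(E[e], nu[e], D);
    buildB(g, B);
    double eps[6], sig[6];
    for (int i = 0; i < 6; ++i) {
      double s = 0;
      for (int j = 0; j < 12; ++j) s += B[i][j] * ue[j];
      eps[i] = s;
    }
    for (int i = 0; i < 6; ++i) {
      double s = 0;
      for (int j = 0; j < 6; ++j) s += D[i][j] * eps[j];
      sig[i] = s;
    }
    // f_e = V * B^T sigma
    for (int i = 0; i < 12; ++i) {
      double s = 0;
      for (int k = 0; k < 6; ++k) s += B[k][i] * sig[k];
      Fint(nd[i / 3], i % 3) += s * V;
    }
  }
  return Fint;
}

// Exterior faces of a tet mesh, oriented outward, with owning element.
// [[Rcpp::export]]
List cpp_boundary_faces(NumericMatrix nodes, IntegerMatrix elems) {
  int ne = elems.nrow();
  if (nodes.nrow() >= (1 << 21)) stop("boundary-face hashing supports < 2^21 nodes");
  // local faces opposite each vertex
  static const int LF[4][3] = {{1, 2, 3}, {0, 3, 2}, {0, 1, 3}, {0, 2, 1}};
  std::unordered_map<uint64_t, std::pair<int, int>> seen; // key -> (count, elem*4+face)
  seen.reserve((size_t)ne * 4);
  for (int e = 0; e < ne; ++e) {
    for (int fc = 0; fc < 4; ++fc) {
      int a = elems(e, LF[fc][0]), b = elems(e, LF[fc][1]), c = elems(e, LF[fc][2]);
      int s0 = std::min({a, b, c}), s2 = std::max({a, b, c});
      int s1 = a + b + c - s0 - s2;
      uint64_t key = ((uint64_t)s0 << 42) | ((uint64_t)s1 << 21) | (uint64_t)s2;
      auto it = seen.find(key);
      if (it == seen.end()) seen[key] = {1, e * 4 + fc};
      else it->second.first++;
    }
  }
  std::vector<int> fa, fb, fcv, owner;
  for (auto &kv : seen) {
    if (kv.second.first != 1) continue;
    int e = kv.second.second / 4, fc = kv.second.second % 4;
    int v[3] = {elems(e, LF[fc][0]), elems(e, LF[fc][1]), elems(e, LF[fc][2])};
    int opp = elems(e, fc);
    // orient outward: normal away from the opposite vertex
    double p0[3], p1[3], p2[3], po[3];
    for (int d = 0; d < 3; ++d) {
      p0[d] = nodes(v[0] - 1, d); p1[d] = nodes(v[1] - 1, d);
      p2[d] = nodes(v[2] - 1, d); po[d] = nodes(opp - 1, d);
    }
    double u[3] = {p1[0] - p0[0], p1[1] - p0[1], p1[2] - p0[2]};
    double w[3] = {p2[0] - p0[0], p2[1] - p0[1], p2[2] - p0[2]};
    double n[3] = {u[1] * w[2] - u[2] * w[1], u[2] * w[0] - u[0] * w[2],
                   u[0] * w[1] - u[1] * w[0]};
    double dpo = n[0] * (po[0] - p0[0]) + n[1] * (po[1] - p0[1]) + n[2] * (po[2] - p0[2]);
    if (dpo > 0) std::swap(v[1], v[2]);
    fa.push_back(v[0]); fb.push_back(v[1]); fcv.push_back(v[2]);
    owner.push_back(e + 1);
  }
  int nb = (int)fa.size();
  IntegerMatrix faces(nb, 3);
  for (int q = 0; q < nb; ++q) {
    faces(q, 0) = fa[q]; faces(q, 1) = fb[q]; faces(q, 2) = fcv[q];
  }
  return List::create(_["faces"] = faces, _["element"] = wrap(owner));
}
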