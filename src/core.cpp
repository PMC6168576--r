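// Lattice-spring shell core: energies, analytic forces, damped Newtonian
// relaxation, effective edge strains, and geometric queries.
//
// Conventions: positions are N x 3 (mm); all index matrices arrive 1-based
// from R and are shifted here.  A hinge row is (v0, v1, v2, v3): v0-v1 the
// shared edge, v2 the opposite vertex of the first incident face, v3 of the
// second.  Face normals follow counter-clockwise orientation.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <unordered_map>
#include <algorithm>
using namespace Rcpp;

static inline void vsub(const double* a, const double* b, double* out) {
  out[0] = a[0] - b[0]; out[1] = a[1] - b[1]; out[2] = a[2] - b[2];
}
static inline double vdot(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void vcross(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double vnorm(const double* a) { return std::sqrt(vdot(a, a)); }

struct Vec3 { double x[3]; };

// Signed dihedral angle of a hinge and its gradient w.r.t. the four
// vertices.  theta = 0 for coplanar faces; the sign follows the orientation
// of the shared edge v0 -> v1.  Returns false on degenerate faces.
static bool hinge_theta_grad(const double* x0, const double* x1,
                             const double* x2, const double* x3,
                             double& theta, double g[4][3],
                             bool want_grad) {
  double e[3], u2[3], u3[3], n1[3], n2[3];
  vsub(x1, x0, e);
  vsub(x2, x0, u2);
  vsub(x3, x0, u3);
  vcross(e, u2, n1);  // normal of face (x0, x1, x2)
  vcross(u3, e, n2);  // normal of face (x0, x3, x1)
  double elen = vnorm(e);
  double n1sq = vdot(n1, n1), n2sq = vdot(n2, n2);
  if (elen < 1e-300 || n1sq < 1e-300 || n2sq < 1e-300) return false;
  // degenerate-sliver guard: |N| = |e| * height; below 1e-3 * |e| the
  // dihedral gradient (~1/|N|^2) is ill-conditioned and is suppressed
  double hmin = 1e-3 * elen;
  if (n1sq < hmin * hmin * elen * elen || n2sq < hmin * hmin * elen * elen)
    return false;
  double ehat[3] = { e[0] / elen, e[1] / elen, e[2] / elen };
  double cr[3];
  vcross(n1, n2, cr);
  theta = std::atan2(vdot(cr, ehat), vdot(n1, n2));
  if (!want_grad) return true;
  double m1[3] = { n1[0] / n1sq, n1[1] / n1sq, n1[2] / n1sq };
  double m2[3] = { n2[0] / n2sq, n2[1] / n2sq, n2[2] / n2sq };
  double d21[3], d31[3];
  vsub(x2, x1, d21);
  vsub(x3, x1, d31);
  double a0 = vdot(d21, ehat), b0 = vdot(d31, ehat);
  double a1 = vdot(u2, ehat), b1 = vdot(u3, ehat);
  for (int c = 0; c < 3; ++c) {
    g[2][c] = -elen * m1[c];
    g[3][c] = -elen * m2[c];
    g[0][c] = -a0 * m1[c] - b0 * m2[c];
    g[1][c] =  a1 * m1[c] + b1 * m2[c];
  }
  return true;
}

// Closest point on triangle (a,b,c) to p; barycentrics in w. (Ericson 2005)
static void closest_point_triangle(const double* p, const double* a,
                                   const double* b, const double* c,
                                   double* q, double* w) {
  double ab[3], ac[3], ap[3];
  vsub(b, a, ab); vsub(c, a, ac); vsub(p, a, ap);
  double d1 = vdot(ab, ap), d2 = vdot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) {
    for (int i = 0; i < 3; ++i) q[i] = a[i];
    w[0] = 1; w[1] = 0; w[2] = 0; return;
  }
  double bp[3]; vsub(p, b, bp);
  double d3 = vdot(ab, bp), d4 = vdot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) {
    for (int i = 0; i < 3; ++i) q[i] = b[i];
    w[0] = 0; w[1] = 1; w[2] = 0; return;
  }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) q[i] = a[i] + v * ab[i];
    w[0] = 1 - v; w[1] = v; w[2] = 0; return;
  }
  double cp[3]; vsub(p, c, cp);
  double d5 = vdot(ab, cp), d6 = vdot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) {
    for (int i = 0; i < 3; ++i) q[i] = c[i];
    w[0] = 0; w[1] = 0; w[2] = 1; return;
  }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double v = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) q[i] = a[i] + v * ac[i];
    w[0] = 1 - v; w[1] = 0; w[2] = v; return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double v = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) q[i] = b[i] + v * (c[i] - b[i]);
    w[0] = 0; w[1] = 1 - v; w[2] = v; return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, u = vc * denom;
  for (int i = 0; i < 3; ++i) q[i] = a[i] + v * ab[i] + u * ac[i];
  w[0] = 1 - v - u; w[1] = v; w[2] = u;
}

// ---------------------------------------------------------------------------
// Model: bundles topology + parameters for force assembly.

struct ContactPair { int node; int face; };

struct Model {
  int n;                      // nodes
  const double* pos;          // n x 3 column-major (current working array)
  std::vector<int> e0, e1;    // edges
  std::vector<double> l0;
  std::vector<uint8_t> ebroken;
  double ks;
  std::vector<int> h0, h1, h2, h3;  // hinges
  std::vector<double> theta0;
  std::vector<int> hinge_edge;      // edge id of each hinge
  std::vector<int> hf1, hf2;        // incident faces of each hinge
  double kb;
  std::vector<int> f0, f1, f2;      // faces
  std::vector<double> A0;
  std::vector<int> fe0, fe1, fe2;   // edge ids of each face
  double kv;
  std::vector<double> foot, nrm;    // n x 3 each (flattened col-major)
  double hoff, ksub;
  double kc, dc;
  std::vector<int> adj_ptr, adj_idx;  // vertex adjacency (CSR, sorted)
  std::vector<ContactPair> pairs;     // cached candidate contact pairs

  bool face_active(int f) const {
    return !ebroken[fe0[f]] && !ebroken[fe1[f]] && !ebroken[fe2[f]];
  }
  // a hinge transmits bending only while both incident faces are intact
  bool hinge_active(int h) const {
    return face_active(hf1[h]) && face_active(hf2[h]);
  }
  bool adjacent(int v, int u) const {
    int lo = adj_ptr[v], hi = adj_ptr[v + 1];
    return std::binary_search(adj_idx.begin() + lo, adj_idx.begin() + hi, u);
  }
};

static void build_contact_pairs(Model& M, const std::vector<double>& X,
                                double margin) {
  M.pairs.clear();
  if (M.kc <= 0 || M.dc <= 0) return;
  const int n = M.n;
  const double range = M.dc + margin;
  // uniform grid over nodes
  double mn[3] = { 1e300, 1e300, 1e300 }, mx[3] = { -1e300, -1e300, -1e300 };
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) {
      double v = X[i + n * c];
      if (v < mn[c]) mn[c] = v;
      if (v > mx[c]) mx[c] = v;
    }
  double cell = range > 0 ? range : 1.0;
  int dims[3];
  for (int c = 0; c < 3; ++c) {
    dims[c] = std::max(1, std::min(256, (int)((mx[c] - mn[c]) / cell) + 1));
  }
  auto cell_of = [&](double v, int c) {
    int k = (int)((v - mn[c]) / cell);
    if (k < 0) k = 0;
    if (k >= dims[c]) k = dims[c] - 1;
    return k;
  };
  std::unordered_map<int64_t, std::vector<int>> grid;
  grid.reserve(n * 2);
  for (int i = 0; i < n; ++i) {
    int64_t key = cell_of(X[i], 0)
      + (int64_t)dims[0] * (cell_of(X[i + n], 1)
      + (int64_t)dims[1] * cell_of(X[i + 2 * n], 2));
    grid[key].push_back(i);
  }
  int nf = (int)M.f0.size();
  for (int f = 0; f < nf; ++f) {
    int a = M.f0[f], b = M.f1[f], c = M.f2[f];
    double bmin[3], bmax[3];
    for (int d = 0; d < 3; ++d) {
      double va = X[a + n * d], vb = X[b + n * d], vc = X[c + n * d];
      bmin[d] = std::min(va, std::min(vb, vc)) - range;
      bmax[d] = std::max(va, std::max(vb, vc)) + range;
    }
    int lo[3], hi[3];
    for (int d = 0; d < 3; ++d) {
      lo[d] = cell_of(bmin[d], d);
      hi[d] = cell_of(bmax[d], d);
    }
    for (int gx = lo[0]; gx <= hi[0]; ++gx)
      for (int gy = lo[1]; gy <= hi[1]; ++gy)
        for (int gz = lo[2]; gz <= hi[2]; ++gz) {
          int64_t key = gx + (int64_t)dims[0] * (gy + (int64_t)dims[1] * gz);
          auto it = grid.find(key);
          if (it == grid.end()) continue;
          for (int node : it->second) {
            if (node == a || node == b || node == c) continue;
            if (M.adjacent(node, a) || M.adjacent(node, b) ||
                M.adjacent(node, c)) continue;
            bool in = true;
            for (int d = 0; d < 3; ++d) {
              double v = X[node + n * d];
              if (v < bmin[d] || v > bmax[d]) { in = false; break; }
            }
            if (in) M.pairs.push_back({ node, f });
          }
        }
  }
}

// Assemble all forces into F (n x 3, zeroed here).  Returns total energy.
static double compute_forces(const Model& M, const std::vector<double>& X,
                             std::vector<double>& F) {
  const int n = M.n;
  std::fill(F.begin(), F.end(), 0.0);
  double E = 0.0;
  // stretch
  const int ne = (int)M.e0.size();
  for (int e = 0; e < ne; ++e) {
    if (M.ebroken[e]) continue;
    int a = M.e0[e], b = M.e1[e];
    double d[3] = { X[b] - X[a], X[b + n] - X[a + n],
                    X[b + 2 * n] - X[a + 2 * n] };
    double len = vnorm(d);
    if (len < 1e-300) continue;
    double eps = (len - M.l0[e]) / M.l0[e];
    E += 0.5 * M.ks * M.l0[e] * eps * eps;
    double fmag = M.ks * eps / len;  // force on a along +d
    for (int c = 0; c < 3; ++c) {
      F[a + n * c] += fmag * d[c];
      F[b + n * c] -= fmag * d[c];
    }
  }
  // bending
  const int nh = (int)M.h0.size();
  if (M.kb > 0) {
    double g[4][3], theta;
    for (int h = 0; h < nh; ++h) {
      if (!M.hinge_active(h)) continue;
      int idx[4] = { M.h0[h], M.h1[h], M.h2[h], M.h3[h] };
      double x[4][3];
      for (int k = 0; k < 4; ++k)
        for (int c = 0; c < 3; ++c) x[k][c] = X[idx[k] + n * c];
      if (!hinge_theta_grad(x[0], x[1], x[2], x[3], theta, g, true)) continue;
      double dth = theta - M.theta0[h];
      E += M.kb * dth * dth;
      double coef = 2.0 * M.kb * dth;
      for (int k = 0; k < 4; ++k)
        for (int c = 0; c < 3; ++c) F[idx[k] + n * c] -= coef * g[k][c];
    }
  }
  // face area
  const int nf = (int)M.f0.size();
  if (M.kv > 0) {
    for (int f = 0; f < nf; ++f) {
      if (!M.face_active(f)) continue;
      int a = M.f0[f], b = M.f1[f], c = M.f2[f];
      double xa[3], xb[3], xc[3];
      for (int d = 0; d < 3; ++d) {
        xa[d] = X[a + n * d]; xb[d] = X[b + n * d]; xc[d] = X[c + n * d];
      }
      double ab[3], ac[3], nrm[3];
      vsub(xb, xa, ab); vsub(xc, xa, ac);
      vcross(ab, ac, nrm);
      double nn = vnorm(nrm);
      if (nn < 1e-300) continue;
      double A = 0.5 * nn;
      double rel = A / M.A0[f] - 1.0;
      E += 0.5 * M.kv * M.A0[f] * rel * rel;
      double dEdA = M.kv * rel;
      double nh3[3] = { nrm[0] / nn, nrm[1] / nn, nrm[2] / nn };
      // grad_a A = 0.5 * nhat x (xc - xb), cyclic
      double cb[3], acv[3], ba[3], gA[3];
      vsub(xc, xb, cb);
      vcross(nh3, cb, gA);
      for (int d = 0; d < 3; ++d) F[a + n * d] -= dEdA * 0.5 * gA[d];
      vsub(xa, xc, acv);
      vcross(nh3, acv, gA);
      for (int d = 0; d < 3; ++d) F[b + n * d] -= dEdA * 0.5 * gA[d];
      vsub(xb, xa, ba);
      vcross(nh3, ba, gA);
      for (int d = 0; d < 3; ++d) F[c + n * d] -= dEdA * 0.5 * gA[d];
    }
  }
  // substrate tether to offset surface
  if (M.ksub > 0) {
    for (int i = 0; i < n; ++i) {
      double dx[3];
      for (int c = 0; c < 3; ++c) {
        double target = M.foot[i + n * c] + M.hoff * M.nrm[i + n * c];
        dx[c] = X[i + n * c] - target;
      }
      E += 0.5 * M.ksub * vdot(dx, dx);
      for (int c = 0; c < 3; ++c) F[i + n * c] -= M.ksub * dx[c];
    }
  }
  // node-face contact over cached pairs
  if (M.kc > 0 && M.dc > 0) {
    for (const ContactPair& cp : M.pairs) {
      int i = cp.node, f = cp.face;
      int a = M.f0[f], b = M.f1[f], c = M.f2[f];
      double p[3], xa[3], xb[3], xc[3], q[3], w[3];
      for (int d = 0; d < 3; ++d) {
        p[d] = X[i + n * d];
        xa[d] = X[a + n * d]; xb[d] = X[b + n * d]; xc[d] = X[c + n * d];
      }
      closest_point_triangle(p, xa, xb, xc, q, w);
      double dvec[3];
      vsub(p, q, dvec);
      double d = vnorm(dvec);
      if (d >= M.dc || d < 1e-12) continue;
      double pen = M.dc - d;
      E += 0.5 * M.kc * pen * pen;
      double fmag = M.kc * pen / d;  // repulsive on the node
      for (int dd = 0; dd < 3; ++dd) {
        double fc = fmag * dvec[dd];
        F[i + n * dd] += fc;
        F[a + n * dd] -= w[0] * fc;
        F[b + n * dd] -= w[1] * fc;
        F[c + n * dd] -= w[2] * fc;
      }
    }
  }
  return E;
}

static Model make_model(NumericMatrix pos, IntegerMatrix edges,
                        NumericVector l0, LogicalVector broken, double ks,
                        IntegerMatrix hinges, NumericVector theta0,
                        IntegerVector hinge_edge, IntegerMatrix hinge_faces,
                        double kb,
                        IntegerMatrix faces, NumericVector A0,
                        IntegerMatrix face_edges, double kv,
                        NumericMatrix foot, NumericMatrix nrm, double hoff,
                        double ksub, double kc, double dc,
                        IntegerVector adj_ptr, IntegerVector adj_idx) {
  Model M;
  M.n = pos.nrow();
  M.ks = ks; M.kb = kb; M.kv = kv; M.ksub = ksub;
  M.kc = kc; M.dc = dc; M.hoff = hoff;
  int ne = edges.nrow();
  M.e0.resize(ne); M.e1.resize(ne); M.l0.resize(ne); M.ebroken.resize(ne);
  for (int e = 0; e < ne; ++e) {
    M.e0[e] = edges(e, 0) - 1;
    M.e1[e] = edges(e, 1) - 1;
    M.l0[e] = l0[e];
    M.ebroken[e] = broken[e] ? 1 : 0;
  }
  int nh = hinges.nrow();
  M.h0.resize(nh); M.h1.resize(nh); M.h2.resize(nh); M.h3.resize(nh);
  M.theta0.resize(nh); M.hinge_edge.resize(nh);
  M.hf1.resize(nh); M.hf2.resize(nh);
  for (int h = 0; h < nh; ++h) {
    M.h0[h] = hinges(h, 0) - 1;
    M.h1[h] = hinges(h, 1) - 1;
    M.h2[h] = hinges(h, 2) - 1;
    M.h3[h] = hinges(h, 3) - 1;
    M.theta0[h] = theta0[h];
    M.hinge_edge[h] = hinge_edge[h] - 1;
    M.hf1[h] = hinge_faces(h, 0) - 1;
    M.hf2[h] = hinge_faces(h, 1) - 1;
  }
  int nf = faces.nrow();
  M.f0.resize(nf); M.f1.resize(nf); M.f2.resize(nf);
  M.A0.resize(nf); M.fe0.resize(nf); M.fe1.resize(nf); M.fe2.resize(nf);
  for (int f = 0; f < nf; ++f) {
    M.f0[f] = faces(f, 0) - 1;
    M.f1[f] = faces(f, 1) - 1;
    M.f2[f] = faces(f, 2) - 1;
    M.A0[f] = A0[f];
    M.fe0[f] = face_edges(f, 0) - 1;
    M.fe1[f] = face_edges(f, 1) - 1;
    M.fe2[f] = face_edges(f, 2) - 1;
  }
  int n = M.n;
  M.foot.resize(3 * n); M.nrm.resize(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) {
      M.foot[i + n * c] = foot(i, c);
      M.nrm[i + n * c] = nrm(i, c);
    }
  M.adj_ptr.assign(adj_ptr.begin(), adj_ptr.end());
  M.adj_idx.assign(adj_idx.begin(), adj_idx.end());
  for (auto& v : M.adj_ptr) v -= 1;  // R passes 1-based offsets
  for (auto& v : M.adj_idx) v -= 1;
  return M;
}

// [[Rcpp::export]]
List cpp_forces_energy(NumericMatrix pos, IntegerMatrix edges,
                       NumericVector l0, LogicalVector broken, double ks,
                       IntegerMatrix hinges, NumericVector theta0,
                       IntegerVector hinge_edge, IntegerMatrix hinge_faces,
                       double kb,
                       IntegerMatrix faces, NumericVector A0,
                       IntegerMatrix face_edges, double kv,
                       NumericMatrix foot, NumericMatrix nrm, double hoff,
                       double ksub, double kc, double dc,
                       IntegerVector adj_ptr, IntegerVector adj_idx) {
  Model M = make_model(pos, edges, l0, broken, ks, hinges, theta0, hinge_edge,
                       hinge_faces, kb, faces, A0, face_edges, kv, foot, nrm,
                       hoff, ksub, kc, dc, adj_ptr, adj_idx);
  int n = M.n;
  std::vector<double> X(3 * n), F(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) X[i + n * c] = pos(i, c);
  build_contact_pairs(M, X, 0.0);
  double E = compute_forces(M, X, F);
  NumericMatrix Fout(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) Fout(i, c) = F[i + n * c];
  return List::create(_["energy"] = E, _["forces"] = Fout);
}

// [[Rcpp::export]]
List cpp_relax(NumericMatrix pos, NumericMatrix vel, LogicalVector fixed,
               IntegerMatrix edges, NumericVector l0, LogicalVector broken,
               double ks, IntegerMatrix hinges, NumericVector theta0,
               IntegerVector hinge_edge, IntegerMatrix hinge_faces,
               double kb, IntegerMatrix faces,
               NumericVector A0, IntegerMatrix face_edges, double kv,
               NumericMatrix foot, NumericMatrix nrm, double hoff,
               double ksub, double kc, double dc, IntegerVector adj_ptr,
               IntegerVector adj_idx, double mass, double gamma, double dt,
               double tolF, double tolV, int maxit, int contact_every,
               bool fire) {
  Model M = make_model(pos, edges, l0, broken, ks, hinges, theta0, hinge_edge,
                       hinge_faces, kb, faces, A0, face_edges, kv, foot, nrm,
                       hoff, ksub, kc, dc, adj_ptr, adj_idx);
  const int n = M.n;
  std::vector<double> X(3 * n), V(3 * n), F(3 * n);
  std::vector<uint8_t> fix(n);
  for (int i = 0; i < n; ++i) {
    fix[i] = fixed[i] ? 1 : 0;
    for (int c = 0; c < 3; ++c) {
      X[i + n * c] = pos(i, c);
      V[i + n * c] = vel(i, c);
    }
  }
  double contact_margin = 2.0 * dc;
  bool converged = false;
  double maxF = R_PosInf, maxV = R_PosInf, E = NA_REAL;
  int it = 0;
  bool blown = false;
  // FIRE (fast inertial relaxation engine) adaptation on top of the
  // semi-implicit Euler damped-Newtonian step: same stationary state
  // (F = 0, v = 0), adaptively tuned damping and time step.
  const double f_inc = 1.1, f_dec = 0.5, f_alpha = 0.99;
  const double alpha0 = 0.1;
  const int n_min = 5;
  double alpha = alpha0;
  double dt_cur = dt, dt_max = 2.0 * dt;
  int n_pos = 0;
  for (it = 0; it < maxit; ++it) {
    if (M.kc > 0 && M.dc > 0 && (it % contact_every == 0))
      build_contact_pairs(M, X, contact_margin);
    E = compute_forces(M, X, F);
    if (fire) {
      double P = 0, fnorm2 = 0, vnorm2 = 0;
      for (int i = 0; i < n; ++i) {
        if (fix[i]) continue;
        for (int c = 0; c < 3; ++c) {
          int k = i + n * c;
          P += F[k] * V[k];
          fnorm2 += F[k] * F[k];
          vnorm2 += V[k] * V[k];
        }
      }
      if (P > 0) {
        ++n_pos;
        double mix = (fnorm2 > 0) ? alpha * std::sqrt(vnorm2 / fnorm2) : 0.0;
        for (int i = 0; i < n; ++i) {
          if (fix[i]) continue;
          for (int c = 0; c < 3; ++c) {
            int k = i + n * c;
            V[k] = (1.0 - alpha) * V[k] + mix * F[k];
          }
        }
        if (n_pos > n_min) {
          dt_cur = std::min(dt_cur * f_inc, dt_max);
          alpha *= f_alpha;
        }
      } else {
        n_pos = 0;
        dt_cur *= f_dec;
        alpha = alpha0;
        std::fill(V.begin(), V.end(), 0.0);
      }
    }
    double gamma_eff = fire ? 0.0 : gamma;
    maxF = 0.0; maxV = 0.0;
    for (int i = 0; i < n; ++i) {
      if (fix[i]) {
        for (int c = 0; c < 3; ++c) V[i + n * c] = 0.0;
        continue;
      }
      double f2 = 0, v2 = 0;
      for (int c = 0; c < 3; ++c) {
        int k = i + n * c;
        double a = F[k] / mass - gamma_eff * V[k];
        V[k] += dt_cur * a;
        X[k] += dt_cur * V[k];
        f2 += F[k] * F[k];
        v2 += V[k] * V[k];
      }
      if (f2 > maxF) maxF = f2;
      if (v2 > maxV) maxV = v2;
    }
    maxF = std::sqrt(maxF);
    maxV = std::sqrt(maxV);
    if (!std::isfinite(maxF) || maxF > 1e12) { blown = true; break; }
    if (maxF < tolF && maxV < tolV) { converged = true; ++it; break; }
  }
  NumericMatrix Xout(n, 3), Vout(n, 3);
  int iworst = 0;
  double worst = -1.0;
  // recompute residual at the returned configuration
  if (!blown) {
    if (M.kc > 0 && M.dc > 0) build_contact_pairs(M, X, contact_margin);
    E = compute_forces(M, X, F);
    maxF = 0.0;
    for (int i = 0; i < n; ++i) {
      if (fix[i]) continue;
      double f2 = 0;
      for (int c = 0; c < 3; ++c) f2 += F[i + n * c] * F[i + n * c];
      if (f2 > worst) { worst = f2; iworst = i; }
    }
    maxF = worst > 0 ? std::sqrt(worst) : 0.0;
  }
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) {
      Xout(i, c) = X[i + n * c];
      Vout(i, c) = V[i + n * c];
    }
  return List::create(_["pos"] = Xout, _["vel"] = Vout,
                      _["iterations"] = it, _["converged"] = converged,
                      _["diverged"] = blown, _["max_force"] = maxF,
                      _["max_speed"] = maxV, _["energy"] = E,
                      _["worst_node"] = iworst + 1);
}

// [[Rcpp::export]]
NumericVector cpp_hinge_angles(NumericMatrix pos, IntegerMatrix hinges) {
  int nh = hinges.nrow(), n = pos.nrow();
  NumericVector th(nh);
  double g[4][3];
  for (int h = 0; h < nh; ++h) {
    double x[4][3];
    for (int k = 0; k < 4; ++k) {
      int idx = hinges(h, k) - 1;
      for (int c = 0; c < 3; ++c) x[k][c] = pos(idx, c);
    }
    double theta = NA_REAL;
    if (!hinge_theta_grad(x[0], x[1], x[2], x[3], theta, g, false))
      theta = NA_REAL;
    th[h] = theta;
    (void)n;
  }
  return th;
}

// Edge-wise curvature kappa_e = 2*theta / (h1 + h2) with h_i the triangle
// heights over the shared edge; 0 for boundary edges.
// [[Rcpp::export]]
NumericVector cpp_edge_kappa(NumericMatrix pos, IntegerMatrix edges,
                             IntegerVector edge_hinge, IntegerMatrix hinges) {
  int ne = edges.nrow();
  NumericVector kap(ne);
  double g[4][3];
  for (int e = 0; e < ne; ++e) {
    int h = edge_hinge[e];
    if (h == NA_INTEGER || h <= 0) { kap[e] = 0.0; continue; }
    h -= 1;
    double x[4][3];
    for (int k = 0; k < 4; ++k) {
      int idx = hinges(h, k) - 1;
      for (int c = 0; c < 3; ++c) x[k][c] = pos(idx, c);
    }
    double theta;
    if (!hinge_theta_grad(x[0], x[1], x[2], x[3], theta, g, false)) {
      kap[e] = NA_REAL; continue;
    }
    double ev[3], u2[3], u3[3], n1[3], n2[3];
    vsub(x[1], x[0], ev);
    vsub(x[2], x[0], u2);
    vsub(x[3], x[0], u3);
    vcross(ev, u2, n1);
    vcross(u3, ev, n2);
    double elen = vnorm(ev);
    double h1 = vnorm(n1) / elen;  // 2*A1/|e|
    double h2 = vnorm(n2) / elen;
    kap[e] = 2.0 * theta / (h1 + h2);
  }
  return kap;
}

// Effective edge strain: membrane strain plus (mode = 1) the outer-fibre
// bending term (ts/2)*|kappa - kappa0|.  Broken edges give NA.
// [[Rcpp::export]]
NumericVector cpp_edge_strain(NumericMatrix pos, IntegerMatrix edges,
                              NumericVector l0, LogicalVector broken,
                              IntegerVector edge_hinge, IntegerMatrix hinges,
                              IntegerMatrix hinge_faces,
                              IntegerMatrix face_edges,
                              NumericVector kappa0, double ts, int mode) {
  int ne = edges.nrow();
  NumericVector out(ne);
  NumericVector kap;
  if (mode == 1) kap = cpp_edge_kappa(pos, edges, edge_hinge, hinges);
  auto face_ok = [&](int f) {
    return !broken[face_edges(f, 0) - 1] && !broken[face_edges(f, 1) - 1] &&
           !broken[face_edges(f, 2) - 1];
  };
  for (int e = 0; e < ne; ++e) {
    if (broken[e]) { out[e] = NA_REAL; continue; }
    int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
    double d[3] = { pos(b, 0) - pos(a, 0), pos(b, 1) - pos(a, 1),
                    pos(b, 2) - pos(a, 2) };
    double eps = (vnorm(d) - l0[e]) / l0[e];
    if (mode == 1 && edge_hinge[e] != NA_INTEGER && edge_hinge[e] > 0 &&
        R_finite(kap[e])) {
      int h = edge_hinge[e] - 1;
      if (face_ok(hinge_faces(h, 0) - 1) && face_ok(hinge_faces(h, 1) - 1))
        eps += 0.5 * ts * std::fabs(kap[e] - kappa0[e]);
    }
    out[e] = eps;
  }
  return out;
}

// Closest points on a triangle mesh for a set of query points (brute force
// with bounding-box rejection against the current best distance).
// [[Rcpp::export]]
List cpp_closest_mesh(NumericMatrix pts, NumericMatrix verts,
                      IntegerMatrix faces) {
  int m = pts.nrow(), nf = faces.nrow();
  NumericMatrix out(m, 3);
  NumericVector dist(m);
  std::vector<double> bmin(3 * nf), bmax(3 * nf);
  for (int f = 0; f < nf; ++f) {
    for (int c = 0; c < 3; ++c) {
      double v0 = verts(faces(f, 0) - 1, c);
      double v1 = verts(faces(f, 1) - 1, c);
      double v2 = verts(faces(f, 2) - 1, c);
      bmin[f + nf * c] = std::min(v0, std::min(v1, v2));
      bmax[f + nf * c] = std::max(v0, std::max(v1, v2));
    }
  }
  for (int i = 0; i < m; ++i) {
    double p[3] = { pts(i, 0), pts(i, 1), pts(i, 2) };
    double best = 1e300, bq[3] = { p[0], p[1], p[2] };
    for (int f = 0; f < nf; ++f) {
      double lb = 0.0;
      for (int c = 0; c < 3; ++c) {
        double d = 0.0;
        if (p[c] < bmin[f + nf * c]) d = bmin[f + nf * c] - p[c];
        else if (p[c] > bmax[f + nf * c]) d = p[c] - bmax[f + nf * c];
        lb += d * d;
      }
      if (lb >= best) continue;
      double a[3], b[3], cc[3], q[3], w[3];
      for (int c = 0; c < 3; ++c) {
        a[c] = verts(faces(f, 0) - 1, c);
        b[c] = verts(faces(f, 1) - 1, c);
        cc[c] = verts(faces(f, 2) - 1, c);
      }
      closest_point_triangle(p, a, b, cc, q, w);
      double dv[3];
      vsub(p, q, dv);
      double d2 = vdot(dv, dv);
      if (d2 < best) {
        best = d2;
        for (int c = 0; c < 3; ++c) bq[c] = q[c];
      }
    }
    for (int c = 0; c < 3; ++c) out(i, c) = bq[c];
    dist[i] = std::sqrt(best);
  }
  return List::create(_["points"] = out, _["dist"] = dist);
}

// Interpolate per-vertex fields at 2D query points by barycentric
// interpolation on the (x, y) projection of the mesh.  Rows of `values`
// correspond to vertices.  Queries outside every triangle give NA.
// [[Rcpp::export]]
NumericMatrix cpp_interp_xy(NumericMatrix pts2d, NumericMatrix verts,
                            IntegerMatrix faces, NumericMatrix values) {
  int m = pts2d.nrow(), nf = faces.nrow(), k = values.ncol();
  NumericMatrix out(m, k);
  std::fill(out.begin(), out.end(), NA_REAL);
  for (int i = 0; i < m; ++i) {
    double px = pts2d(i, 0), py = pts2d(i, 1);
    for (int f = 0; f < nf; ++f) {
      int a = faces(f, 0) - 1, b = faces(f, 1) - 1, c = faces(f, 2) - 1;
      double ax = verts(a, 0), ay = verts(a, 1);
      double bx = verts(b, 0), by = verts(b, 1);
      double cx = verts(c, 0), cy = verts(c, 1);
      double lox = std::min(ax, std::min(bx, cx));
      double hix = std::max(ax, std::max(bx, cx));
      double loy = std::min(ay, std::min(by, cy));
      double hiy = std::max(ay, std::max(by, cy));
      if (px < lox - 1e-12 || px > hix + 1e-12 ||
          py < loy - 1e-12 || py > hiy + 1e-12) continue;
      double det = (bx - ax) * (cy - ay) - (cx - ax) * (by - ay);
      if (std::fabs(det) < 1e-300) continue;
      double w1 = ((bx - px) * (cy - py) - (cx - px) * (by - py)) / det;
      double w2 = ((cx - px) * (ay - py) - (ax - px) * (cy - py)) / det;
      double w3 = 1.0 - w1 - w2;
      double tol = -1e-9;
      if (w1 < tol || w2 < tol || w3 < tol) continue;
      for (int j = 0; j < k; ++j)
        out(i, j) = w1 * values(a, j) + w2 * values(b, j) + w3 * values(c, j);
      break;
    }
  }
  return out;
}
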