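// Quadric edge-collapse mesh decimation (Garland & Heckbert style).
//
// Per-vertex 4x4 plane quadrics accumulated from area-weighted face
// planes; boundary edges add perpendicular constraint planes so open
// section rims stay put.  Edges are collapsed cheapest-first from a lazy
// priority queue until the live face count reaches the target exactly.
// Interior collapses remove 2 faces, boundary-edge collapses remove 1,
// which is what lets the loop land on an exact face budget.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

struct Quadric {
  double q[10]; // symmetric 4x4: 11,12,13,14,22,23,24,33,34,44
  Quadric() { std::fill(q, q + 10, 0.0); }
  void add_plane(double a, double b, double c, double d, double w) {
    q[0] += w * a * a; q[1] += w * a * b; q[2] += w * a * c; q[3] += w * a * d;
    q[4] += w * b * b; q[5] += w * b * c; q[6] += w * b * d;
    q[7] += w * c * c; q[8] += w * c * d;
    q[9] += w * d * d;
  }
  void operator+=(const Quadric& o) {
    for (int i = 0; i < 10; ++i) q[i] += o.q[i];
  }
  double eval(double x, double y, double z) const {
    return q[0]*x*x + 2*q[1]*x*y + 2*q[2]*x*z + 2*q[3]*x
         + q[4]*y*y + 2*q[5]*y*z + 2*q[6]*y
         + q[7]*z*z + 2*q[8]*z
         + q[9];
  }
  // minimise x'Qx over position; false if the 3x3 system is near-singular
  bool optimum(double out[3]) const {
    double a11 = q[0], a12 = q[1], a13 = q[2];
    double a22 = q[4], a23 = q[5], a33 = q[7];
    double b1 = -q[3], b2 = -q[6], b3 = -q[8];
    double det = a11*(a22*a33 - a23*a23) - a12*(a12*a33 - a23*a13)
               + a13*(a12*a23 - a22*a13);
    double scale = std::max({std::fabs(a11), std::fabs(a22), std::fabs(a33), 1e-300});
    if (std::fabs(det) < 1e-10 * scale * scale * scale) return false;
    out[0] = ( b1*(a22*a33 - a23*a23) - a12*(b2*a33 - a23*b3)
             + a13*(b2*a23 - a22*b3)) / det;
    out[1] = ( a11*(b2*a33 - a23*b3) - b1*(a12*a33 - a23*a13)
             + a13*(a12*b3 - b2*a13)) / det;
    out[2] = ( a11*(a22*b3 - b2*a23) - a12*(a12*b3 - b2*a13)
             + b1*(a12*a23 - a22*a13)) / det;
    return std::isfinite(out[0]) && std::isfinite(out[1]) && std::isfinite(out[2]);
  }
};

struct HeapEdge {
  double cost;
  int u, v;
  long stamp_u, stamp_v;
  double pos[3];
  bool operator<(const HeapEdge& o) const { return cost > o.cost; } // min-heap
};

static inline void face_normal(const std::vector<double>& X,
                               const std::vector<double>& Y,
                               const std::vector<double>& Z,
                               int a, int b, int c, double n[3]) {
  double ux = X[b]-X[a], uy = Y[b]-Y[a], uz = Z[b]-Z[a];
  double wx = X[c]-X[a], wy = Y[c]-Y[a], wz = Z[c]-Z[a];
  n[0] = uy*wz - uz*wy;
  n[1] = uz*wx - ux*wz;
  n[2] = ux*wy - uy*wx;
}

// [[Rcpp::export(name = ".decimate_qem_cpp")]]
List decimate_qem_cpp(NumericMatrix V, IntegerMatrix Fin, int target,
                      double boundary_weight = 100.0) {
  const int nv = V.nrow();
  const int nf0 = Fin.nrow();
  std::vector<double> X(nv), Y(nv), Z(nv);
  for (int i = 0; i < nv; ++i) { X[i]=V(i,0); Y[i]=V(i,1); Z[i]=V(i,2); }
  std::vector<int> F(3 * (size_t)nf0);
  for (int f = 0; f < nf0; ++f)
    for (int j = 0; j < 3; ++j) F[3*(size_t)f + j] = Fin(f, j) - 1;

  std::vector<char> face_alive(nf0, 1), vert_alive(nv, 1);
  std::vector<std::vector<int>> vfaces(nv);
  for (int f = 0; f < nf0; ++f)
    for (int j = 0; j < 3; ++j) vfaces[F[3*(size_t)f+j]].push_back(f);

  // vertex quadrics from area-weighted face planes
  std::vector<Quadric> Q(nv);
  for (int f = 0; f < nf0; ++f) {
    int a = F[3*(size_t)f], b = F[3*(size_t)f+1], c = F[3*(size_t)f+2];
    double n[3];
    face_normal(X, Y, Z, a, b, c, n);
    double len = std::sqrt(n[0]*n[0] + n[1]*n[1] + n[2]*n[2]);
    if (len <= 0) continue;
    double area = 0.5 * len;
    double nx = n[0]/len, ny = n[1]/len, nz = n[2]/len;
    double d = -(nx*X[a] + ny*Y[a] + nz*Z[a]);
    Q[a].add_plane(nx, ny, nz, d, area);
    Q[b].add_plane(nx, ny, nz, d, area);
    Q[c].add_plane(nx, ny, nz, d, area);
  }

  // boundary detection via edge -> face-count map, plus constraint planes
  std::vector<char> vert_boundary(nv, 0);
  {
    std::vector<std::pair<long long,int>> edges; // (key, face)
    edges.reserve(3 * (size_t)nf0);
    for (int f = 0; f < nf0; ++f) {
      int vv[3] = {F[3*(size_t)f], F[3*(size_t)f+1], F[3*(size_t)f+2]};
      for (int j = 0; j < 3; ++j) {
        int p = vv[j], q = vv[(j+1)%3];
        long long key = (long long)std::min(p,q) * nv + std::max(p,q);
        edges.push_back({key, f});
      }
    }
    std::sort(edges.begin(), edges.end());
    for (size_t i = 0; i < edges.size(); ) {
      size_t j = i;
      while (j < edges.size() && edges[j].first == edges[i].first) ++j;
      if (j - i == 1) { // boundary edge
        int f = edges[i].second;
        int p = (int)(edges[i].first / nv), q = (int)(edges[i].first % nv);
        vert_boundary[p] = 1; vert_boundary[q] = 1;
        int a = F[3*(size_t)f], b = F[3*(size_t)f+1], c = F[3*(size_t)f+2];
        double nf_[3];
        face_normal(X, Y, Z, a, b, c, nf_);
        double ex = X[q]-X[p], ey = Y[q]-Y[p], ez = Z[q]-Z[p];
        // plane containing the edge, perpendicular to the face
        double cx = ey*nf_[2]-ez*nf_[1], cy = ez*nf_[0]-ex*nf_[2],
               cz = ex*nf_[1]-ey*nf_[0];
        double cl = std::sqrt(cx*cx + cy*cy + cz*cz);
        if (cl > 0) {
          cx /= cl; cy /= cl; cz /= cl;
          double d = -(cx*X[p] + cy*Y[p] + cz*Z[p]);
          double elen2 = ex*ex + ey*ey + ez*ez;
          Q[p].add_plane(cx, cy, cz, d, boundary_weight * elen2);
          Q[q].add_plane(cx, cy, cz, d, boundary_weight * elen2);
        }
      }
      i = j;
    }
  }

  std::vector<long> stamp(nv, 0);
  std::priority_queue<HeapEdge> heap;

  // faces currently shared by an edge (intersection of incidence lists)
  auto shared_faces = [&](int u, int v, std::vector<int>& out) {
    out.clear();
    for (int f : vfaces[u]) {
      if (!face_alive[f]) continue;
      int a = F[3*(size_t)f], b = F[3*(size_t)f+1], c = F[3*(size_t)f+2];
      if (a == v || b == v || c == v) out.push_back(f);
    }
  };

  auto neighbors = [&](int u, std::vector<int>& out) {
    out.clear();
    for (int f : vfaces[u]) {
      if (!face_alive[f]) continue;
      for (int j = 0; j < 3; ++j) {
        int w = F[3*(size_t)f+j];
        if (w != u) out.push_back(w);
      }
    }
    std::sort(out.begin(), out.end());
    out.erase(std::unique(out.begin(), out.end()), out.end());
  };

  std::vector<int> tmp_shared, tmp_nu, tmp_nv;

  auto push_edge = [&](int u, int v) {
    if (u == v || !vert_alive[u] || !vert_alive[v]) return;
    shared_faces(u, v, tmp_shared);
    if (tmp_shared.empty()) return;
    bool edge_boundary = tmp_shared.size() == 1;
    bool bu = vert_boundary[u], bv = vert_boundary[v];
    if (bu && bv && !edge_boundary) return; // would pinch the rim
    Quadric qe = Q[u]; qe += Q[v];
    double pos[3];
    double cost;
    bool have = false;
    if (bu != bv) {
      int bvert = bu ? u : v; // interior vertex slides onto the rim vertex
      pos[0] = X[bvert]; pos[1] = Y[bvert]; pos[2] = Z[bvert];
      cost = qe.eval(pos[0], pos[1], pos[2]);
      have = true;
    } else if (!edge_boundary && !bu) {
      double opt[3];
      if (qe.optimum(opt)) {
        pos[0]=opt[0]; pos[1]=opt[1]; pos[2]=opt[2];
        cost = qe.eval(opt[0], opt[1], opt[2]);
        have = true;
      }
    }
    if (!have) {
      // candidates: midpoint and both endpoints
      double cand[3][3] = {
        {0.5*(X[u]+X[v]), 0.5*(Y[u]+Y[v]), 0.5*(Z[u]+Z[v])},
        {X[u], Y[u], Z[u]},
        {X[v], Y[v], Z[v]}};
      cost = R_PosInf;
      for (int k = 0; k < 3; ++k) {
        double cst = qe.eval(cand[k][0], cand[k][1], cand[k][2]);
        if (cst < cost) { cost = cst; pos[0]=cand[k][0]; pos[1]=cand[k][1]; pos[2]=cand[k][2]; }
      }
    }
    if (!std::isfinite(cost)) return;
    HeapEdge he;
    he.cost = std::max(cost, 0.0);
    he.u = u; he.v = v;
    he.stamp_u = stamp[u]; he.stamp_v = stamp[v];
    he.pos[0]=pos[0]; he.pos[1]=pos[1]; he.pos[2]=pos[2];
    heap.push(he);
  };

  { // seed: every unique live edge
    std::vector<long long> seen;
    seen.reserve(3 * (size_t)nf0);
    for (int f = 0; f < nf0; ++f) {
      int vv[3] = {F[3*(size_t)f], F[3*(size_t)f+1], F[3*(size_t)f+2]};
      for (int j = 0; j < 3; ++j) {
        int p = std::min(vv[j], vv[(j+1)%3]);
        int q = std::max(vv[j], vv[(j+1)%3]);
        seen.push_back((long long)p * nv + q);
      }
    }
    std::sort(seen.begin(), seen.end());
    seen.erase(std::unique(seen.begin(), seen.end()), seen.end());
    for (long long key : seen) push_edge((int)(key / nv), (int)(key % nv));
  }

  int alive = nf0;
  std::vector<int> dying;

  while (alive > target && !heap.empty()) {
    HeapEdge he = heap.top(); heap.pop();
    int u = he.u, v = he.v;
    if (!vert_alive[u] || !vert_alive[v]) continue;
    if (he.stamp_u != stamp[u] || he.stamp_v != stamp[v]) continue;

    shared_faces(u, v, tmp_shared);
    int nshared = (int)tmp_shared.size();
    if (nshared == 0) continue;
    if (nshared > alive - target) continue; // would overshoot the budget

    // link condition: common neighbours must be exactly the apex vertices
    neighbors(u, tmp_nu);
    neighbors(v, tmp_nv);
    int ncommon = 0;
    {
      size_t i = 0, j = 0;
      while (i < tmp_nu.size() && j < tmp_nv.size()) {
        if (tmp_nu[i] < tmp_nv[j]) ++i;
        else if (tmp_nu[i] > tmp_nv[j]) ++j;
        else { ++ncommon; ++i; ++j; }
      }
    }
    if (ncommon != nshared) continue;

    // normal-flip / degeneracy guard on the surviving fan
    double ox = X[u], oy = Y[u], oz = Z[u];
    double ovx = X[v], ovy = Y[v], ovz = Z[v];
    bool flip = false;
    dying.assign(tmp_shared.begin(), tmp_shared.end());
    for (int pass = 0; pass < 2 && !flip; ++pass) {
      int w = pass == 0 ? u : v;
      for (int f : vfaces[w]) {
        if (!face_alive[f]) continue;
        if (std::find(dying.begin(), dying.end(), f) != dying.end()) continue;
        int a = F[3*(size_t)f], b = F[3*(size_t)f+1], c = F[3*(size_t)f+2];
        double nb[3];
        face_normal(X, Y, Z, a, b, c, nb);
        X[u]=he.pos[0]; Y[u]=he.pos[1]; Z[u]=he.pos[2];
        X[v]=he.pos[0]; Y[v]=he.pos[1]; Z[v]=he.pos[2];
        double na[3];
        face_normal(X, Y, Z, a, b, c, na);
        X[u]=ox; Y[u]=oy; Z[u]=oz;
        X[v]=ovx; Y[v]=ovy; Z[v]=ovz;
        double dot = nb[0]*na[0] + nb[1]*na[1] + nb[2]*na[2];
        double la = std::sqrt(na[0]*na[0]+na[1]*na[1]+na[2]*na[2]);
        if (dot <= 0 || la < 1e-14) { flip = true; break; }
      }
    }
    if (flip) continue;

    // ---- commit the collapse: v merges into u at he.pos ----
    X[u] = he.pos[0]; Y[u] = he.pos[1]; Z[u] = he.pos[2];
    Q[u] += Q[v];
    if (vert_boundary[v]) vert_boundary[u] = 1;
    for (int f : dying) {
      if (!face_alive[f]) continue;
      face_alive[f] = 0;
      --alive;
    }
    for (int f : vfaces[v]) {
      if (!face_alive[f]) continue;
      for (int j = 0; j < 3; ++j)
        if (F[3*(size_t)f+j] == v) F[3*(size_t)f+j] = u;
      vfaces[u].push_back(f);
    }
    vert_alive[v] = 0;
    ++stamp[u];
    // drop dead entries from u's incidence list now and then
    if (vfaces[u].size() > 64) {
      std::vector<int> keep;
      for (int f : vfaces[u]) if (face_alive[f]) keep.push_back(f);
      vfaces[u].swap(keep);
    }
    neighbors(u, tmp_nu);
    for (int w : tmp_nu) push_edge(u, w);
  }

  // compact the result
  std::vector<int> vmap(nv, -1);
  int nvo = 0;
  for (int i = 0; i < nv; ++i) if (vert_alive[i]) vmap[i] = nvo++;
  int nfo = 0;
  for (int f = 0; f < nf0; ++f) if (face_alive[f]) ++nfo;
  NumericMatrix Vout(nvo, 3);
  for (int i = 0; i < nv; ++i) {
    if (vmap[i] < 0) continue;
    Vout(vmap[i], 0) = X[i];
    Vout(vmap[i], 1) = Y[i];
    Vout(vmap[i], 2) = Z[i];
  }
  IntegerMatrix Fout(nfo, 3);
  int r = 0;
  for (int f = 0; f < nf0; ++f) {
    if (!face_alive[f]) continue;
    for (int j = 0; j < 3; ++j) Fout(r, j) = vmap[F[3*(size_t)f+j]] + 1;
    ++r;
  }
  return List::create(_["vertices"] = Vout, _["faces"] = Fout,
                      _["achieved"] = alive);
}
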