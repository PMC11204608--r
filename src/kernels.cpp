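#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Isosurface extraction by marching tetrahedra.
//
// Each grid cell is split into six tetrahedra sharing the main diagonal, so
// neighbouring cells tile space conformally and the extracted surface is
// watertight for any field padded with below-level values.  Surface vertices
// are shared through a global edge table keyed on the grid-corner pair.
// ---------------------------------------------------------------------------

static const int TET[6][4] = {
  {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
  {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}
};
// corner bit code: i = dx + 2*dy + 4*dz
static const int CDX[8] = {0, 1, 0, 1, 0, 1, 0, 1};
static const int CDY[8] = {0, 0, 1, 1, 0, 0, 1, 1};
static const int CDZ[8] = {0, 0, 0, 0, 1, 1, 1, 1};

struct MTState {
  std::unordered_map<uint64_t, int> edge;
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;
};

static int mt_vertex(MTState &st, uint64_t ga, uint64_t gb,
                     double ax, double ay, double az,
                     double bx, double by, double bz,
                     double va, double vb, double level) {
  uint64_t key = ga < gb ? (ga << 32) | gb : (gb << 32) | ga;
  std::unordered_map<uint64_t, int>::iterator it = st.edge.find(key);
  if (it != st.edge.end()) return it->second;
  double t = (level - va) / (vb - va);
  int id = (int)st.vx.size();
  st.vx.push_back(ax + t * (bx - ax));
  st.vy.push_back(ay + t * (by - ay));
  st.vz.push_back(az + t * (bz - az));
  st.edge[key] = id;
  return id;
}

static void mt_emit(MTState &st, int a, int b, int c,
                    double rx, double ry, double rz) {
  // orient so the normal points away from the inside of the solid
  double ux = st.vx[b] - st.vx[a], uy = st.vy[b] - st.vy[a], uz = st.vz[b] - st.vz[a];
  double wx = st.vx[c] - st.vx[a], wy = st.vy[c] - st.vy[a], wz = st.vz[c] - st.vz[a];
  double nx = uy * wz - uz * wy, ny = uz * wx - ux * wz, nz = ux * wy - uy * wx;
  double gx = (st.vx[a] + st.vx[b] + st.vx[c]) / 3.0 - rx;
  double gy = (st.vy[a] + st.vy[b] + st.vy[c]) / 3.0 - ry;
  double gz = (st.vz[a] + st.vz[b] + st.vz[c]) / 3.0 - rz;
  if (nx * gx + ny * gy + nz * gz < 0) { int tmp = b; b = c; c = tmp; }
  st.f0.push_back(a); st.f1.push_back(b); st.f2.push_back(c);
}

// [[Rcpp::export]]
List cpp_marching_tets(NumericVector field, IntegerVector dims,
                       NumericVector spacing, NumericVector origin,
                       double level) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double *fv = field.begin();
  MTState st;

  double px[8], py[8], pz[8], cv[8];
  uint64_t gid[8];
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        int nin = 0;
        for (int c = 0; c < 8; ++c) {
          int ii = i + CDX[c], jj = j + CDY[c], kk = k + CDZ[c];
          size_t lin = (size_t)ii + (size_t)nx * ((size_t)jj + (size_t)ny * kk);
          cv[c] = fv[lin];
          gid[c] = (uint64_t)lin;
          px[c] = ox + ii * sx; py[c] = oy + jj * sy; pz[c] = oz + kk * sz;
          if (cv[c] >= level) ++nin;
        }
        if (nin == 0 || nin == 8) continue;
        for (int t = 0; t < 6; ++t) {
          int ins[4], outs[4], ni = 0, no = 0;
          for (int m = 0; m < 4; ++m) {
            int c = TET[t][m];
            if (cv[c] >= level) ins[ni++] = c; else outs[no++] = c;
          }
          if (ni == 0 || ni == 4) continue;
          double rx = 0, ry = 0, rz = 0;
          for (int m = 0; m < ni; ++m) { rx += px[ins[m]]; ry += py[ins[m]]; rz += pz[ins[m]]; }
          rx /= ni; ry /= ni; rz /= ni;
          if (ni == 1) {
            int a = ins[0];
            int v0 = mt_vertex(st, gid[a], gid[outs[0]], px[a], py[a], pz[a], px[outs[0]], py[outs[0]], pz[outs[0]], cv[a], cv[outs[0]], level);
            int v1 = mt_vertex(st, gid[a], gid[outs[1]], px[a], py[a], pz[a], px[outs[1]], py[outs[1]], pz[outs[1]], cv[a], cv[outs[1]], level);
            int v2 = mt_vertex(st, gid[a], gid[outs[2]], px[a], py[a], pz[a], px[outs[2]], py[outs[2]], pz[outs[2]], cv[a], cv[outs[2]], level);
            mt_emit(st, v0, v1, v2, rx, ry, rz);
          } else if (ni == 3) {
            int a = outs[0];
            int v0 = mt_vertex(st, gid[ins[0]], gid[a], px[ins[0]], py[ins[0]], pz[ins[0]], px[a], py[a], pz[a], cv[ins[0]], cv[a], level);
            int v1 = mt_vertex(st, gid[ins[1]], gid[a], px[ins[1]], py[ins[1]], pz[ins[1]], px[a], py[a], pz[a], cv[ins[1]], cv[a], level);
            int v2 = mt_vertex(st, gid[ins[2]], gid[a], px[ins[2]], py[ins[2]], pz[ins[2]], px[a], py[a], pz[a], cv[ins[2]], cv[a], level);
            mt_emit(st, v0, v1, v2, rx, ry, rz);
          } else {
            int a = ins[0], b = ins[1], c = outs[0], d = outs[1];
            int q0 = mt_vertex(st, gid[a], gid[c], px[a], py[a], pz[a], px[c], py[c], pz[c], cv[a], cv[c], level);
            int q1 = mt_vertex(st, gid[a], gid[d], px[a], py[a], pz[a], px[d], py[d], pz[d], cv[a], cv[d], level);
            int q2 = mt_vertex(st, gid[b], gid[d], px[b], py[b], pz[b], px[d], py[d], pz[d], cv[b], cv[d], level);
            int q3 = mt_vertex(st, gid[b], gid[c], px[b], py[b], pz[b], px[c], py[c], pz[c], cv[b], cv[c], level);
            mt_emit(st, q0, q1, q2, rx, ry, rz);
            mt_emit(st, q0, q2, q3, rx, ry, rz);
          }
        }
      }

  int nV = (int)st.vx.size(), nF = (int)st.f0.size();
  NumericMatrix V(nV, 3);
  for (int i = 0; i < nV; ++i) { V(i, 0) = st.vx[i]; V(i, 1) = st.vy[i]; V(i, 2) = st.vz[i]; }
  IntegerMatrix F(nF, 3);
  for (int i = 0; i < nF; ++i) { F(i, 0) = st.f0[i] + 1; F(i, 1) = st.f1[i] + 1; F(i, 2) = st.f2[i] + 1; }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// ---------------------------------------------------------------------------
// Closest point on a triangle (Ericson, Real-Time Collision Detection)
// ---------------------------------------------------------------------------
static inline void closest_pt_tri(const double *p, const double *a,
                                  const double *b, const double *c,
                                  double *out) {
  double ab[3] = {b[0]-a[0], b[1]-a[1], b[2]-a[2]};
  double ac[3] = {c[0]-a[0], c[1]-a[1], c[2]-a[2]};
  double ap[3] = {p[0]-a[0], p[1]-a[1], p[2]-a[2]};
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  if (d1 <= 0 && d2 <= 0) { out[0]=a[0]; out[1]=a[1]; out[2]=a[2]; return; }
  double bp[3] = {p[0]-b[0], p[1]-b[1], p[2]-b[2]};
  double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
  double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
  if (d3 >= 0 && d4 <= d3) { out[0]=b[0]; out[1]=b[1]; out[2]=b[2]; return; }
  double vc = d1*d4 - d3*d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    out[0]=a[0]+v*ab[0]; out[1]=a[1]+v*ab[1]; out[2]=a[2]+v*ab[2]; return;
  }
  double cp[3] = {p[0]-c[0], p[1]-c[1], p[2]-c[2]};
  double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
  double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
  if (d6 >= 0 && d5 <= d6) { out[0]=c[0]; out[1]=c[1]; out[2]=c[2]; return; }
  double vb = d5*d2 - d1*d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    out[0]=a[0]+w*ac[0]; out[1]=a[1]+w*ac[1]; out[2]=a[2]+w*ac[2]; return;
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    out[0]=b[0]+w*(c[0]-b[0]); out[1]=b[1]+w*(c[1]-b[1]); out[2]=b[2]+w*(c[2]-b[2]); return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  out[0]=a[0]+ab[0]*v+ac[0]*w; out[1]=a[1]+ab[1]*v+ac[1]*w; out[2]=a[2]+ab[2]*v+ac[2]*w;
}

// Uniform-grid-accelerated closest point queries on a triangle soup.
// [[Rcpp::export]]
List cpp_closest_points(NumericMatrix Q, NumericMatrix V, IntegerMatrix F) {
  const int nq = Q.nrow(), nf = F.nrow();
  NumericVector dist(nq);
  NumericMatrix P(nq, 3);
  IntegerVector fid(nq);
  if (nf == 0) stop("mesh has no faces");

  // mesh bbox
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
  for (int i = 0; i < V.nrow(); ++i)
    for (int d = 0; d < 3; ++d) {
      if (V(i, d) < lo[d]) lo[d] = V(i, d);
      if (V(i, d) > hi[d]) hi[d] = V(i, d);
    }
  // cell size from mean triangle extent
  double msz = 0;
  for (int f = 0; f < nf; ++f) {
    double e = 0;
    for (int d = 0; d < 3; ++d) {
      double t0 = V(F(f,0)-1, d), t1 = V(F(f,1)-1, d), t2 = V(F(f,2)-1, d);
      double mn = std::min(t0, std::min(t1, t2)), mx = std::max(t0, std::max(t1, t2));
      e = std::max(e, mx - mn);
    }
    msz += e;
  }
  msz /= nf;
  double h = std::max(msz * 2.0, 1e-9);
  int ng[3];
  for (int d = 0; d < 3; ++d) {
    double ext = std::max(hi[d] - lo[d], 1e-9);
    ng[d] = std::max(1, std::min(160, (int)std::ceil(ext / h)));
  }
  double cs[3];
  for (int d = 0; d < 3; ++d) cs[d] = std::max((hi[d] - lo[d]) / ng[d], 1e-9);
  double hmin = std::min(cs[0], std::min(cs[1], cs[2]));

  // bin triangles by bbox
  const size_t ncell = (size_t)ng[0] * ng[1] * ng[2];
  std::vector<std::vector<int> > bins(ncell);
  for (int f = 0; f < nf; ++f) {
    int c0[3], c1[3];
    for (int d = 0; d < 3; ++d) {
      double t0 = V(F(f,0)-1, d), t1 = V(F(f,1)-1, d), t2 = V(F(f,2)-1, d);
      double mn = std::min(t0, std::min(t1, t2)), mx = std::max(t0, std::max(t1, t2));
      c0[d] = std::max(0, std::min(ng[d]-1, (int)((mn - lo[d]) / cs[d])));
      c1[d] = std::max(0, std::min(ng[d]-1, (int)((mx - lo[d]) / cs[d])));
    }
    for (int z = c0[2]; z <= c1[2]; ++z)
      for (int y = c0[1]; y <= c1[1]; ++y)
        for (int x = c0[0]; x <= c1[0]; ++x)
          bins[(size_t)x + (size_t)ng[0] * ((size_t)y + (size_t)ng[1] * z)].push_back(f);
  }

  const int maxr = ng[0] + ng[1] + ng[2] + 2;
  double a[3], b[3], c[3], p[3], out[3];
  for (int q = 0; q < nq; ++q) {
    p[0] = Q(q, 0); p[1] = Q(q, 1); p[2] = Q(q, 2);
    int cc[3];
    for (int d = 0; d < 3; ++d) {
      int ci = (int)((p[d] - lo[d]) / cs[d]);
      cc[d] = std::max(0, std::min(ng[d]-1, ci));
    }
    double best = R_PosInf; int bestf = -1;
    for (int r = 0; r <= maxr; ++r) {
      // within the grid, a ring-r cell is at least (r-1)*hmin away
      if (bestf >= 0 && (double)(r - 1) * hmin >= best) break;
      bool any = false;
      int x0 = cc[0]-r, x1 = cc[0]+r, y0 = cc[1]-r, y1 = cc[1]+r, z0 = cc[2]-r, z1 = cc[2]+r;
      for (int z = std::max(0, z0); z <= std::min(ng[2]-1, z1); ++z)
        for (int y = std::max(0, y0); y <= std::min(ng[1]-1, y1); ++y)
          for (int x = std::max(0, x0); x <= std::min(ng[0]-1, x1); ++x) {
            // only the shell of the Chebyshev ball
            if (r > 0 && x != x0 && x != x1 && y != y0 && y != y1 && z != z0 && z != z1)
              continue;
            any = true;
            const std::vector<int> &bin = bins[(size_t)x + (size_t)ng[0] * ((size_t)y + (size_t)ng[1] * z)];
            if (bin.empty()) continue;
            // exact point-to-cell-box distance prune
            double bd2 = 0.0;
            double cl[3] = {lo[0] + x * cs[0], lo[1] + y * cs[1], lo[2] + z * cs[2]};
            double ch[3] = {cl[0] + cs[0], cl[1] + cs[1], cl[2] + cs[2]};
            for (int d = 0; d < 3; ++d) {
              double dd = (p[d] < cl[d]) ? cl[d] - p[d] : ((p[d] > ch[d]) ? p[d] - ch[d] : 0.0);
              bd2 += dd * dd;
            }
            if (bestf >= 0 && bd2 >= best * best) continue;
            for (size_t m = 0; m < bin.size(); ++m) {
              int f = bin[m];
              for (int d = 0; d < 3; ++d) {
                a[d] = V(F(f,0)-1, d); b[d] = V(F(f,1)-1, d); c[d] = V(F(f,2)-1, d);
              }
              closest_pt_tri(p, a, b, c, out);
              double dx = out[0]-p[0], dy = out[1]-p[1], dz = out[2]-p[2];
              double dd = std::sqrt(dx*dx + dy*dy + dz*dz);
              if (dd < best) { best = dd; bestf = f; P(q,0)=out[0]; P(q,1)=out[1]; P(q,2)=out[2]; }
            }
          }
      if (!any && bestf >= 0) break;
    }
    dist[q] = best;
    fid[q] = bestf + 1;
  }
  return List::create(_["distance"] = dist, _["point"] = P, _["face"] = fid);
}

// ---------------------------------------------------------------------------
// Connected components of faces (faces joined through shared vertices)
// ---------------------------------------------------------------------------
static int uf_find(std::vector<int> &up, int x) {
  while (up[x] != x) { up[x] = up[up[x]]; x = up[x]; }
  return x;
}

// [[Rcpp::export]]
IntegerVector cpp_face_components(IntegerMatrix F, int nV) {
  std::vector<int> up(nV);
  for (int i = 0; i < nV; ++i) up[i] = i;
  const int nf = F.nrow();
  for (int f = 0; f < nf; ++f) {
    int a = uf_find(up, F(f,0)-1), b = uf_find(up, F(f,1)-1), c = uf_find(up, F(f,2)-1);
    if (b != a) up[b] = a;
    if (c != a) up[uf_find(up, c)] = a;
  }
  std::unordered_map<int,int> relab;
  IntegerVector comp(nf);
  int nxt = 0;
  for (int f = 0; f < nf; ++f) {
    int r = uf_find(up, F(f,0)-1);
    std::unordered_map<int,int>::iterator it = relab.find(r);
    if (it == relab.end()) { relab[r] = ++nxt; comp[f] = nxt; }
    else comp[f] = it->second;
  }
  return comp;
}
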