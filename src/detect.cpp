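// Grid-based tunnel detection for a single frame.
//
// The void space of a frame is discretised on a regular cubic lattice with
// 26-neighbour connectivity. Each node's clearance is the exact distance to
// the nearest atom surface (distance to the nearest atom centre minus that
// atom's vdW radius), found with a cell-list nearest-neighbour search and
// memoised lazily, so only the region explored by the path search pays for
// clearance evaluation. A node whose raw clearance falls just below the
// probe (within half a lattice diagonal) is re-tested after a bounded local
// clearance maximisation; this keeps channels whose true radius admits the
// probe traversable even when no lattice node sits on their axis. Tunnels
// are minimum-cost Dijkstra paths (edge cost len / r_mean^wc) from the node
// nearest the starting point to the exterior (nodes radially beyond the
// outermost atom plus shell_radius), extracted greedily best-throughput
// first; after each accepted path the nodes inside its void tube are
// blocked, so each physical exit yields one tunnel. Finally path nodes are
// polished by a finer local search, giving sub-grid bottleneck accuracy.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

namespace {

struct CellList {
  double h, lo[3];
  int dim[3];
  double vdw_max;
  std::vector<double> ax, ay, az, ar;  // atom data, CSR order
  std::vector<int> cell_start;         // CSR offsets, size ncell+1

  void build(const NumericMatrix &coords, const NumericVector &vdw,
             double cell) {
    int n = coords.nrow();
    h = cell;
    double hi[3];
    for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
    vdw_max = 0.0;
    for (int i = 0; i < n; ++i) {
      for (int d = 0; d < 3; ++d) {
        double v = coords(i, d);
        if (v < lo[d]) lo[d] = v;
        if (v > hi[d]) hi[d] = v;
      }
      if (vdw[i] > vdw_max) vdw_max = vdw[i];
    }
    size_t ncell = 1;
    for (int d = 0; d < 3; ++d) {
      lo[d] -= 1e-9;
      dim[d] = std::max(1, (int)std::floor((hi[d] - lo[d]) / h) + 1);
      ncell *= dim[d];
    }
    std::vector<int> cidx(n);
    std::vector<int> count(ncell + 1, 0);
    for (int i = 0; i < n; ++i) {
      int c[3];
      for (int d = 0; d < 3; ++d) {
        c[d] = (int)std::floor((coords(i, d) - lo[d]) / h);
        if (c[d] < 0) c[d] = 0;
        if (c[d] >= dim[d]) c[d] = dim[d] - 1;
      }
      cidx[i] = ((size_t)c[0] * dim[1] + c[1]) * dim[2] + c[2];
      ++count[cidx[i] + 1];
    }
    cell_start.assign(ncell + 1, 0);
    for (size_t c = 0; c < ncell; ++c)
      cell_start[c + 1] = cell_start[c] + count[c + 1];
    ax.resize(n); ay.resize(n); az.resize(n); ar.resize(n);
    std::vector<int> fill(cell_start.begin(), cell_start.end() - 1);
    for (int i = 0; i < n; ++i) {
      int p = fill[cidx[i]]++;
      ax[p] = coords(i, 0); ay[p] = coords(i, 1); az[p] = coords(i, 2);
      ar[p] = vdw[i];
    }
  }

  // exact clearance: min_i (|q - a_i| - vdw_i)
  double clearance(double qx, double qy, double qz) const {
    int cq[3];
    double q[3] = { qx, qy, qz };
    for (int d = 0; d < 3; ++d)
      cq[d] = (int)std::floor((q[d] - lo[d]) / h);
    double best = R_PosInf;
    int kmax = dim[0] + dim[1] + dim[2] + 2;
    for (int k = 0; k <= kmax; ++k) {
      // no atom in farther rings can beat the current best
      if (best < R_PosInf && best + vdw_max <= (k - 1) * h) break;
      for (int ix = cq[0] - k; ix <= cq[0] + k; ++ix) {
        if (ix < 0 || ix >= dim[0]) continue;
        bool face_x = (ix == cq[0] - k || ix == cq[0] + k);
        double bx = (ix < cq[0]) ? (q[0] - (lo[0] + (ix + 1) * h))
                  : (ix > cq[0]) ? ((lo[0] + ix * h) - q[0]) : 0.0;
        for (int iy = cq[1] - k; iy <= cq[1] + k; ++iy) {
          if (iy < 0 || iy >= dim[1]) continue;
          bool face_y = (iy == cq[1] - k || iy == cq[1] + k);
          double by = (iy < cq[1]) ? (q[1] - (lo[1] + (iy + 1) * h))
                    : (iy > cq[1]) ? ((lo[1] + iy * h) - q[1]) : 0.0;
          int zlo = cq[2] - k, zhi = cq[2] + k, zstep = 1;
          if (face_x || face_y) { /* whole z-range is on the ring */ }
          else zstep = (zhi > zlo) ? (zhi - zlo) : 1;  // only the two z-faces
          for (int iz = zlo; iz <= zhi; iz += zstep) {
            if (iz < 0 || iz >= dim[2]) continue;
            double bz = (iz < cq[2]) ? (q[2] - (lo[2] + (iz + 1) * h))
                      : (iz > cq[2]) ? ((lo[2] + iz * h) - q[2]) : 0.0;
            double box2 = bx * bx + by * by + bz * bz;
            if (best < R_PosInf &&
                std::sqrt(box2) - vdw_max >= best) continue;
            size_t c = ((size_t)ix * dim[1] + iy) * dim[2] + iz;
            for (int p = cell_start[c]; p < cell_start[c + 1]; ++p) {
              double dx = qx - ax[p], dy = qy - ay[p], dz = qz - az[p];
              double cc = std::sqrt(dx * dx + dy * dy + dz * dz) - ar[p];
              if (cc < best) best = cc;
            }
            if (zstep <= 0) break;
          }
        }
      }
    }
    return best;
  }

  // best clearance within a small box around q: two-stage local search.
  // stop_at: early exit once that clearance is reached (use R_PosInf for a
  // full maximisation).
  double refine(double q[3], double step1, double step2, double *best_c,
                double stop_at = R_PosInf) const {
    double bp[3] = { q[0], q[1], q[2] };
    double best = clearance(q[0], q[1], q[2]);
    const double steps[2] = { step1, step2 };
    for (int stage = 0; stage < 2 && best < stop_at; ++stage) {
      double c0[3] = { bp[0], bp[1], bp[2] };
      for (int a = -1; a <= 1 && best < stop_at; ++a)
        for (int b = -1; b <= 1 && best < stop_at; ++b)
          for (int c = -1; c <= 1; ++c) {
            if (a == 0 && b == 0 && c == 0) continue;
            double p[3] = { c0[0] + a * steps[stage],
                            c0[1] + b * steps[stage],
                            c0[2] + c * steps[stage] };
            double cc = clearance(p[0], p[1], p[2]);
            if (cc > best + 1e-12) {
              best = cc;
              bp[0] = p[0]; bp[1] = p[1]; bp[2] = p[2];
              if (best >= stop_at) break;
            }
          }
    }
    q[0] = bp[0]; q[1] = bp[1]; q[2] = bp[2];
    *best_c = best;
    return best;
  }
};

struct Grid {
  double lo[3], spacing;
  int dim[3];
  size_t nnode;
  int idx(int ix, int iy, int iz) const {
    return (int)(((size_t)ix * dim[1] + iy) * dim[2] + iz);
  }
  void pos(int id, double *p) const {
    int iz = id % dim[2];
    int iy = (id / dim[2]) % dim[1];
    int ix = id / (dim[1] * dim[2]);
    p[0] = lo[0] + ix * spacing;
    p[1] = lo[1] + iy * spacing;
    p[2] = lo[2] + iz * spacing;
  }
  void coords(int id, int *c) const {
    c[2] = id % dim[2];
    c[1] = (id / dim[2]) % dim[1];
    c[0] = id / (dim[1] * dim[2]);
  }
};

} // namespace

// [[Rcpp::export(name = ".detect_frame_cpp")]]
List detect_frame_cpp(NumericMatrix coords, NumericVector vdw,
                      NumericVector start, double probe, double wc,
                      double spacing, double shell_radius, double shell_depth,
                      int max_tunnels, double block_cap, bool refine) {
  const int natom = coords.nrow();
  if (natom < 4) stop("need at least 4 atoms");

  CellList cl;
  cl.build(coords, vdw, 2.5);

  double cen[3] = {0, 0, 0};
  for (int i = 0; i < natom; ++i) {
    cen[0] += coords(i, 0); cen[1] += coords(i, 1); cen[2] += coords(i, 2);
  }
  for (int d = 0; d < 3; ++d) cen[d] /= natom;
  double rmax = 0.0;
  for (int i = 0; i < natom; ++i) {
    double dx = coords(i, 0) - cen[0], dy = coords(i, 1) - cen[1],
           dz = coords(i, 2) - cen[2];
    double rr = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (rr > rmax) rmax = rr;
  }
  const double r_ext = rmax + shell_radius;
  const double reach = r_ext + shell_depth;

  Grid g;
  g.spacing = spacing;
  for (int d = 0; d < 3; ++d) {
    g.lo[d] = cen[d] - reach;
    g.dim[d] = (int)std::floor(2.0 * reach / spacing) + 1;
  }
  g.nnode = (size_t)g.dim[0] * g.dim[1] * g.dim[2];

  double sd = 0.0;
  for (int d = 0; d < 3; ++d) sd += (start[d] - cen[d]) * (start[d] - cen[d]);
  if (std::sqrt(sd) > r_ext)
    stop("start point lies outside the structure (radial distance %.2f > %.2f)",
         std::sqrt(sd), r_ext);
  int sc[3];
  for (int d = 0; d < 3; ++d) {
    sc[d] = (int)std::floor((start[d] - g.lo[d]) / spacing + 0.5);
    if (sc[d] < 0) sc[d] = 0;
    if (sc[d] >= g.dim[d]) sc[d] = g.dim[d] - 1;
  }
  const int start_id = g.idx(sc[0], sc[1], sc[2]);
  double spos[3];
  g.pos(start_id, spos);
  double start_clear = cl.clearance(spos[0], spos[1], spos[2]);
  if (start_clear <= 0.0)
    stop("start point lies inside an atom (clearance %.3f at nearest grid node)",
         start_clear);

  // lazy effective clearance: raw, or locally refined when the raw value
  // falls within half a lattice diagonal below the probe
  std::vector<double> clear_cache(g.nnode,
                                  std::numeric_limits<double>::quiet_NaN());
  std::vector<unsigned char> blocked(g.nnode, 0);
  // a local search can raise clearance by at most its diagonal reach;
  // only nodes within that band below the probe are worth refining
  const double band = (spacing / 3.0 + spacing / 9.0) * std::sqrt(3.0);
  struct Eval {
    const CellList *cl; const Grid *g; double probe, band, spacing;
    std::vector<double> *cache;
    double operator()(int id) {
      double c = (*cache)[id];
      if (!std::isnan(c)) return c;
      double p[3];
      g->pos(id, p);
      c = cl->clearance(p[0], p[1], p[2]);
      if (c < probe && c + band >= probe) {
        double q[3] = { p[0], p[1], p[2] }, rc;
        cl->refine(q, spacing / 3.0, spacing / 9.0, &rc, probe);
        if (rc > c) c = rc;
      }
      (*cache)[id] = c;
      return c;
    }
  } eval = { &cl, &g, probe, band, spacing, &clear_cache };
  clear_cache[start_id] = start_clear;

  int noff[26][3];
  double nlen[26];
  {
    int m = 0;
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c) {
          if (a == 0 && b == 0 && c == 0) continue;
          noff[m][0] = a; noff[m][1] = b; noff[m][2] = c;
          nlen[m] = spacing * std::sqrt((double)(a * a + b * b + c * c));
          ++m;
        }
  }

  List tunnels;
  const double r_ext2 = r_ext * r_ext;
  if (start_clear < probe) return tunnels;  // sealed: no admissible start

  std::vector<double> dist(g.nnode);
  std::vector<int> pred(g.nnode);

  for (int iter = 0; iter < max_tunnels; ++iter) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    std::fill(pred.begin(), pred.end(), -1);
    typedef std::pair<double, int> QE;
    std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
    dist[start_id] = 0.0;
    pq.push(QE(0.0, start_id));
    int exit_id = -1;

    while (!pq.empty()) {
      QE top = pq.top(); pq.pop();
      int u = top.second;
      if (top.first > dist[u]) continue;
      double up[3];
      g.pos(u, up);
      double ur2 = 0.0;
      for (int d = 0; d < 3; ++d) ur2 += (up[d] - cen[d]) * (up[d] - cen[d]);
      if (ur2 > r_ext2) { exit_id = u; break; }  // cheapest exterior node
      int uc[3];
      g.coords(u, uc);
      double cu = clear_cache[u];
      for (int m = 0; m < 26; ++m) {
        int vx = uc[0] + noff[m][0], vy = uc[1] + noff[m][1],
            vz = uc[2] + noff[m][2];
        if (vx < 0 || vx >= g.dim[0] || vy < 0 || vy >= g.dim[1] ||
            vz < 0 || vz >= g.dim[2]) continue;
        int v = g.idx(vx, vy, vz);
        if (blocked[v]) continue;
        double cv = eval(v);
        if (cv < probe) continue;
        double rm = 0.5 * (cu + cv);
        double w = (wc == 2.0) ? nlen[m] / (rm * rm)
                 : (wc == 0.0) ? nlen[m]
                 : (wc == 1.0) ? nlen[m] / rm
                 : nlen[m] / std::pow(rm, wc);
        double nd = dist[u] + w;
        if (nd < dist[v]) {
          dist[v] = nd;
          pred[v] = u;
          pq.push(QE(nd, v));
        }
      }
    }

    if (exit_id < 0) break;

    std::vector<int> path;
    for (int u = exit_id; u != -1; u = pred[u]) path.push_back(u);
    std::reverse(path.begin(), path.end());

    // block the tunnel's void tube (start neighbourhood exempt)
    double keep2 = (block_cap + spacing) * (block_cap + spacing);
    for (size_t pi = 0; pi < path.size(); ++pi) {
      int u = path[pi];
      double up[3];
      g.pos(u, up);
      double rb = std::min(clear_cache[u], block_cap);
      if (rb < spacing) rb = spacing;
      int c0[3], lo_i[3], hi_i[3];
      g.coords(u, c0);
      int span = (int)std::ceil(rb / spacing);
      for (int d = 0; d < 3; ++d) {
        lo_i[d] = std::max(0, c0[d] - span);
        hi_i[d] = std::min(g.dim[d] - 1, c0[d] + span);
      }
      for (int ix = lo_i[0]; ix <= hi_i[0]; ++ix)
        for (int iy = lo_i[1]; iy <= hi_i[1]; ++iy)
          for (int iz = lo_i[2]; iz <= hi_i[2]; ++iz) {
            int v = g.idx(ix, iy, iz);
            double vp[3];
            g.pos(v, vp);
            double d2 = 0.0, ds2 = 0.0;
            for (int d = 0; d < 3; ++d) {
              d2 += (vp[d] - up[d]) * (vp[d] - up[d]);
              ds2 += (vp[d] - spos[d]) * (vp[d] - spos[d]);
            }
            if (d2 <= rb * rb && ds2 > keep2) blocked[v] = 1;
          }
    }

    // profile: polished node positions + clearances
    NumericMatrix prof(path.size(), 4);
    for (size_t pi = 0; pi < path.size(); ++pi) {
      double p[3];
      g.pos(path[pi], p);
      double best = clear_cache[path[pi]];
      if (refine) {
        double rc;
        cl.refine(p, spacing / 2.0, spacing / 8.0, &rc);
        if (rc > best) best = rc;
      }
      prof(pi, 0) = p[0]; prof(pi, 1) = p[1]; prof(pi, 2) = p[2];
      prof(pi, 3) = best;
    }
    tunnels.push_back(prof);
  }

  return tunnels;
}

// Exact clearance (distance to nearest atom surface) at arbitrary points.
// [[Rcpp::export(name = ".clearance_at_cpp")]]
NumericVector clearance_at_cpp(NumericMatrix coords, NumericVector vdw,
                               NumericMatrix points) {
  CellList cl;
  cl.build(coords, vdw, 2.5);
  int n = points.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = cl.clearance(points(i, 0), points(i, 1), points(i, 2));
  return out;
}

// Pairwise mean point distance between order-aligned resampled paths.
// P: n x (3k) matrix, row i = (x1,y1,z1,...,xk,yk,zk) of path i.
// Returns the lower-triangle dist vector (as used by stats::as.dist).
// [[Rcpp::export(name = ".path_distmat_cpp")]]
NumericVector path_distmat_cpp(NumericMatrix P) {
  int n = P.nrow();
  int k = P.ncol() / 3;
  NumericVector out((size_t)n * (n - 1) / 2);
  size_t m = 0;
  for (int j = 0; j < n - 1; ++j)
    for (int i = j + 1; i < n; ++i) {
      double s = 0.0;
      for (int t = 0; t < k; ++t) {
        double dx = P(i, 3 * t) - P(j, 3 * t);
        double dy = P(i, 3 * t + 1) - P(j, 3 * t + 1);
        double dz = P(i, 3 * t + 2) - P(j, 3 * t + 2);
        s += std::sqrt(dx * dx + dy * dy + dz * dz);
      }
      out[m++] = s / k;
    }
  return out;
}
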