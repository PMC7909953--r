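#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Voxel volumes are passed as flat 0/1 integer vectors with index
// i = x + nx * (y + ny * z), x/y/z 0-based. All sizes used here fit in int
// (largest grids are a few hundred voxels per side).

static inline long lidx(int x, int y, int z, int nx, int ny) {
  return (long)x + (long)nx * ((long)y + (long)ny * (long)z);
}

// ---------------------------------------------------------------------------
// Simple-point test (26-adjacency for foreground, 6-adjacency for background).
// A voxel is simple iff deleting it does not change the topology of its
// 3x3x3 neighbourhood: exactly one 26-component of foreground among the 26
// neighbours, and exactly one 6-component of background in the 18-neighbourhood
// that is 6-adjacent to the centre.
// ---------------------------------------------------------------------------

// nb: 27 occupancy values of the 3x3x3 cube, index (dx+1) + 3*(dy+1) + 9*(dz+1).
static bool simple_point(const int nb[27]) {
  // --- condition 1: one 26-connected foreground component among neighbours ---
  int comp[27];
  for (int i = 0; i < 27; ++i) comp[i] = 0;
  int ncomp_fg = 0;
  int stack[27];
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || comp[i]) continue;
    if (++ncomp_fg > 1) return false;
    int sp = 0;
    stack[sp++] = i;
    comp[i] = 1;
    while (sp > 0) {
      int c = stack[--sp];
      int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int x = cx + dx, y = cy + dy, z = cz + dz;
            if (x < 0 || x > 2 || y < 0 || y > 2 || z < 0 || z > 2) continue;
            int j = x + 3 * y + 9 * z;
            if (j == 13 || j == c || !nb[j] || comp[j]) continue;
            comp[j] = 1;
            stack[sp++] = j;
          }
    }
  }
  if (ncomp_fg != 1) return false;

  // --- condition 2: one 6-component of background in the 18-neighbourhood
  //     touching a face neighbour of the centre ---
  // 18-neighbourhood: |dx|+|dy|+|dz| <= 2, excluding centre and corners.
  int bcomp[27];
  for (int i = 0; i < 27; ++i) bcomp[i] = 0;
  int ncomp_bg = 0;
  for (int i = 0; i < 27; ++i) {
    int ix = i % 3 - 1, iy = (i / 3) % 3 - 1, iz = i / 9 - 1;
    int man = std::abs(ix) + std::abs(iy) + std::abs(iz);
    if (man != 1) continue;          // seed only from face neighbours
    if (nb[i] || bcomp[i]) continue; // must be background, unvisited
    if (++ncomp_bg > 1) return false;
    int sp = 0;
    stack[sp++] = i;
    bcomp[i] = 1;
    while (sp > 0) {
      int c = stack[--sp];
      int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      const int face[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int f = 0; f < 6; ++f) {
        int x = cx + face[f][0], y = cy + face[f][1], z = cz + face[f][2];
        if (x < 0 || x > 2 || y < 0 || y > 2 || z < 0 || z > 2) continue;
        int man2 = std::abs(x - 1) + std::abs(y - 1) + std::abs(z - 1);
        if (man2 == 0 || man2 == 3) continue; // centre or corner: outside 18-nbhd
        int j = x + 3 * y + 9 * z;
        if (nb[j] || bcomp[j]) continue;
        bcomp[j] = 1;
        stack[sp++] = j;
      }
    }
  }
  return ncomp_bg == 1;
}

static inline void load_neighbourhood(const std::vector<uint8_t>& v,
                                      int x, int y, int z,
                                      int nx, int ny, int nz, int nb[27]) {
  int k = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++k) {
        int xx = x + dx, yy = y + dy, zz = z + dz;
        // note: loop order makes k = (dx+1) + 3*(dy+1) + 9*(dz+1)
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          nb[k] = 0;
        else
          nb[k] = v[lidx(xx, yy, zz, nx, ny)];
      }
}

static inline int count_fg_neighbours(const int nb[27]) {
  int n = 0;
  for (int i = 0; i < 27; ++i)
    if (i != 13 && nb[i]) ++n;
  return n;
}

// Homotopic thinning to a 1-voxel-wide curve skeleton. Six directional
// subiterations per pass (borders U/D/N/S/E/W); within a subiteration,
// candidate border points that are simple and not line endpoints are deleted
// sequentially with re-checking, which keeps every deletion homotopic.
// [[Rcpp::export]]
LogicalVector cpp_thin3d(LogicalVector vol, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long n = (long)nx * ny * nz;
  std::vector<uint8_t> v(n);
  std::vector<long> fg;
  for (long i = 0; i < n; ++i) {
    v[i] = vol[i] ? 1 : 0;
    if (v[i]) fg.push_back(i);
  }
  const int dir[6][3] = {{0,0,-1},{0,0,1},{0,-1,0},{0,1,0},{-1,0,0},{1,0,0}};
  int nb[27];
  std::vector<long> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (size_t t = 0; t < fg.size(); ++t) {
        long i = fg[t];
        if (!v[i]) continue;
        int x = (int)(i % nx), y = (int)((i / nx) % ny), z = (int)(i / ((long)nx * ny));
        int xx = x + dir[d][0], yy = y + dir[d][1], zz = z + dir[d][2];
        bool border = (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
                      ? true : !v[lidx(xx, yy, zz, nx, ny)];
        if (!border) continue;
        load_neighbourhood(v, x, y, z, nx, ny, nz, nb);
        int nn = count_fg_neighbours(nb);
        if (nn <= 1) continue; // endpoint or isolated point: keep
        if (simple_point(nb)) cand.push_back(i);
      }
      // sequential deletion with re-check
      for (size_t t = 0; t < cand.size(); ++t) {
        long i = cand[t];
        int x = (int)(i % nx), y = (int)((i / nx) % ny), z = (int)(i / ((long)nx * ny));
        load_neighbourhood(v, x, y, z, nx, ny, nz, nb);
        int nn = count_fg_neighbours(nb);
        if (nn <= 1) continue;
        if (!simple_point(nb)) continue;
        v[i] = 0;
        changed = true;
      }
    }
    // compact the foreground list between passes
    size_t w = 0;
    for (size_t t = 0; t < fg.size(); ++t)
      if (v[fg[t]]) fg[w++] = fg[t];
    fg.resize(w);
  }
  LogicalVector out(n);
  for (long i = 0; i < n; ++i) out[i] = v[i] != 0;
  out.attr("dim") = dims;
  return out;
}

// 26-connected component labelling; returns integer labels (0 = background),
// labelled in scan order so labelling is deterministic.
// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector vol, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long n = (long)nx * ny * nz;
  IntegerVector lab(n);
  std::vector<long> stack;
  int next = 0;
  for (long i = 0; i < n; ++i) {
    if (!vol[i] || lab[i]) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      long c = stack.back();
      stack.pop_back();
      int x = (int)(c % nx), y = (int)((c / nx) % ny), z = (int)(c / ((long)nx * ny));
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
            long j = lidx(xx, yy, zz, nx, ny);
            if (!vol[j] || lab[j]) continue;
            lab[j] = next;
            stack.push_back(j);
          }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Brute-force nearest neighbour from each query row to the reference set.
// Ties (equal distance within 1e-12) are broken by the lexicographically
// smallest reference coordinate. Returns 1-based indices and distances.
// [[Rcpp::export]]
List cpp_nearest_neighbour(NumericMatrix query, NumericMatrix ref) {
  int nq = query.nrow(), nr = ref.nrow();
  IntegerVector idx(nq);
  NumericVector dist(nq);
  for (int i = 0; i < nq; ++i) {
    double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    int best = -1;
    double bestd = R_PosInf;
    for (int j = 0; j < nr; ++j) {
      double dx = ref(j, 0) - qx, dy = ref(j, 1) - qy, dz = ref(j, 2) - qz;
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      bool take = false;
      if (d < bestd - 1e-12) take = true;
      else if (d < bestd + 1e-12 && best >= 0) {
        // lexicographic tie-break on reference coordinates
        for (int k = 0; k < 3; ++k) {
          if (ref(j, k) < ref(best, k) - 1e-12) { take = true; break; }
          if (ref(j, k) > ref(best, k) + 1e-12) break;
        }
      }
      if (take) { best = j; bestd = d; }
    }
    idx[i] = best + 1;
    dist[i] = bestd;
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

// Gap span along the digital line between paired points. Points are given in
// continuous voxel coordinates (voxel centre = index + 0.5, 0-based). For each
// pair, the segment is traversed voxel by voxel (Amanatides-Woo traversal,
// which visits every voxel the continuous segment passes through); voxels
// foreground in neither mask are "non-resin". The gap is the Euclidean
// distance between the first and last non-resin voxel centres (0 if fewer
// than two such voxels). Returned in voxel units.
// [[Rcpp::export]]
NumericVector cpp_line_gaps(NumericMatrix a_pts, NumericMatrix b_pts,
                            LogicalVector mask_a, LogicalVector mask_b,
                            IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = a_pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double p[3] = {a_pts(i,0), a_pts(i,1), a_pts(i,2)};
    double q[3] = {b_pts(i,0), b_pts(i,1), b_pts(i,2)};
    int c[3], e[3], step[3];
    double tmax[3], tdelta[3];
    double d[3];
    for (int k = 0; k < 3; ++k) {
      d[k] = q[k] - p[k];
      c[k] = (int)std::floor(p[k]);
      e[k] = (int)std::floor(q[k]);
      int lim = (k == 0 ? nx : (k == 1 ? ny : nz));
      if (c[k] < 0) c[k] = 0; if (c[k] >= lim) c[k] = lim - 1;
      if (e[k] < 0) e[k] = 0; if (e[k] >= lim) e[k] = lim - 1;
      if (d[k] > 1e-12) {
        step[k] = 1;
        tmax[k] = ((c[k] + 1) - p[k]) / d[k];
        tdelta[k] = 1.0 / d[k];
      } else if (d[k] < -1e-12) {
        step[k] = -1;
        tmax[k] = (c[k] - p[k]) / d[k];
        tdelta[k] = -1.0 / d[k];
      } else {
        step[k] = 0;
        tmax[k] = R_PosInf;
        tdelta[k] = R_PosInf;
      }
    }
    bool have_first = false;
    double first[3] = {0,0,0}, last[3] = {0,0,0};
    long maxit = (long)nx + ny + nz + 3;
    for (long it = 0; it < maxit; ++it) {
      long j = lidx(c[0], c[1], c[2], nx, ny);
      if (!mask_a[j] && !mask_b[j]) {
        if (!have_first) {
          have_first = true;
          for (int k = 0; k < 3; ++k) first[k] = c[k] + 0.5;
        }
        for (int k = 0; k < 3; ++k) last[k] = c[k] + 0.5;
      }
      if (c[0] == e[0] && c[1] == e[1] && c[2] == e[2]) break;
      int axis = 0;
      if (tmax[1] < tmax[axis]) axis = 1;
      if (tmax[2] < tmax[axis]) axis = 2;
      c[axis] += step[axis];
      tmax[axis] += tdelta[axis];
    }
    double g = 0.0;
    if (have_first) {
      double dx = last[0] - first[0], dy = last[1] - first[1], dz = last[2] - first[2];
      g = std::sqrt(dx * dx + dy * dy + dz * dz);
    }
    out[i] = g;
  }
  return out;
}

// Rasterize a set of capsules (cylinders with hemispherical caps) given by
// segment endpoints in continuous voxel coordinates and radii in voxel units.
// A voxel is foreground iff its centre lies within radius of a segment.
// [[Rcpp::export]]
LogicalVector cpp_rasterize_capsules(NumericMatrix p0, NumericMatrix p1,
                                     NumericVector radius, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long n = (long)nx * ny * nz;
  LogicalVector out(n);
  int nseg = p0.nrow();
  for (int s = 0; s < nseg; ++s) {
    double ax = p0(s,0), ay = p0(s,1), az = p0(s,2);
    double bx = p1(s,0), by = p1(s,1), bz = p1(s,2);
    double r = radius[s], r2 = r * r;
    int x0 = std::max(0, (int)std::floor(std::min(ax, bx) - r - 1));
    int x1 = std::min(nx - 1, (int)std::ceil(std::max(ax, bx) + r + 1));
    int y0 = std::max(0, (int)std::floor(std::min(ay, by) - r - 1));
    int y1 = std::min(ny - 1, (int)std::ceil(std::max(ay, by) + r + 1));
    int z0 = std::max(0, (int)std::floor(std::min(az, bz) - r - 1));
    int z1 = std::min(nz - 1, (int)std::ceil(std::max(az, bz) + r + 1));
    double ux = bx - ax, uy = by - ay, uz = bz - az;
    double L2 = ux * ux + uy * uy + uz * uz;
    for (int z = z0; z <= z1; ++z)
      for (int y = y0; y <= y1; ++y)
        for (int x = x0; x <= x1; ++x) {
          double cx = x + 0.5, cy = y + 0.5, cz = z + 0.5;
          double wx = cx - ax, wy = cy - ay, wz = cz - az;
          double t = 0.0;
          if (L2 > 0) {
            t = (wx * ux + wy * uy + wz * uz) / L2;
            if (t < 0) t = 0; else if (t > 1) t = 1;
          }
          double dx = wx - t * ux, dy = wy - t * uy, dz = wz - t * uz;
          if (dx * dx + dy * dy + dz * dz <= r2)
            out[lidx(x, y, z, nx, ny)] = true;
        }
  }
  out.attr("dim") = dims;
  return out;
}
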