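// Voxel-level primitives shared by the phantom, airway and sampling stages.
// Volumes are R arrays with dim = c(nz, ny, nx), column-major, so the linear
// 0-based index of voxel (z, y, x) is z + nz * (y + ny * x).

#include <Rcpp.h>
#include <queue>
#include <algorithm>
using namespace Rcpp;

static inline int lin(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

// 26-neighborhood offsets (dz, dy, dx)
static const int NB26[26][3] = {
  {-1,-1,-1},{-1,-1,0},{-1,-1,1},{-1,0,-1},{-1,0,0},{-1,0,1},{-1,1,-1},{-1,1,0},{-1,1,1},
  { 0,-1,-1},{ 0,-1,0},{ 0,-1,1},{ 0,0,-1},          { 0,0,1},{ 0,1,-1},{ 0,1,0},{ 0,1,1},
  { 1,-1,-1},{ 1,-1,0},{ 1,-1,1},{ 1,0,-1},{ 1,0,0},{ 1,0,1},{ 1,1,-1},{ 1,1,0},{ 1,1,1}
};
static const int NB6[6][3] = {
  {-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}
};

// [[Rcpp::export(name = ".cc_label26")]]
IntegerVector cc_label26(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int N = nz * ny * nx;
  IntegerVector lab(N, 0);
  int cur = 0;
  std::vector<int> stack;
  for (int i = 0; i < N; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++cur;
    stack.clear();
    stack.push_back(i);
    lab[i] = cur;
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      int z = p % nz, r = p / nz, y = r % ny, x = r / ny;
      for (int k = 0; k < 26; ++k) {
        int zz = z + NB26[k][0], yy = y + NB26[k][1], xx = x + NB26[k][2];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        int q = lin(zz, yy, xx, nz, ny);
        if (mask[q] && lab[q] == 0) { lab[q] = cur; stack.push_back(q); }
      }
    }
  }
  lab.attr("n_components") = cur;
  return lab;
}

// Adaptive region growing: BFS from the seed admitting voxels with value
// strictly below a threshold, relaxed upward in fixed steps.  A step that
// multiplies the mask volume by more than `explosion` is rolled back and
// growth stops (leak control).  status: 0 = stopped by explosion control,
// 1 = reached max_thr, 2 = leak onto the volume boundary, 3 = seed >= start_thr.
// [[Rcpp::export(name = ".region_grow")]]
List region_grow_cpp(NumericVector ct, IntegerVector dims, IntegerVector seed_zyx0,
                     double start_thr, double step, double max_thr,
                     double explosion, double boundary_frac) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const long N = (long)nz * ny * nx;
  LogicalVector mask(N, false);
  std::vector<unsigned char> in_frontier(N, 0);
  std::vector<int> frontier;            // rejected candidates adjacent to mask
  std::vector<int> queue_;
  const int seed = lin(seed_zyx0[0], seed_zyx0[1], seed_zyx0[2], nz, ny);
  double thr = start_thr;
  int status = 1;

  if (ct[seed] >= thr) {
    return List::create(_["mask"] = mask, _["final_thr"] = thr, _["status"] = 3,
                        _["volume"] = 0);
  }

  long inner = (long)std::max(nz - 2, 0) * std::max(ny - 2, 0) * std::max(nx - 2, 0);
  long n_boundary_vox = N - inner;
  long boundary_hits = 0;
  long vol = 0;

  std::vector<int> added;               // voxels admitted in the current step
  auto bfs = [&](double t) {
    while (!queue_.empty()) {
      int p = queue_.back(); queue_.pop_back();
      int z = p % nz, r = p / nz, y = r % ny, x = r / ny;
      for (int k = 0; k < 26; ++k) {
        int zz = z + NB26[k][0], yy = y + NB26[k][1], xx = x + NB26[k][2];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        int q = lin(zz, yy, xx, nz, ny);
        if (mask[q]) continue;
        if (ct[q] < t) {
          mask[q] = true; ++vol; added.push_back(q); queue_.push_back(q);
          if (in_frontier[q]) in_frontier[q] = 0;
          if (zz == 0 || zz == nz - 1 || yy == 0 || yy == ny - 1 || xx == 0 || xx == nx - 1)
            ++boundary_hits;
        } else if (!in_frontier[q]) {
          in_frontier[q] = 1; frontier.push_back(q);
        }
      }
    }
  };

  // initial growth at start threshold
  mask[seed] = true; vol = 1; added.clear(); added.push_back(seed);
  {
    int z = seed % nz, r = seed / nz, y = r % ny, x = r / ny;
    if (z == 0 || z == nz - 1 || y == 0 || y == ny - 1 || x == 0 || x == nx - 1)
      ++boundary_hits;
  }
  queue_.push_back(seed);
  bfs(thr);
  if ((double)boundary_hits / (double)n_boundary_vox > boundary_frac) {
    return List::create(_["mask"] = mask, _["final_thr"] = thr, _["status"] = 2,
                        _["volume"] = (double)vol);
  }

  while (thr + step <= max_thr + 1e-9) {
    double new_thr = thr + step;
    long prev_vol = vol;
    added.clear();
    // re-examine frontier under the relaxed threshold
    std::vector<int> keep;
    keep.reserve(frontier.size());
    for (int q : frontier) {
      if (!in_frontier[q]) continue;    // absorbed earlier
      if (mask[q]) { in_frontier[q] = 0; continue; }
      if (ct[q] < new_thr) {
        in_frontier[q] = 0;
        mask[q] = true; ++vol; added.push_back(q); queue_.push_back(q);
        int z = q % nz, r = q / nz, y = r % ny, x = r / ny;
        if (z == 0 || z == nz - 1 || y == 0 || y == ny - 1 || x == 0 || x == nx - 1)
          ++boundary_hits;
      } else keep.push_back(q);
    }
    frontier.swap(keep);
    bfs(new_thr);
    if (prev_vol > 0 && (double)vol > explosion * (double)prev_vol) {
      // roll back this step: the pre-explosion mask is the answer
      for (int q : added) {
        mask[q] = false;
        int z = q % nz, r = q / nz, y = r % ny, x = r / ny;
        if (z == 0 || z == nz - 1 || y == 0 || y == ny - 1 || x == 0 || x == nx - 1)
          --boundary_hits;
      }
      vol = prev_vol;
      status = 0;
      break;
    }
    thr = new_thr;
    if ((double)boundary_hits / (double)n_boundary_vox > boundary_frac) {
      status = 2;
      break;
    }
  }
  return List::create(_["mask"] = mask, _["final_thr"] = thr, _["status"] = status,
                      _["volume"] = (double)vol);
}

// ---- topology-preserving thinning -----------------------------------------

// Occupancy of the 3x3x3 neighborhood as a 27-cell cube, center index 13.
static inline int cube_idx(int dz, int dy, int dx) {
  return (dz + 1) * 9 + (dy + 1) * 3 + (dx + 1);
}

// Malandain-style simple-point test: exactly one 26-connected foreground
// component in N26, and exactly one 6-connected background component in N18
// that touches a face neighbor of the center.
static bool is_simple(const std::vector<unsigned char>& obj,
                      int z, int y, int x, int nz, int ny, int nx) {
  unsigned char cube[27];
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int zz = z + dz, yy = y + dy, xx = x + dx;
        unsigned char v = 0;
        if (zz >= 0 && zz < nz && yy >= 0 && yy < ny && xx >= 0 && xx < nx)
          v = obj[lin(zz, yy, xx, nz, ny)];
        cube[cube_idx(dz, dy, dx)] = v;
      }
  cube[13] = 0; // remove center

  // foreground 26-components among the 26 neighbors
  int compF = 0;
  int labF[27]; std::fill(labF, labF + 27, 0);
  for (int c = 0; c < 27; ++c) {
    if (c == 13 || !cube[c] || labF[c]) continue;
    ++compF;
    std::vector<int> st; st.push_back(c); labF[c] = compF;
    while (!st.empty()) {
      int p = st.back(); st.pop_back();
      int pz = p / 9 - 1, py = (p % 9) / 3 - 1, px = p % 3 - 1;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dz && !dy && !dx) continue;
            int qz = pz + dz, qy = py + dy, qx = px + dx;
            if (qz < -1 || qz > 1 || qy < -1 || qy > 1 || qx < -1 || qx > 1) continue;
            int q = cube_idx(qz, qy, qx);
            if (q == 13 || !cube[q] || labF[q]) continue;
            labF[q] = compF; st.push_back(q);
          }
    }
  }
  if (compF != 1) return false;

  // background 6-components within N18, touching a face neighbor
  int labB[27]; std::fill(labB, labB + 27, 0);
  int compB = 0;
  for (int c = 0; c < 27; ++c) {
    if (c == 13) continue;
    int cz = c / 9 - 1, cy = (c % 9) / 3 - 1, cx = c % 3 - 1;
    int man = std::abs(cz) + std::abs(cy) + std::abs(cx);
    if (man > 2) continue;               // N18 only
    if (cube[c] || labB[c]) continue;
    if (man != 1) continue;              // seed floods from face neighbors only
    ++compB;
    std::vector<int> st; st.push_back(c); labB[c] = compB;
    while (!st.empty()) {
      int p = st.back(); st.pop_back();
      int pz = p / 9 - 1, py = (p % 9) / 3 - 1, px = p % 3 - 1;
      static const int F6[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
      for (int k = 0; k < 6; ++k) {
        int qz = pz + F6[k][0], qy = py + F6[k][1], qx = px + F6[k][2];
        if (qz < -1 || qz > 1 || qy < -1 || qy > 1 || qx < -1 || qx > 1) continue;
        if (std::abs(qz) + std::abs(qy) + std::abs(qx) > 2) continue;
        int q = cube_idx(qz, qy, qx);
        if (q == 13 || cube[q] || labB[q]) continue;
        labB[q] = compB; st.push_back(q);
      }
    }
  }
  return compB == 1;
}

static inline int count_nb26(const std::vector<unsigned char>& obj,
                             int z, int y, int x, int nz, int ny, int nx) {
  int n = 0;
  for (int k = 0; k < 26; ++k) {
    int zz = z + NB26[k][0], yy = y + NB26[k][1], xx = x + NB26[k][2];
    if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
    if (obj[lin(zz, yy, xx, nz, ny)]) ++n;
  }
  return n;
}

// Distance-ordered homotopic thinning: peel simple, non-endpoint border
// voxels in increasing chamfer-distance order until stable.  Produces a
// unit-wide, connected, well-centered skeleton.
// [[Rcpp::export(name = ".skeletonize3d")]]
LogicalVector skeletonize_cpp(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const long N = (long)nz * ny * nx;
  std::vector<unsigned char> obj(N, 0);
  for (long i = 0; i < N; ++i) obj[i] = mask[i] ? 1 : 0;

  // chamfer 3-4-5 distance to background
  std::vector<int> dt(N, 0);
  const int INF = 1 << 28;
  for (long i = 0; i < N; ++i) dt[i] = obj[i] ? INF : 0;
  // forward pass
  for (int x = 0; x < nx; ++x) for (int y = 0; y < ny; ++y) for (int z = 0; z < nz; ++z) {
    long i = lin(z, y, x, nz, ny);
    if (dt[i] == 0) continue;
    int best = dt[i];
    for (int k = 0; k < 26; ++k) {
      int dz = NB26[k][0], dy = NB26[k][1], dx = NB26[k][2];
      // predecessors in scan order (x, then y, then z)
      if (dx > 0 || (dx == 0 && (dy > 0 || (dy == 0 && dz >= 0)))) continue;
      int zz = z + dz, yy = y + dy, xx = x + dx;
      int w = 3 + std::abs(dz) + std::abs(dy) + std::abs(dx) - 1; // 3,4,5
      int d;
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        d = w;                            // outside the volume is background
      else
        d = dt[lin(zz, yy, xx, nz, ny)] + w;
      if (d < best) best = d;
    }
    dt[i] = best;
  }
  // backward pass
  for (int x = nx - 1; x >= 0; --x) for (int y = ny - 1; y >= 0; --y) for (int z = nz - 1; z >= 0; --z) {
    long i = lin(z, y, x, nz, ny);
    if (dt[i] == 0) continue;
    int best = dt[i];
    for (int k = 0; k < 26; ++k) {
      int dz = NB26[k][0], dy = NB26[k][1], dx = NB26[k][2];
      if (dx < 0 || (dx == 0 && (dy < 0 || (dy == 0 && dz <= 0)))) continue;
      int zz = z + dz, yy = y + dy, xx = x + dx;
      int w = 3 + std::abs(dz) + std::abs(dy) + std::abs(dx) - 1;
      int d;
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        d = w;
      else
        d = dt[lin(zz, yy, xx, nz, ny)] + w;
      if (d < best) best = d;
    }
    dt[i] = best;
  }

  bool changed = true;
  std::vector<std::pair<int, long> > cand;
  while (changed) {
    changed = false;
    cand.clear();
    for (int x = 0; x < nx; ++x) for (int y = 0; y < ny; ++y) for (int z = 0; z < nz; ++z) {
      long i = lin(z, y, x, nz, ny);
      if (!obj[i]) continue;
      // border voxel: has a 6-neighbor background (or volume edge)
      bool border = false;
      for (int k = 0; k < 6; ++k) {
        int zz = z + NB6[k][0], yy = y + NB6[k][1], xx = x + NB6[k][2];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) { border = true; break; }
        if (!obj[lin(zz, yy, xx, nz, ny)]) { border = true; break; }
      }
      if (border) cand.push_back(std::make_pair(dt[i], i));
    }
    std::sort(cand.begin(), cand.end());
    for (size_t c = 0; c < cand.size(); ++c) {
      long i = cand[c].second;
      if (!obj[i]) continue;
      int z = i % nz; long r = i / nz; int y = r % ny, x = r / ny;
      int nb = count_nb26(obj, z, y, x, nz, ny, nx);
      if (nb < 2) continue;               // endpoint or isolated: keep
      if (is_simple(obj, z, y, x, nz, ny, nx)) {
        obj[i] = 0;
        changed = true;
      }
    }
  }

  LogicalVector out(N, false);
  for (long i = 0; i < N; ++i) out[i] = obj[i] != 0;
  return out;
}

// Trilinear resampling of a (z, y, x) array to a new shape, cell-centered
// coordinate mapping, clamped at the edges.
// [[Rcpp::export(name = ".resample_trilinear")]]
NumericVector trilinear_resample_cpp(NumericVector input, IntegerVector in_dims,
                                     IntegerVector out_dims) {
  const int nz = in_dims[0], ny = in_dims[1], nx = in_dims[2];
  const int oz = out_dims[0], oy = out_dims[1], ox = out_dims[2];
  NumericVector out((long)oz * oy * ox);
  std::vector<double> zc(oz), yc(oy), xc(ox);
  for (int i = 0; i < oz; ++i) zc[i] = std::min(std::max(((i + 0.5) * nz) / oz - 0.5, 0.0), (double)(nz - 1));
  for (int i = 0; i < oy; ++i) yc[i] = std::min(std::max(((i + 0.5) * ny) / oy - 0.5, 0.0), (double)(ny - 1));
  for (int i = 0; i < ox; ++i) xc[i] = std::min(std::max(((i + 0.5) * nx) / ox - 0.5, 0.0), (double)(nx - 1));
  for (int x = 0; x < ox; ++x) {
    int x0 = (int)std::floor(xc[x]); int x1 = std::min(x0 + 1, nx - 1); double fx = xc[x] - x0;
    for (int y = 0; y < oy; ++y) {
      int y0 = (int)std::floor(yc[y]); int y1 = std::min(y0 + 1, ny - 1); double fy = yc[y] - y0;
      for (int z = 0; z < oz; ++z) {
        int z0 = (int)std::floor(zc[z]); int z1 = std::min(z0 + 1, nz - 1); double fz = zc[z] - z0;
        double c00 = input[lin(z0, y0, x0, nz, ny)] * (1 - fz) + input[lin(z1, y0, x0, nz, ny)] * fz;
        double c10 = input[lin(z0, y1, x0, nz, ny)] * (1 - fz) + input[lin(z1, y1, x0, nz, ny)] * fz;
        double c01 = input[lin(z0, y0, x1, nz, ny)] * (1 - fz) + input[lin(z1, y0, x1, nz, ny)] * fz;
        double c11 = input[lin(z0, y1, x1, nz, ny)] * (1 - fz) + input[lin(z1, y1, x1, nz, ny)] * fz;
        double c0 = c00 * (1 - fy) + c10 * fy;
        double c1 = c01 * (1 - fy) + c11 * fy;
        out[lin(z, y, x, oz, oy)] = c0 * (1 - fx) + c1 * fx;
      }
    }
  }
  return out;
}
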