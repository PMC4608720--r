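#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Grid-based cavity machinery. Voxels are cubic with edge `spacing`;
// a voxel is "protein" when its centre lies within (vdw + probe) of any
// atom centre. Empty voxels qualify as cavity candidates when a ray along
// at least `min_blocked` of the 6 axis directions hits a protein voxel
// inside the grid (buriedness test); candidates are grouped by
// 26-connectivity flood fill.

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// [[Rcpp::export]]
List cpp_voxelize(NumericMatrix coords, NumericVector radii,
                  double spacing, double probe) {
  const int n = coords.nrow();
  if (n == 0) stop("cannot voxelize an empty frame");
  double rmax = 0.0;
  for (int a = 0; a < n; ++a) rmax = std::max(rmax, radii[a]);
  const double margin = rmax + probe + 2.0 * spacing;
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) {
    lo[d] = R_PosInf; hi[d] = R_NegInf;
    for (int a = 0; a < n; ++a) {
      lo[d] = std::min(lo[d], coords(a, d));
      hi[d] = std::max(hi[d], coords(a, d));
    }
    lo[d] -= margin; hi[d] += margin;
  }
  int dims[3];
  for (int d = 0; d < 3; ++d)
    dims[d] = (int)std::ceil((hi[d] - lo[d]) / spacing) + 1;
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector occ((R_xlen_t)nx * ny * nz, false);
  for (int a = 0; a < n; ++a) {
    const double reach = radii[a] + probe;
    const double r2 = reach * reach;
    int ilo[3], ihi[3];
    for (int d = 0; d < 3; ++d) {
      ilo[d] = std::max(0, (int)std::floor((coords(a, d) - reach - lo[d]) / spacing - 0.5));
      ihi[d] = std::min(dims[d] - 1, (int)std::ceil((coords(a, d) + reach - lo[d]) / spacing - 0.5) + 1);
    }
    for (int k = ilo[2]; k <= ihi[2]; ++k) {
      const double dz = lo[2] + (k + 0.5) * spacing - coords(a, 2);
      for (int j = ilo[1]; j <= ihi[1]; ++j) {
        const double dy = lo[1] + (j + 0.5) * spacing - coords(a, 1);
        const double dyz = dy * dy + dz * dz;
        if (dyz > r2) continue;
        for (int i = ilo[0]; i <= ihi[0]; ++i) {
          const double dx = lo[0] + (i + 0.5) * spacing - coords(a, 0);
          if (dx * dx + dyz < r2) occ[idx3(i, j, k, nx, ny)] = true;
        }
      }
    }
  }
  return List::create(_["origin"] = NumericVector::create(lo[0], lo[1], lo[2]),
                      _["dims"] = IntegerVector::create(nx, ny, nz),
                      _["occupancy"] = occ);
}

// [[Rcpp::export]]
List cpp_detect_cavities(LogicalVector occ, IntegerVector dims,
                         double spacing, int min_blocked, double min_volume) {
  if (min_blocked < 4 || min_blocked > 6)
    stop("min_blocked must be 4, 5 or 6");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  std::vector<unsigned char> blocked(nvox, 0);
  // sweep each axis in both directions, accumulating "protein seen so far"
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      bool seen = false;
      for (int i = 0; i < nx; ++i) {          // -x direction
        if (seen) blocked[idx3(i, j, k, nx, ny)]++;
        if (occ[idx3(i, j, k, nx, ny)]) seen = true;
      }
      seen = false;
      for (int i = nx - 1; i >= 0; --i) {     // +x direction
        if (seen) blocked[idx3(i, j, k, nx, ny)]++;
        if (occ[idx3(i, j, k, nx, ny)]) seen = true;
      }
    }
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      bool seen = false;
      for (int j = 0; j < ny; ++j) {
        if (seen) blocked[idx3(i, j, k, nx, ny)]++;
        if (occ[idx3(i, j, k, nx, ny)]) seen = true;
      }
      seen = false;
      for (int j = ny - 1; j >= 0; --j) {
        if (seen) blocked[idx3(i, j, k, nx, ny)]++;
        if (occ[idx3(i, j, k, nx, ny)]) seen = true;
      }
    }
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      bool seen = false;
      for (int k = 0; k < nz; ++k) {
        if (seen) blocked[idx3(i, j, k, nx, ny)]++;
        if (occ[idx3(i, j, k, nx, ny)]) seen = true;
      }
      seen = false;
      for (int k = nz - 1; k >= 0; --k) {
        if (seen) blocked[idx3(i, j, k, nx, ny)]++;
        if (occ[idx3(i, j, k, nx, ny)]) seen = true;
      }
    }
  // candidate voxels: empty and buried in >= min_blocked directions
  std::vector<char> cand(nvox, 0);
  for (R_xlen_t v = 0; v < nvox; ++v)
    if (!occ[v] && blocked[v] >= min_blocked) cand[v] = 1;
  // 26-connectivity flood fill over candidates
  std::vector<int> comp(nvox, -1);
  std::vector<std::vector<int>> members;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int v0 = idx3(i, j, k, nx, ny);
        if (!cand[v0] || comp[v0] >= 0) continue;
        const int cid = (int)members.size();
        members.push_back(std::vector<int>());
        std::queue<std::array<int, 3>> q;
        q.push({i, j, k});
        comp[v0] = cid;
        while (!q.empty()) {
          auto c = q.front(); q.pop();
          members[cid].push_back(idx3(c[0], c[1], c[2], nx, ny));
          for (int dk = -1; dk <= 1; ++dk)
            for (int dj = -1; dj <= 1; ++dj)
              for (int di = -1; di <= 1; ++di) {
                if (!di && !dj && !dk) continue;
                const int ni = c[0] + di, nj = c[1] + dj, nk = c[2] + dk;
                if (ni < 0 || nj < 0 || nk < 0 || ni >= nx || nj >= ny || nk >= nz)
                  continue;
                const int nv = idx3(ni, nj, nk, nx, ny);
                if (cand[nv] && comp[nv] < 0) {
                  comp[nv] = cid;
                  q.push({ni, nj, nk});
                }
              }
        }
      }
  const double vvox = spacing * spacing * spacing;
  List out_members;
  NumericVector out_vol;
  NumericMatrix out_centroid(0, 3);
  std::vector<int> keep;
  for (size_t c = 0; c < members.size(); ++c) {
    const double vol = members[c].size() * vvox;
    if (vol >= min_volume) keep.push_back((int)c);
  }
  NumericMatrix centroids((int)keep.size(), 3);
  NumericVector vols((int)keep.size());
  List comps((int)keep.size());
  for (size_t c = 0; c < keep.size(); ++c) {
    const std::vector<int>& m = members[keep[c]];
    IntegerVector mv(m.size());
    double cx = 0, cy = 0, cz = 0;
    for (size_t t = 0; t < m.size(); ++t) {
      mv[t] = m[t];
      const int v = m[t];
      const int i = v % nx, j = (v / nx) % ny, k = v / (nx * ny);
      cx += i; cy += j; cz += k;
    }
    comps[c] = mv;
    vols[c] = m.size() * vvox;
    centroids(c, 0) = cx / m.size();
    centroids(c, 1) = cy / m.size();
    centroids(c, 2) = cz / m.size();
  }
  return List::create(_["members"] = comps, _["volumes"] = vols,
                      _["centroids_vox"] = centroids);
}

// minimum squared distance from each listed voxel centre to any seed atom;
// returns true when any voxel of the component is within `radius`
// [[Rcpp::export]]
LogicalVector cpp_components_near(List members, NumericVector origin,
                                  IntegerVector dims, double spacing,
                                  NumericMatrix seeds, double radius) {
  const int nx = dims[0], ny = dims[1];
  const double r2 = radius * radius;
  LogicalVector out(members.size());
  for (int c = 0; c < members.size(); ++c) {
    IntegerVector m = members[c];
    bool near = false;
    for (int t = 0; t < m.size() && !near; ++t) {
      const int v = m[t];
      const int i = v % nx, j = (v / nx) % ny, k = v / (nx * ny);
      const double x = origin[0] + (i + 0.5) * spacing;
      const double y = origin[1] + (j + 0.5) * spacing;
      const double z = origin[2] + (k + 0.5) * spacing;
      for (int s = 0; s < seeds.nrow(); ++s) {
        const double dx = x - seeds(s, 0), dy = y - seeds(s, 1),
                     dz = z - seeds(s, 2);
        if (dx * dx + dy * dy + dz * dz <= r2) { near = true; break; }
      }
    }
    out[c] = near;
  }
  return out;
}
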