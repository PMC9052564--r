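#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Grey-level texture matrix kernels. All functions take a 3-D integer level
// array (column-major, x fastest) with 0 marking voxels outside the ROI and
// levels 1..ng inside. Directions follow the IBSI 3-D convention: the 13
// unique offsets (one per axial pair), neighbourhoods are 26-connected,
// distances are Chebyshev.

static const int DIR13[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0},
  {1, 0, 1}, {1, 0, -1},
  {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Symmetric co-occurrence counts at Chebyshev distance 1, merged over the
// requested directions (rows of `dirs`, each an (dx,dy,dz) offset).
// [[Rcpp::export]]
NumericMatrix cpp_glcm(IntegerVector levels, IntegerVector dim, int ng,
                       IntegerMatrix dirs) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix counts(ng, ng);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int li = levels[idx3(x, y, z, nx, ny)];
        if (li == 0) continue;
        for (int d = 0; d < dirs.nrow(); ++d) {
          int xx = x + dirs(d, 0), yy = y + dirs(d, 1), zz = z + dirs(d, 2);
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          int lj = levels[idx3(xx, yy, zz, nx, ny)];
          if (lj == 0) continue;
          counts(li - 1, lj - 1) += 1.0;
          counts(lj - 1, li - 1) += 1.0;
        }
      }
  return counts;
}

// Run-length counts merged over the requested directions. A run is a maximal
// segment of consecutive in-ROI voxels with equal level along one direction.
// Returns an ng x max_run_length count matrix.
// [[Rcpp::export]]
NumericMatrix cpp_glrlm(IntegerVector levels, IntegerVector dim, int ng,
                        IntegerMatrix dirs) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  int maxdim = std::max(nx, std::max(ny, nz));
  NumericMatrix counts(ng, maxdim);
  int maxlen = 1;
  for (int d = 0; d < dirs.nrow(); ++d) {
    const int dx = dirs(d, 0), dy = dirs(d, 1), dz = dirs(d, 2);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int li = levels[idx3(x, y, z, nx, ny)];
          if (li == 0) continue;
          // run starts where the previous voxel along d is absent or differs
          int px = x - dx, py = y - dy, pz = z - dz;
          if (px >= 0 && px < nx && py >= 0 && py < ny && pz >= 0 && pz < nz &&
              levels[idx3(px, py, pz, nx, ny)] == li)
            continue;
          int len = 1;
          int cx = x + dx, cy = y + dy, cz = z + dz;
          while (cx >= 0 && cx < nx && cy >= 0 && cy < ny && cz >= 0 &&
                 cz < nz && levels[idx3(cx, cy, cz, nx, ny)] == li) {
            ++len;
            cx += dx; cy += dy; cz += dz;
          }
          counts(li - 1, len - 1) += 1.0;
          if (len > maxlen) maxlen = len;
        }
  }
  return counts(Range(0, ng - 1), Range(0, maxlen - 1));
}

// Chebyshev distance of every in-ROI voxel to the nearest voxel outside the
// ROI (out-of-grid counts as outside), border convention: border voxels get 1.
// Two-pass chamfer over the 26-neighbourhood is exact for this metric.
// [[Rcpp::export]]
IntegerVector cpp_roi_distance_map(IntegerVector levels, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  const int INF = 1 << 29;
  std::vector<int> dist(n);
  for (int i = 0; i < n; ++i) dist[i] = levels[i] == 0 ? 0 : INF;
  // forward pass
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = idx3(x, y, z, nx, ny);
        if (levels[i] == 0) continue;
        int best = dist[i];
        for (int dz = -1; dz <= 0; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dz == 0 && (dy > 0 || (dy == 0 && dx >= 0))) continue;
              int xx = x + dx, yy = y + dy, zz = z + dz;
              int nb = (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0)
                           ? 0
                           : dist[idx3(xx, yy, zz, nx, ny)];
              if (nb + 1 < best) best = nb + 1;
            }
        // out-of-grid on the +x/+y/+z faces handled in the backward pass
        dist[i] = best;
      }
  // backward pass
  for (int z = nz - 1; z >= 0; --z)
    for (int y = ny - 1; y >= 0; --y)
      for (int x = nx - 1; x >= 0; --x) {
        int i = idx3(x, y, z, nx, ny);
        if (levels[i] == 0) continue;
        int best = dist[i];
        for (int dz = 0; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dz == 0 && (dy < 0 || (dy == 0 && dx <= 0))) continue;
              int xx = x + dx, yy = y + dy, zz = z + dz;
              int nb = (xx >= nx || xx < 0 || yy >= ny || yy < 0 || zz >= nz)
                           ? 0
                           : dist[idx3(xx, yy, zz, nx, ny)];
              if (nb + 1 < best) best = nb + 1;
            }
        dist[i] = best;
      }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = dist[i];
  out.attr("dim") = dim;
  return out;
}

// 26-connected zones of equal level. Returns one row per zone:
// (level, size, min Chebyshev border distance over the zone's voxels).
// `dist` must come from cpp_roi_distance_map on the same array.
// [[Rcpp::export]]
IntegerMatrix cpp_zones(IntegerVector levels, IntegerVector dim,
                        IntegerVector dist) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> zl, zs, zd;
  std::vector<int> stack;
  for (int i0 = 0; i0 < n; ++i0) {
    if (seen[i0] || levels[i0] == 0) continue;
    const int lv = levels[i0];
    int size = 0, dmin = 1 << 29;
    stack.clear();
    stack.push_back(i0);
    seen[i0] = 1;
    while (!stack.empty()) {
      int i = stack.back();
      stack.pop_back();
      ++size;
      if (dist[i] < dmin) dmin = dist[i];
      int x = i % nx, y = (i / nx) % ny, z = i / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
              continue;
            int j = idx3(xx, yy, zz, nx, ny);
            if (!seen[j] && levels[j] == lv) {
              seen[j] = 1;
              stack.push_back(j);
            }
          }
    }
    zl.push_back(lv);
    zs.push_back(size);
    zd.push_back(dmin);
  }
  IntegerMatrix out(zl.size(), 3);
  for (size_t k = 0; k < zl.size(); ++k) {
    out(k, 0) = zl[k];
    out(k, 1) = zs[k];
    out(k, 2) = zd[k];
  }
  colnames(out) = CharacterVector::create("level", "size", "distance");
  return out;
}

// NGTDM per-level absolute differences to the mean of the valid 26-
// neighbourhood. Returns ng x 2: column 1 the difference sums s_i, column 2
// the voxel counts n_i.
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector levels, IntegerVector dim, int ng) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(ng, 2);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int li = levels[idx3(x, y, z, nx, ny)];
        if (li == 0) continue;
        double sum = 0.0;
        int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 ||
                  zz >= nz)
                continue;
              int lj = levels[idx3(xx, yy, zz, nx, ny)];
              if (lj == 0) continue;
              sum += lj;
              ++cnt;
            }
        if (cnt > 0) {
          out(li - 1, 0) += std::fabs(li - sum / cnt);
          out(li - 1, 1) += 1.0;
        }
      }
  return out;
}

// Cross-validated k-NN positive-class scores for several k at once.
// X is n x d (column-major), fold holds 1-based fold ids; for each case the
// scores use only training rows outside its fold. Distance ties break by
// training-row order (stable sort), matching the R scorer's contract.
// Returns an n x length(ks) score matrix.
// [[Rcpp::export]]
NumericMatrix cpp_knn_cv_scores(NumericMatrix X, IntegerVector y,
                                IntegerVector fold, IntegerVector ks) {
  const int n = X.nrow(), d = X.ncol(), nk = ks.size();
  const int kmax = *std::max_element(ks.begin(), ks.end());
  NumericMatrix out(n, nk);
  std::vector<int> idx;
  idx.reserve(n);
  std::vector<double> dist(n);
  for (int q = 0; q < n; ++q) {
    idx.clear();
    for (int t = 0; t < n; ++t) {
      if (fold[t] == fold[q]) continue;
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double diff = X(t, c) - X(q, c);
        s += diff * diff;
      }
      dist[t] = s;
      idx.push_back(t);
    }
    const int m = (int)idx.size();
    const int kk = std::min(kmax, m);
    std::partial_sort(idx.begin(), idx.begin() + kk, idx.end(),
                      [&](int a, int b) {
                        if (dist[a] != dist[b]) return dist[a] < dist[b];
                        return a < b;
                      });
    int pos = 0;
    std::vector<double> cum(kk);
    for (int r = 0; r < kk; ++r) {
      pos += y[idx[r]];
      cum[r] = (double)pos / (r + 1);
    }
    for (int c = 0; c < nk; ++c)
      out(q, c) = cum[std::min(ks[c], kk) - 1];
  }
  return out;
}
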