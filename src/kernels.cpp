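#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Voxel kernels shared by the scanner, tree-extraction and measurement code.
// Volumes are passed as flat vectors in R's column-major order with dims
// (nx, ny, nz); voxel (i, j, k) (0-based) lives at i + nx*(j + ny*k).

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + (long long)ny * k);
}

// 26-connected (or 6-connected) component labelling of a binary volume.
// Labels are 1..n in order of the smallest linear index they contain, so the
// tie rule "component containing the lexicographically smallest voxel" is
// label 1 after sorting by size then label.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dims,
                                   int connectivity = 26) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh > 1) continue;
        offs.push_back(dx); offs.push_back(dy); offs.push_back(dz);
      }
  int nextLab = 0;
  std::vector<long long> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++nextLab;
    lab[s] = nextLab;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      long long cur = stack.back(); stack.pop_back();
      int k = cur / ((long long)nx * ny);
      int r = cur % ((long long)nx * ny);
      int j = r / nx, i = r % nx;
      for (size_t o = 0; o < offs.size(); o += 3) {
        int ii = i + offs[o], jj = j + offs[o + 1], kk = k + offs[o + 2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        long long t = idx3(ii, jj, kk, nx, ny);
        if (mask[t] != 0 && lab[t] == 0) { lab[t] = nextLab; stack.push_back(t); }
      }
    }
  }
  lab.attr("n") = nextLab;
  return lab;
}

// Geodesic (within-mask) distance in mm from a seed voxel, Dijkstra over the
// 26-neighbourhood with physical edge lengths from `spacing`.  Background and
// unreachable voxels get -1.
// [[Rcpp::export]]
NumericVector cpp_geodesic_dist(IntegerVector mask, IntegerVector dims,
                                NumericVector spacing, int seed) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector dist(n, -1.0);
  if (seed < 0 || seed >= n || mask[seed] == 0)
    stop("seed voxel outside the mask");
  struct Nb { int dx, dy, dz; double w; };
  std::vector<Nb> nbs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        double w = std::sqrt(dx * dx * spacing[0] * spacing[0] +
                             dy * dy * spacing[1] * spacing[1] +
                             dz * dz * spacing[2] * spacing[2]);
        nbs.push_back({dx, dy, dz, w});
      }
  typedef std::pair<double, long long> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  dist[seed] = 0.0;
  pq.push({0.0, (long long)seed});
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    double d = top.first; long long cur = top.second;
    if (d > dist[cur] + 1e-12) continue;
    int k = cur / ((long long)nx * ny);
    int r = cur % ((long long)nx * ny);
    int j = r / nx, i = r % nx;
    for (size_t o = 0; o < nbs.size(); ++o) {
      int ii = i + nbs[o].dx, jj = j + nbs[o].dy, kk = k + nbs[o].dz;
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
        continue;
      long long t = idx3(ii, jj, kk, nx, ny);
      if (mask[t] == 0) continue;
      double nd = d + nbs[o].w;
      if (dist[t] < 0 || nd < dist[t] - 1e-12) {
        dist[t] = nd;
        pq.push({nd, t});
      }
    }
  }
  return dist;
}

// Trilinear interpolation at continuous 0-based voxel coordinates.
// Points outside [0, dim-1] in any axis return NA.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dims,
                            NumericMatrix pts) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int np = pts.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (!(x >= 0 && y >= 0 && z >= 0 &&
          x <= nx - 1 && y <= ny - 1 && z <= nz - 1)) {
      out[p] = NA_REAL;
      continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 == nx - 1) --i0;
    if (j0 == ny - 1) --j0;
    if (k0 == nz - 1) --k0;
    if (nx == 1) i0 = 0;
    if (ny == 1) j0 = 0;
    if (nz == 1) k0 = 0;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
        k1 = std::min(k0 + 1, nz - 1);
    double c000 = vol[idx3(i0, j0, k0, nx, ny)], c100 = vol[idx3(i1, j0, k0, nx, ny)];
    double c010 = vol[idx3(i0, j1, k0, nx, ny)], c110 = vol[idx3(i1, j1, k0, nx, ny)];
    double c001 = vol[idx3(i0, j0, k1, nx, ny)], c101 = vol[idx3(i1, j0, k1, nx, ny)];
    double c011 = vol[idx3(i0, j1, k1, nx, ny)], c111 = vol[idx3(i1, j1, k1, nx, ny)];
    double c00 = c000 * (1 - fx) + c100 * fx;
    double c10 = c010 * (1 - fx) + c110 * fx;
    double c01 = c001 * (1 - fx) + c101 * fx;
    double c11 = c011 * (1 - fx) + c111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[p] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// 1-D convolution along one axis (0=x, 1=y, 2=z) with reflecting boundary.
// Kernel length must be odd.
// [[Rcpp::export]]
NumericVector cpp_convolve_axis(NumericVector vol, IntegerVector dims,
                                NumericVector kernel, int axis) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int kl = kernel.size();
  const int hr = kl / 2;
  NumericVector out(n);
  int len = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double acc = 0.0;
        int pos = (axis == 0) ? i : (axis == 1) ? j : k;
        for (int t = -hr; t <= hr; ++t) {
          int q = pos + t;
          if (q < 0) q = -q - 1;            // reflect
          if (q >= len) q = 2 * len - q - 1;
          int ii = i, jj = j, kk = k;
          if (axis == 0) ii = q; else if (axis == 1) jj = q; else kk = q;
          acc += kernel[t + hr] * vol[idx3(ii, jj, kk, nx, ny)];
        }
        out[idx3(i, j, k, nx, ny)] = acc;
      }
  return out;
}

// Flood fill of non-blocked voxels 6-connected to the volume border;
// returns 1 where reachable ("exterior"), 0 elsewhere.
// [[Rcpp::export]]
IntegerVector cpp_fill_from_border(IntegerVector blocked, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector ext(n, 0);
  std::vector<long long> stack;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (i != 0 && j != 0 && k != 0 && i != nx - 1 && j != ny - 1 && k != nz - 1)
          continue;
        long long s = idx3(i, j, k, nx, ny);
        if (blocked[s] == 0 && ext[s] == 0) { ext[s] = 1; stack.push_back(s); }
      }
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  while (!stack.empty()) {
    long long cur = stack.back(); stack.pop_back();
    int k = cur / ((long long)nx * ny);
    int r = cur % ((long long)nx * ny);
    int j = r / nx, i = r % nx;
    for (int o = 0; o < 6; ++o) {
      int ii = i + dx[o], jj = j + dy[o], kk = k + dz[o];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
        continue;
      long long t = idx3(ii, jj, kk, nx, ny);
      if (blocked[t] == 0 && ext[t] == 0) { ext[t] = 1; stack.push_back(t); }
    }
  }
  return ext;
}
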