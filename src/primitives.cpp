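// Low-level 3D image primitives backing the segmentation pipeline.
// All arrays are R arrays in (z, y, x) order: index = z + nz*(y + ny*x),
// i.e. z is the fastest-varying (first) dimension, matching the R side.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static inline R_xlen_t idx3(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)x);
}

// 26-neighbourhood offsets (foreground); 6-neighbourhood for background fills.
struct Neigh { int dz, dy, dx; };

static std::vector<Neigh> neighbours(int conn) {
  std::vector<Neigh> out;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int manh = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (conn == 6 && manh != 1) continue;
        out.push_back({dz, dy, dx});
      }
  return out;
}

// Connected-component labelling of a logical 3D mask.
// Labels are assigned in order of first (lexicographic z,y,x-major) encounter,
// so the result is deterministic.
// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector mask, int connectivity = 26) {
  IntegerVector dim = mask.attr("dim");
  if (dim.size() != 3) stop("mask must be a 3D array");
  int nz = dim[0], ny = dim[1], nx = dim[2];
  IntegerVector lab(mask.size(), 0);
  lab.attr("dim") = dim;
  std::vector<Neigh> nb = neighbours(connectivity);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = idx3(z, y, x, nz, ny);
        if (!mask[i] || lab[i]) continue;
        ++next;
        lab[i] = next;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          R_xlen_t cur = stack.back(); stack.pop_back();
          int cz = (int)(cur % nz);
          int rem = (int)(cur / nz);
          int cy = rem % ny;
          int cx = rem / ny;
          for (const Neigh &d : nb) {
            int zz = cz + d.dz, yy = cy + d.dy, xx = cx + d.dx;
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
              continue;
            R_xlen_t j = idx3(zz, yy, xx, nz, ny);
            if (mask[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
          }
        }
      }
  lab.attr("n_components") = next;
  return lab;
}

// Fill enclosed background cavities: background is flood-filled (6-conn) from
// every border voxel; anything not reached becomes foreground.
// [[Rcpp::export(name = ".fill_holes_3d")]]
LogicalVector fill_holes_3d(LogicalVector mask) {
  IntegerVector dim = mask.attr("dim");
  if (dim.size() != 3) stop("mask must be a 3D array");
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<uint8_t> outside(mask.size(), 0);
  std::vector<Neigh> nb = neighbours(6);
  std::vector<R_xlen_t> stack;
  auto push_if_bg = [&](int z, int y, int x) {
    R_xlen_t i = idx3(z, y, x, nz, ny);
    if (!mask[i] && !outside[i]) { outside[i] = 1; stack.push_back(i); }
  };
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z)
        if (z == 0 || z == nz - 1 || y == 0 || y == ny - 1 || x == 0 || x == nx - 1)
          push_if_bg(z, y, x);
  while (!stack.empty()) {
    R_xlen_t cur = stack.back(); stack.pop_back();
    int cz = (int)(cur % nz);
    int rem = (int)(cur / nz);
    int cy = rem % ny;
    int cx = rem / ny;
    for (const Neigh &d : nb) {
      int zz = cz + d.dz, yy = cy + d.dy, xx = cx + d.dx;
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      push_if_bg(zz, yy, xx);
    }
  }
  LogicalVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) out[i] = mask[i] || !outside[i];
  out.attr("dim") = dim;
  return out;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher) with grid
// spacing `w` in physical units. f is the input squared-distance row.
static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 double w, std::vector<int> &v, std::vector<double> &zb) {
  int n = (int)f.size();
  double w2 = w * w;
  int k = 0;
  v[0] = 0;
  zb[0] = -INFINITY;
  zb[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s > zb[k]) break;
      --k;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    int p = v[k];
    d[q] = w2 * (q - p) * (q - p) + f[p];
  }
}

// Anisotropic Euclidean distance transform: for each foreground voxel the
// physical distance to the nearest background voxel. spacing = (z,y,x) in um.
// [[Rcpp::export(name = ".edt_3d")]]
NumericVector edt_3d(LogicalVector mask, NumericVector spacing) {
  IntegerVector dim = mask.attr("dim");
  if (dim.size() != 3) stop("mask must be a 3D array");
  if (spacing.size() != 3) stop("spacing must have length 3");
  int nz = dim[0], ny = dim[1], nx = dim[2];
  // large finite sentinel, not Inf: the parabola intersection in dt1d would
  // produce NaN from Inf - Inf on lines that are entirely foreground
  const double BIG = 1e20;
  NumericVector d2(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i)
    d2[i] = mask[i] ? BIG : 0.0;
  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), dd(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);
  // pass along z
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) f[z] = d2[idx3(z, y, x, nz, ny)];
      f.resize(nz); dd.resize(nz);
      dt1d(f, dd, spacing[0], v, zb);
      for (int z = 0; z < nz; ++z) d2[idx3(z, y, x, nz, ny)] = dd[z];
      f.resize(nmax); dd.resize(nmax);
    }
  // pass along y
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) f[y] = d2[idx3(z, y, x, nz, ny)];
      f.resize(ny); dd.resize(ny);
      dt1d(f, dd, spacing[1], v, zb);
      for (int y = 0; y < ny; ++y) d2[idx3(z, y, x, nz, ny)] = dd[y];
      f.resize(nmax); dd.resize(nmax);
    }
  // pass along x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = d2[idx3(z, y, x, nz, ny)];
      f.resize(nx); dd.resize(nx);
      dt1d(f, dd, spacing[2], v, zb);
      for (int x = 0; x < nx; ++x) d2[idx3(z, y, x, nz, ny)] = dd[x];
      f.resize(nmax); dd.resize(nmax);
    }
  NumericVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) out[i] = std::sqrt(d2[i]);
  out.attr("dim") = dim;
  return out;
}

// Separable Gaussian blur; sigma per axis in voxel units. Kernel truncated at
// 3 sigma and renormalised (reflective edge handling).
static void blur_axis(std::vector<double> &a, int nz, int ny, int nx,
                      int axis, double sigma) {
  if (sigma <= 0) return;
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double &v : k) v /= s;
  int len = axis == 0 ? nz : (axis == 1 ? ny : nx);
  std::vector<double> line(len), tmp(len);
  int n1 = axis == 0 ? ny : nz;
  int n2 = axis == 2 ? ny : nx;
  for (int j2 = 0; j2 < n2; ++j2)
    for (int j1 = 0; j1 < n1; ++j1) {
      for (int t = 0; t < len; ++t) {
        int z = axis == 0 ? t : j1;
        int y = axis == 1 ? t : (axis == 0 ? j1 : j2);
        int x = axis == 2 ? t : j2;
        line[t] = a[idx3(z, y, x, nz, ny)];
      }
      for (int t = 0; t < len; ++t) {
        double acc = 0;
        for (int i = -r; i <= r; ++i) {
          int u = t + i;
          if (u < 0) u = -u - 1;
          if (u >= len) u = 2 * len - u - 1;
          acc += k[i + r] * line[u];
        }
        tmp[t] = acc;
      }
      for (int t = 0; t < len; ++t) {
        int z = axis == 0 ? t : j1;
        int y = axis == 1 ? t : (axis == 0 ? j1 : j2);
        int x = axis == 2 ? t : j2;
        a[idx3(z, y, x, nz, ny)] = tmp[t];
      }
    }
}

// [[Rcpp::export(name = ".gaussian_blur_3d")]]
NumericVector gaussian_blur_3d(NumericVector img, NumericVector sigma_vox) {
  IntegerVector dim = img.attr("dim");
  if (dim.size() != 3) stop("img must be a 3D array");
  if (sigma_vox.size() != 3) stop("sigma_vox must have length 3");
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<double> a(img.begin(), img.end());
  blur_axis(a, nz, ny, nx, 0, sigma_vox[0]);
  blur_axis(a, nz, ny, nx, 1, sigma_vox[1]);
  blur_axis(a, nz, ny, nx, 2, sigma_vox[2]);
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// Geodesic nearest-seed partition of the foreground of `mask`: multi-source
// Dijkstra over the 26-neighbour graph with physical step lengths. Seeds are
// linear (1-based) indices into the array; voxels get the label (1..nseed) of
// the geodesically closest seed. Deterministic: ties resolved by insertion
// order (earlier seed wins at equal distance).
// [[Rcpp::export(name = ".geodesic_partition")]]
IntegerVector geodesic_partition(LogicalVector mask, IntegerVector seeds,
                                 NumericVector spacing) {
  IntegerVector dim = mask.attr("dim");
  if (dim.size() != 3) stop("mask must be a 3D array");
  int nz = dim[0], ny = dim[1], nx = dim[2];
  IntegerVector lab(mask.size(), 0);
  lab.attr("dim") = dim;
  std::vector<double> dist(mask.size(), R_PosInf);
  std::vector<Neigh> nb = neighbours(26);
  std::vector<double> step(nb.size());
  for (size_t i = 0; i < nb.size(); ++i) {
    double dz = nb[i].dz * spacing[0], dy = nb[i].dy * spacing[1],
           dx = nb[i].dx * spacing[2];
    step[i] = std::sqrt(dz * dz + dy * dy + dx * dx);
  }
  struct Node { double d; uint64_t order; R_xlen_t i; int lab; };
  struct Cmp {
    bool operator()(const Node &a, const Node &b) const {
      if (a.d != b.d) return a.d > b.d;
      return a.order > b.order;  // earlier pushes win ties
    }
  };
  std::priority_queue<Node, std::vector<Node>, Cmp> pq;
  uint64_t order = 0;
  for (int s = 0; s < seeds.size(); ++s) {
    R_xlen_t i = (R_xlen_t)seeds[s] - 1;
    if (i < 0 || i >= mask.size() || !mask[i])
      stop("seed %d is not a foreground voxel", s + 1);
    pq.push({0.0, order++, i, s + 1});
  }
  while (!pq.empty()) {
    Node nd = pq.top(); pq.pop();
    if (lab[nd.i]) continue;
    lab[nd.i] = nd.lab;
    dist[nd.i] = nd.d;
    int cz = (int)(nd.i % nz);
    int rem = (int)(nd.i / nz);
    int cy = rem % ny;
    int cx = rem / ny;
    for (size_t k = 0; k < nb.size(); ++k) {
      int zz = cz + nb[k].dz, yy = cy + nb[k].dy, xx = cx + nb[k].dx;
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      R_xlen_t j = idx3(zz, yy, xx, nz, ny);
      if (!mask[j] || lab[j]) continue;
      double ndist = nd.d + step[k];
      if (ndist < dist[j]) {
        dist[j] = ndist;
        pq.push({ndist, order++, j, nd.lab});
      }
    }
  }
  return lab;
}
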