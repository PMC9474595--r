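#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Exact 1D squared-distance transform (Felzenszwalh & Huttenlocher) of a
// sampled function f with sample spacing `step` (mm). INF is encoded as 1e300
// so the parabola intersections stay finite.
static void dt1d(std::vector<double>& f, int n, double step,
                 std::vector<double>& d, std::vector<int>& v,
                 std::vector<double>& z) {
  if (n == 1) { d[0] = f[0]; return; }
  int k = 0;
  v[0] = 0;
  z[0] = -1e300;
  z[1] = 1e300;
  for (int q = 1; q < n; ++q) {
    const double qq = q * step;
    double s = 0.0;
    while (true) {
      const double vv = v[k] * step;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2.0 * qq - 2.0 * vv);
      if (s <= z[k] && k > 0) {
        --k;
      } else {
        break;
      }
    }
    if (s <= z[k] && k == 0) {
      v[0] = q;
      z[0] = -1e300;
      z[1] = 1e300;
    } else {
      ++k;
      v[k] = q;
      z[k] = s;
      z[k + 1] = 1e300;
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    const double qq = q * step;
    while (z[k + 1] < qq) ++k;
    const double diff = qq - v[k] * step;
    d[q] = diff * diff + f[v[k]];
  }
}

// Squared Euclidean distance (mm^2) from every voxel to the nearest TRUE
// voxel centre. 2D images are handled by passing a trailing dim of 1.
// Voxels are addressed i + nx*(j + ny*k), matching R array layout.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  bool anyset = false;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (mask[i]) { out[i] = 0.0; anyset = true; } else out[i] = 1e300;
  }
  if (!anyset) {
    std::fill(out.begin(), out.end(), R_PosInf);
    out.attr("dim") = dim;
    return out;
  }
  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      const R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      std::copy(out.begin() + base, out.begin() + base + nx, f.begin());
      dt1d(f, nx, spacing[0], d, v, z);
      std::copy(d.begin(), d.begin() + nx, out.begin() + base);
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      const R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)nx * j];
      dt1d(f, ny, spacing[1], d, v, z);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)nx * j] = d[j];
    }
  // pass along z
  if (nz > 1) {
    const R_xlen_t stride = (R_xlen_t)nx * ny;
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t base = i + (R_xlen_t)nx * j;
        for (int k = 0; k < nz; ++k) f[k] = out[base + stride * k];
        dt1d(f, nz, spacing[2], d, v, z);
        for (int k = 0; k < nz; ++k) out[base + stride * k] = d[k];
      }
  }
  out.attr("dim") = dim;
  return out;
}

// Dilation by an explicit structuring element given as integer voxel offsets
// (one row per offset). Stamps the SE onto every set voxel; out-of-bounds
// offsets are clipped.
// [[Rcpp::export]]
LogicalVector cpp_stamp_dilate(LogicalVector mask, IntegerVector dim,
                               IntegerMatrix offsets) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n);
  const int no = offsets.nrow();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t idx = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        if (!mask[idx]) continue;
        for (int o = 0; o < no; ++o) {
          const int ii = i + offsets(o, 0);
          const int jj = j + offsets(o, 1);
          const int kk = k + offsets(o, 2);
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
            continue;
          out[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)] = true;
        }
      }
  out.attr("dim") = dim;
  return out;
}

// 26-connected component labelling (BFS). Labels are 1..K in discovery
// order; background is 0.
// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  std::vector<int> oi, oj, ok;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        oi.push_back(di); oj.push_back(dj); ok.push_back(dk);
      }
  int cur = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    lab[s] = ++cur;
    q.push(s);
    while (!q.empty()) {
      const R_xlen_t p = q.front(); q.pop();
      const int i = (int)(p % nx);
      const int j = (int)((p / nx) % ny);
      const int k = (int)(p / ((R_xlen_t)nx * ny));
      for (size_t o = 0; o < oi.size(); ++o) {
        const int ii = i + oi[o], jj = j + oj[o], kk = k + ok[o];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        const R_xlen_t pp = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
        if (mask[pp] && lab[pp] == 0) { lab[pp] = cur; q.push(pp); }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// 4-connected flood fill of the FALSE background of a 2D image, seeded from
// the border. Used to find interior holes (e.g. obturator foramina in the
// projected pelvis).
// [[Rcpp::export]]
LogicalMatrix cpp_flood_background(LogicalMatrix img) {
  const int nr = img.nrow(), nc = img.ncol();
  LogicalMatrix reach(nr, nc);
  std::queue<std::pair<int, int> > q;
  for (int i = 0; i < nr; ++i) {
    if (!img(i, 0) && !reach(i, 0)) { reach(i, 0) = true; q.push({i, 0}); }
    if (!img(i, nc - 1) && !reach(i, nc - 1)) {
      reach(i, nc - 1) = true; q.push({i, nc - 1});
    }
  }
  for (int j = 0; j < nc; ++j) {
    if (!img(0, j) && !reach(0, j)) { reach(0, j) = true; q.push({0, j}); }
    if (!img(nr - 1, j) && !reach(nr - 1, j)) {
      reach(nr - 1, j) = true; q.push({nr - 1, j});
    }
  }
  const int di[4] = {1, -1, 0, 0};
  const int dj[4] = {0, 0, 1, -1};
  while (!q.empty()) {
    const std::pair<int, int> p = q.front(); q.pop();
    for (int o = 0; o < 4; ++o) {
      const int ii = p.first + di[o], jj = p.second + dj[o];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      if (!img(ii, jj) && !reach(ii, jj)) {
        reach(ii, jj) = true;
        q.push({ii, jj});
      }
    }
  }
  return reach;
}
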