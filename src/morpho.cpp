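#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Arrays are R arrays indexed [z, y, x] (column-major):
// linear index = z + nz * (y + ny * x), all 0-based here.

static inline int lin(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

//' @noRd
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  IntegerVector labels(mask.size(), 0);
  // neighbourhood offsets
  std::vector<std::array<int, 3>> nb;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int manh = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && manh > 1) continue;
        nb.push_back({dz, dy, dx});
      }
  int current = 0;
  std::queue<std::array<int, 3>> q;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int i = lin(z, y, x, nz, ny);
        if (!mask[i] || labels[i] != 0) continue;
        ++current;
        labels[i] = current;
        q.push({z, y, x});
        while (!q.empty()) {
          std::array<int, 3> v = q.front();
          q.pop();
          for (size_t k = 0; k < nb.size(); ++k) {
            int zz = v[0] + nb[k][0], yy = v[1] + nb[k][1], xx = v[2] + nb[k][2];
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
              continue;
            int j = lin(zz, yy, xx, nz, ny);
            if (mask[j] && labels[j] == 0) {
              labels[j] = current;
              q.push({zz, yy, xx});
            }
          }
        }
      }
  labels.attr("n") = current;
  return labels;
}

static inline double triArea(const double a[3], const double b[3],
                             const double c[3]) {
  double u[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double v[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double w[3] = {u[1] * v[2] - u[2] * v[1], u[2] * v[0] - u[0] * v[2],
                 u[0] * v[1] - u[1] * v[0]};
  return 0.5 * std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
}

// Isosurface area by marching tetrahedra: each cell is split into six
// tetrahedra sharing the main diagonal; within a tetrahedron the isosurface
// is a triangle (1 corner inside) or a quad (2 corners inside), with vertices
// linearly interpolated on the crossing edges. The field must be padded so
// the surface closes (callers pad with background).
//' @noRd
// [[Rcpp::export(name = ".cpp_surface_area")]]
double cpp_surface_area(NumericVector field, IntegerVector dims,
                        NumericVector spacing, double level) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double dz = spacing[0], dy = spacing[1], dx = spacing[2];
  static const int corner[8][3] = {{0, 0, 0}, {0, 0, 1}, {0, 1, 0}, {0, 1, 1},
                                   {1, 0, 0}, {1, 0, 1}, {1, 1, 0}, {1, 1, 1}};
  static const int tets[6][4] = {{0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
                                 {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};
  double area = 0.0;
  double val[8], pos[8][3];
  for (int x = 0; x < nx - 1; ++x)
    for (int y = 0; y < ny - 1; ++y)
      for (int z = 0; z < nz - 1; ++z) {
        bool anyIn = false, allIn = true;
        for (int c = 0; c < 8; ++c) {
          int zz = z + corner[c][0], yy = y + corner[c][1], xx = x + corner[c][2];
          val[c] = field[lin(zz, yy, xx, nz, ny)];
          pos[c][0] = zz * dz;
          pos[c][1] = yy * dy;
          pos[c][2] = xx * dx;
          if (val[c] > level) anyIn = true; else allIn = false;
        }
        if (!anyIn || allIn) continue;
        for (int t = 0; t < 6; ++t) {
          int in[4], out[4], ni = 0, no = 0;
          for (int c = 0; c < 4; ++c) {
            int ci = tets[t][c];
            if (val[ci] > level) in[ni++] = ci; else out[no++] = ci;
          }
          if (ni == 0 || ni == 4) continue;
          double p[4][3];
          int np = 0;
          for (int a = 0; a < ni; ++a)
            for (int b = 0; b < no; ++b) {
              double tt = (level - val[in[a]]) / (val[out[b]] - val[in[a]]);
              for (int d = 0; d < 3; ++d)
                p[np][d] = pos[in[a]][d] + tt * (pos[out[b]][d] - pos[in[a]][d]);
              ++np;
            }
          if (np == 3) {
            area += triArea(p[0], p[1], p[2]);
          } else {
            // np == 4, order (i0,o0),(i0,o1),(i1,o0),(i1,o1): quad 0-1-3-2
            area += triArea(p[0], p[1], p[3]) + triArea(p[0], p[3], p[2]);
          }
        }
      }
  return area;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_max_pairwise_dist")]]
double cpp_max_pairwise_dist(NumericMatrix pts) {
  const int n = pts.nrow();
  double best = 0.0;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) {
      double d0 = pts(i, 0) - pts(j, 0);
      double d1 = pts(i, 1) - pts(j, 1);
      double d2 = pts(i, 2) - pts(j, 2);
      double d = d0 * d0 + d1 * d1 + d2 * d2;
      if (d > best) best = d;
    }
  return std::sqrt(best);
}

// Separable Gaussian blur with reflected boundaries; sigma in voxels per
// axis (zyx); sigma <= 0 skips that axis.
//' @noRd
// [[Rcpp::export(name = ".cpp_gaussian_blur")]]
NumericVector cpp_gaussian_blur(NumericVector vol, IntegerVector dims,
                                NumericVector sigma) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  NumericVector cur = clone(vol);
  const int n[3] = {nz, ny, nx};
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma[axis];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> k(2 * r + 1);
    double sum = 0.0;
    for (int i = -r; i <= r; ++i) {
      k[i + r] = std::exp(-0.5 * (i * i) / (s * s));
      sum += k[i + r];
    }
    for (size_t i = 0; i < k.size(); ++i) k[i] /= sum;
    NumericVector out(cur.size());
    int len = n[axis];
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y)
        for (int z = 0; z < nz; ++z) {
          int c[3] = {z, y, x};
          double acc = 0.0;
          for (int i = -r; i <= r; ++i) {
            int q = c[axis] + i;
            if (q < 0) q = -q - 1;            // reflect
            if (q >= len) q = 2 * len - q - 1;
            int cc[3] = {c[0], c[1], c[2]};
            cc[axis] = q;
            acc += k[i + r] * cur[lin(cc[0], cc[1], cc[2], nz, ny)];
          }
          out[lin(z, y, x, nz, ny)] = acc;
        }
    cur = out;
  }
  return cur;
}
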