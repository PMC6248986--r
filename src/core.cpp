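#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// ---- point-in-polygon -------------------------------------------------------
// Even-odd ray casting; points within `eps` of an edge count as inside, so
// voxel centers lying exactly on a polygon boundary are occupied.
static bool point_on_segment(double px, double py, double x1, double y1,
                             double x2, double y2, double eps) {
  double dx = x2 - x1, dy = y2 - y1;
  double L2 = dx * dx + dy * dy;
  double t = (L2 > 0.0) ? ((px - x1) * dx + (py - y1) * dy) / L2 : 0.0;
  if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
  double qx = x1 + t * dx - px, qy = y1 + t * dy - py;
  return qx * qx + qy * qy <= eps * eps;
}

static bool point_in_polygon(double px, double py, const double* x,
                             const double* y, int n, double eps) {
  bool inside = false;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    if (point_on_segment(px, py, x[j], y[j], x[i], y[i], eps)) return true;
    if ((y[i] > py) != (y[j] > py)) {
      double xint = x[j] + (py - y[j]) * (x[i] - x[j]) / (y[i] - y[j]);
      if (px < xint) inside = !inside;
    }
  }
  return inside;
}

// Fill one z-layer of a voxel grid with the interior of a polygon.
// [[Rcpp::export(name = ".fill_polygon_cpp")]]
LogicalMatrix fill_polygon_cpp(NumericMatrix poly, double x0, double y0,
                               double dx, double dy, int nx, int ny) {
  int n = poly.nrow();
  std::vector<double> px(n), py(n);
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    px[i] = poly(i, 0); py[i] = poly(i, 1);
    xmin = std::min(xmin, px[i]); xmax = std::max(xmax, px[i]);
    ymin = std::min(ymin, py[i]); ymax = std::max(ymax, py[i]);
  }
  double eps = 1e-7 * std::max(1.0, std::max(xmax - xmin, ymax - ymin));
  LogicalMatrix out(nx, ny);
  int i0 = std::max(0, (int)std::floor((xmin - x0) / dx) - 1);
  int i1 = std::min(nx - 1, (int)std::ceil((xmax - x0) / dx) + 1);
  int j0 = std::max(0, (int)std::floor((ymin - y0) / dy) - 1);
  int j1 = std::min(ny - 1, (int)std::ceil((ymax - y0) / dy) + 1);
  for (int i = i0; i <= i1; ++i) {
    double cx = x0 + (i + 0.5) * dx;
    for (int j = j0; j <= j1; ++j) {
      double cy = y0 + (j + 0.5) * dy;
      if (point_in_polygon(cx, cy, px.data(), py.data(), n, eps))
        out(i, j) = true;
    }
  }
  return out;
}

// ---- separable Gaussian smoothing ------------------------------------------
// Zero boundary condition (field assumed 0 outside the grid).
static void blur_axis(std::vector<double>& f, int nx, int ny, int nz,
                      int axis, double sigma) {
  if (sigma <= 0) return;
  int radius = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> k(2 * radius + 1);
  double s = 0.0;
  for (int i = -radius; i <= radius; ++i) {
    k[i + radius] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + radius];
  }
  for (double& w : k) w /= s;
  int dims[3] = {nx, ny, nz};
  int stride[3] = {1, nx, nx * ny};
  int n = dims[axis], st = stride[axis];
  std::vector<double> line(n);
  int o1 = (axis == 0) ? 1 : 0, o2 = (axis == 2) ? 1 : 2;
  for (int a = 0; a < dims[o1]; ++a) {
    for (int b = 0; b < dims[o2]; ++b) {
      int base = a * stride[o1] + b * stride[o2];
      for (int i = 0; i < n; ++i) line[i] = f[base + i * st];
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        int lo = std::max(0, i - radius), hi = std::min(n - 1, i + radius);
        for (int j = lo; j <= hi; ++j) acc += line[j] * k[j - i + radius];
        f[base + i * st] = acc;
      }
    }
  }
}

// [[Rcpp::export(name = ".gaussian_blur_cpp")]]
NumericVector gaussian_blur_cpp(NumericVector field, IntegerVector dims,
                                NumericVector sigma_vox) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> f(field.begin(), field.end());
  blur_axis(f, nx, ny, nz, 0, sigma_vox[0]);
  blur_axis(f, nx, ny, nz, 1, sigma_vox[1]);
  blur_axis(f, nx, ny, nz, 2, sigma_vox[2]);
  NumericVector out(f.begin(), f.end());
  out.attr("dim") = dims;
  return out;
}

// ---- marching tetrahedra surface area --------------------------------------
// Extracts the iso-surface of a scalar field sampled at voxel centers and
// returns its total triangle area in physical units. The field is implicitly
// zero-padded so surfaces close at the grid boundary. Each cell between 8
// neighbouring voxel centers is split into 6 tetrahedra sharing the main
// diagonal; within a tetrahedron the iso-surface is a triangle or a quad with
// vertices linearly interpolated along edges, so the mesh is watertight.
struct P3d { double x, y, z; };

static inline P3d lerp_edge(const P3d& a, const P3d& b, double fa, double fb,
                            double iso) {
  double t = (iso - fa) / (fb - fa);
  P3d p = {a.x + t * (b.x - a.x), a.y + t * (b.y - a.y), a.z + t * (b.z - a.z)};
  return p;
}

static inline double tri_area(const P3d& a, const P3d& b, const P3d& c) {
  double ux = b.x - a.x, uy = b.y - a.y, uz = b.z - a.z;
  double vx = c.x - a.x, vy = c.y - a.y, vz = c.z - a.z;
  double cx = uy * vz - uz * vy, cy = uz * vx - ux * vz, cz = ux * vy - uy * vx;
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

// [[Rcpp::export(name = ".mesh_area_cpp")]]
double mesh_area_cpp(NumericVector field, IntegerVector dims,
                     NumericVector spacing, double iso) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double* F = field.begin();
  auto fval = [&](int i, int j, int k) -> double {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return 0.0;
    return F[i + nx * (j + (size_t)ny * k)];
  };
  // cube corner offsets (standard ordering), tets share diagonal v0-v6
  static const int co[8][3] = {{0,0,0},{1,0,0},{1,1,0},{0,1,0},
                               {0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  static const int tets[6][4] = {{0,1,2,6},{0,2,3,6},{0,3,7,6},
                                 {0,7,4,6},{0,4,5,6},{0,5,1,6}};
  double total = 0.0;
  double fv[8]; P3d pv[8];
  for (int k = -1; k < nz; ++k) {
    for (int j = -1; j < ny; ++j) {
      for (int i = -1; i < nx; ++i) {
        bool anyin = false, anyout = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + co[c][0], jj = j + co[c][1], kk = k + co[c][2];
          fv[c] = fval(ii, jj, kk);
          pv[c] = {(ii + 0.5) * sx, (jj + 0.5) * sy, (kk + 0.5) * sz};
          (fv[c] > iso ? anyin : anyout) = true;
        }
        if (!anyin || !anyout) continue;
        for (int t = 0; t < 6; ++t) {
          int idx[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
          int in[4], nin = 0, out[4], nout = 0;
          for (int c = 0; c < 4; ++c) {
            if (fv[idx[c]] > iso) in[nin++] = idx[c];
            else out[nout++] = idx[c];
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1 || nin == 3) {
            int apex = (nin == 1) ? in[0] : out[0];
            int* base = (nin == 1) ? out : in;
            P3d e0 = lerp_edge(pv[apex], pv[base[0]], fv[apex], fv[base[0]], iso);
            P3d e1 = lerp_edge(pv[apex], pv[base[1]], fv[apex], fv[base[1]], iso);
            P3d e2 = lerp_edge(pv[apex], pv[base[2]], fv[apex], fv[base[2]], iso);
            total += tri_area(e0, e1, e2);
          } else {
            int A = in[0], B = in[1], C = out[0], D = out[1];
            P3d ac = lerp_edge(pv[A], pv[C], fv[A], fv[C], iso);
            P3d ad = lerp_edge(pv[A], pv[D], fv[A], fv[D], iso);
            P3d bd = lerp_edge(pv[B], pv[D], fv[B], fv[D], iso);
            P3d bc = lerp_edge(pv[B], pv[C], fv[B], fv[C], iso);
            total += tri_area(ac, ad, bd) + tri_area(ac, bd, bc);
          }
        }
      }
    }
  }
  return total;
}

// ---- connected components (6-connectivity) ---------------------------------
// [[Rcpp::export(name = ".largest_component_cpp")]]
LogicalVector largest_component_cpp(LogicalVector occ, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<int> label(n, 0);
  int ncomp = 0, best = 0; size_t best_size = 0;
  const int* O = LOGICAL(occ);
  std::vector<size_t> stack;
  for (size_t s = 0; s < n; ++s) {
    if (!O[s] || label[s]) continue;
    ++ncomp;
    size_t size = 0;
    stack.push_back(s); label[s] = ncomp;
    while (!stack.empty()) {
      size_t cur = stack.back(); stack.pop_back(); ++size;
      int i = cur % nx, j = (cur / nx) % ny, k = cur / ((size_t)nx * ny);
      const int di[6] = {-1,1,0,0,0,0}, dj[6] = {0,0,-1,1,0,0}, dk[6] = {0,0,0,0,-1,1};
      for (int d = 0; d < 6; ++d) {
        int ii = i + di[d], jj = j + dj[d], kk = k + dk[d];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        size_t q = ii + nx * (jj + (size_t)ny * kk);
        if (O[q] && !label[q]) { label[q] = ncomp; stack.push_back(q); }
      }
    }
    if (size > best_size) { best_size = size; best = ncomp; }
  }
  LogicalVector out(n);
  for (size_t s = 0; s < n; ++s) out[s] = (label[s] == best && O[s]);
  out.attr("dim") = dims;
  out.attr("n_components") = ncomp;
  return out;
}

// ---- moments of occupied voxel centers -------------------------------------
// Returns count, mean (physical coords) and population covariance (1/N).
// [[Rcpp::export(name = ".occupied_moments_cpp")]]
List occupied_moments_cpp(LogicalVector occ, IntegerVector dims,
                          NumericVector spacing, NumericVector origin) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const int* O = LOGICAL(occ);
  double n = 0.0, m[3] = {0, 0, 0};
  size_t s = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++s)
        if (O[s]) {
          n += 1.0;
          m[0] += origin[0] + (i + 0.5) * spacing[0];
          m[1] += origin[1] + (j + 0.5) * spacing[1];
          m[2] += origin[2] + (k + 0.5) * spacing[2];
        }
  if (n == 0) return List::create(Named("n") = 0);
  for (int d = 0; d < 3; ++d) m[d] /= n;
  double C[6] = {0, 0, 0, 0, 0, 0};  // xx yy zz xy xz yz
  s = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++s)
        if (O[s]) {
          double dx = origin[0] + (i + 0.5) * spacing[0] - m[0];
          double dy = origin[1] + (j + 0.5) * spacing[1] - m[1];
          double dz = origin[2] + (k + 0.5) * spacing[2] - m[2];
          C[0] += dx * dx; C[1] += dy * dy; C[2] += dz * dz;
          C[3] += dx * dy; C[4] += dx * dz; C[5] += dy * dz;
        }
  NumericMatrix cov(3, 3);
  cov(0,0) = C[0] / n; cov(1,1) = C[1] / n; cov(2,2) = C[2] / n;
  cov(0,1) = cov(1,0) = C[3] / n;
  cov(0,2) = cov(2,0) = C[4] / n;
  cov(1,2) = cov(2,1) = C[5] / n;
  return List::create(Named("n") = n,
                      Named("mean") = NumericVector::create(m[0], m[1], m[2]),
                      Named("cov") = cov);
}
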