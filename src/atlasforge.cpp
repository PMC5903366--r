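#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double DT_INF = 1e20;

// ---- cubic B-spline prefilter (Unser recursive filtering, mirror boundary) ----

static double initial_causal(const double *c, int n, int stride, double z) {
  // mirror (whole-sample symmetric) boundary
  double tol = 1e-12;
  int horizon = (int)std::ceil(std::log(tol) / std::log(std::fabs(z)));
  if (horizon < n) {
    double zn = z, sum = c[0];
    for (int i = 1; i < horizon; i++) {
      sum += zn * c[i * stride];
      zn *= z;
    }
    return sum;
  }
  double zn = z, iz = 1.0 / z;
  double z2n = std::pow(z, (double)(n - 1));
  double sum = c[0] + z2n * c[(n - 1) * stride];
  z2n *= z2n * iz;
  for (int i = 1; i <= n - 2; i++) {
    sum += (zn + z2n) * c[i * stride];
    zn *= z;
    z2n *= iz;
  }
  return sum / (1.0 - std::pow(z, (double)(2 * n - 2)));
}

static double initial_anticausal(const double *c, int n, int stride, double z) {
  return (z / (z * z - 1.0)) * (z * c[(n - 2) * stride] + c[(n - 1) * stride]);
}

static void filter_line(double *c, int n, int stride, double z) {
  if (n == 1) return;
  const double gain = 6.0; // (1-z)(1-1/z) for z = sqrt(3)-2
  for (int i = 0; i < n; i++) c[i * stride] *= gain;
  c[0] = initial_causal(c, n, stride, z);
  for (int i = 1; i < n; i++) c[i * stride] += z * c[(i - 1) * stride];
  c[(n - 1) * stride] = initial_anticausal(c, n, stride, z);
  for (int i = n - 2; i >= 0; i--)
    c[i * stride] = z * (c[(i + 1) * stride] - c[i * stride]);
}

// [[Rcpp::export]]
NumericVector cpp_bspline_coeffs(NumericVector arr, IntegerVector dim) {
  const double z = std::sqrt(3.0) - 2.0;
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out = clone(arr);
  double *p = out.begin();
  // along x
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      filter_line(p + (size_t)k * nx * ny + (size_t)j * nx, nx, 1, z);
  // along y
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++)
      filter_line(p + (size_t)k * nx * ny + i, ny, nx, z);
  // along z
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++)
      filter_line(p + (size_t)j * nx + i, nz, nx * ny, z);
  return out;
}

// ---- sampling ----

static inline int mirror_idx(int i, int n) {
  if (n == 1) return 0;
  int p = 2 * n - 2;
  i %= p;
  if (i < 0) i += p;
  return (i < n) ? i : p - i;
}

static inline void bspline_w(double u, double w[4]) {
  double u2 = u * u, u3 = u2 * u;
  w[0] = (1.0 - 3.0 * u + 3.0 * u2 - u3) / 6.0;
  w[1] = (4.0 - 6.0 * u2 + 3.0 * u3) / 6.0;
  w[2] = (1.0 + 3.0 * u + 3.0 * u2 - 3.0 * u3) / 6.0;
  w[3] = u3 / 6.0;
}

// mode: 0 = nearest, 1 = trilinear, 3 = cubic B-spline (arr must hold coefficients)
// pts: n x 3 matrix of 0-based voxel coordinates; points outside the field of
// view (beyond half a voxel past the edge) evaluate to 0.
// [[Rcpp::export]]
NumericVector cpp_sample3d(NumericVector arr, IntegerVector dim, NumericMatrix pts,
                           int mode) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t sxy = (size_t)nx * ny;
  int n = pts.nrow();
  NumericVector out(n);
  const double *a = arr.begin();
  for (int r = 0; r < n; r++) {
    double x = pts(r, 0), y = pts(r, 1), z = pts(r, 2);
    if (!R_finite(x) || !R_finite(y) || !R_finite(z) ||
        x < -0.5 || x > nx - 0.5 || y < -0.5 || y > ny - 0.5 ||
        z < -0.5 || z > nz - 0.5) {
      out[r] = 0.0;
      continue;
    }
    if (mode == 0) {
      int i = (int)std::lround(x), j = (int)std::lround(y), k = (int)std::lround(z);
      if (i < 0) i = 0; if (i > nx - 1) i = nx - 1;
      if (j < 0) j = 0; if (j > ny - 1) j = ny - 1;
      if (k < 0) k = 0; if (k > nz - 1) k = nz - 1;
      out[r] = a[(size_t)k * sxy + (size_t)j * nx + i];
    } else if (mode == 1) {
      int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
      double fx = x - i0, fy = y - j0, fz = z - k0;
      double v = 0.0;
      for (int dk = 0; dk < 2; dk++) {
        int kk = k0 + dk; if (kk < 0) kk = 0; if (kk > nz - 1) kk = nz - 1;
        double wz = dk ? fz : 1.0 - fz;
        for (int dj = 0; dj < 2; dj++) {
          int jj = j0 + dj; if (jj < 0) jj = 0; if (jj > ny - 1) jj = ny - 1;
          double wy = dj ? fy : 1.0 - fy;
          for (int di = 0; di < 2; di++) {
            int ii = i0 + di; if (ii < 0) ii = 0; if (ii > nx - 1) ii = nx - 1;
            double wx = di ? fx : 1.0 - fx;
            v += wx * wy * wz * a[(size_t)kk * sxy + (size_t)jj * nx + ii];
          }
        }
      }
      out[r] = v;
    } else {
      int i0 = (int)std::floor(x) - 1, j0 = (int)std::floor(y) - 1,
          k0 = (int)std::floor(z) - 1;
      double wx[4], wy[4], wz[4];
      bspline_w(x - std::floor(x), wx);
      bspline_w(y - std::floor(y), wy);
      bspline_w(z - std::floor(z), wz);
      double v = 0.0;
      for (int dk = 0; dk < 4; dk++) {
        int kk = mirror_idx(k0 + dk, nz);
        for (int dj = 0; dj < 4; dj++) {
          int jj = mirror_idx(j0 + dj, ny);
          double wyz = wy[dj] * wz[dk];
          for (int di = 0; di < 4; di++) {
            int ii = mirror_idx(i0 + di, nx);
            v += wx[di] * wyz * a[(size_t)kk * sxy + (size_t)jj * nx + ii];
          }
        }
      }
      out[r] = v;
    }
  }
  return out;
}

// ---- exact Euclidean distance transform (Felzenszwalb & Huttenlocher) ----

static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &zb, int n, double w2) {
  int k = 0;
  v[0] = 0;
  zb[0] = -DT_INF;
  zb[1] = DT_INF;
  for (int q = 1; q < n; q++) {
    double s;
    for (;;) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (k > 0 && s <= zb[k]) k--; else break;
    }
    k++;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (zb[k + 1] < q) k++;
    double dq = (double)(q - v[k]);
    d[q] = w2 * dq * dq + f[v[k]];
  }
}

// squared world-distance (mm^2) from every voxel to the nearest TRUE voxel of
// `mask`, for an axis-aligned grid with the given spacings.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t sxy = (size_t)nx * ny;
  NumericVector out((size_t)nx * ny * nz);
  double *o = out.begin();
  for (size_t i = 0; i < (size_t)nx * ny * nz; i++)
    o[i] = mask[i] ? 0.0 : DT_INF;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);
  // x
  double w2 = spacing[0] * spacing[0];
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      double *line = o + (size_t)k * sxy + (size_t)j * nx;
      for (int i = 0; i < nx; i++) f[i] = line[i];
      dt1d(f, d, v, zb, nx, w2);
      for (int i = 0; i < nx; i++) line[i] = d[i];
    }
  // y
  w2 = spacing[1] * spacing[1];
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      double *col = o + (size_t)k * sxy + i;
      for (int j = 0; j < ny; j++) f[j] = col[(size_t)j * nx];
      dt1d(f, d, v, zb, ny, w2);
      for (int j = 0; j < ny; j++) col[(size_t)j * nx] = d[j];
    }
  // z
  w2 = spacing[2] * spacing[2];
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      double *col = o + (size_t)j * nx + i;
      for (int k = 0; k < nz; k++) f[k] = col[(size_t)k * sxy];
      dt1d(f, d, v, zb, nz, w2);
      for (int k = 0; k < nz; k++) col[(size_t)k * sxy] = d[k];
    }
  return out;
}

// max over rows of A of the minimum Euclidean distance to any row of B
// (point coordinates in mm; the brute-force directed Hausdorff reference).
// [[Rcpp::export]]
double cpp_hausdorff_brute(NumericMatrix A, NumericMatrix B) {
  int na = A.nrow(), nb = B.nrow();
  double hmax = 0.0;
  for (int i = 0; i < na; i++) {
    double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    double dmin = R_PosInf;
    for (int j = 0; j < nb; j++) {
      double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < dmin) dmin = d2;
    }
    if (dmin > hmax) hmax = dmin;
  }
  return std::sqrt(hmax);
}

// ---- separable Gaussian smoothing (mirror boundary), sigma in voxels ----

static void conv_line(const double *in, double *out, int n, int stride,
                      const std::vector<double> &kern, int rad) {
  for (int i = 0; i < n; i++) {
    double s = 0.0;
    for (int t = -rad; t <= rad; t++)
      s += kern[t + rad] * in[mirror_idx(i + t, n) * (size_t)stride];
    out[(size_t)i * stride] = s;
  }
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_smooth(NumericVector arr, IntegerVector dim,
                                  NumericVector sigma_vox) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t sxy = (size_t)nx * ny, ntot = sxy * nz;
  NumericVector cur = clone(arr);
  NumericVector buf(ntot);
  for (int ax = 0; ax < 3; ax++) {
    double s = sigma_vox[ax];
    if (s <= 0) continue;
    int rad = std::max(1, (int)std::ceil(3.5 * s));
    std::vector<double> kern(2 * rad + 1);
    double tot = 0.0;
    for (int t = -rad; t <= rad; t++) {
      kern[t + rad] = std::exp(-0.5 * t * t / (s * s));
      tot += kern[t + rad];
    }
    for (auto &w : kern) w /= tot;
    double *p = cur.begin(), *q = buf.begin();
    if (ax == 0) {
      for (int k = 0; k < nz; k++)
        for (int j = 0; j < ny; j++)
          conv_line(p + k * sxy + (size_t)j * nx, q + k * sxy + (size_t)j * nx,
                    nx, 1, kern, rad);
    } else if (ax == 1) {
      for (int k = 0; k < nz; k++)
        for (int i = 0; i < nx; i++)
          conv_line(p + k * sxy + i, q + k * sxy + i, ny, nx, kern, rad);
    } else {
      for (int j = 0; j < ny; j++)
        for (int i = 0; i < nx; i++)
          conv_line(p + (size_t)j * nx + i, q + (size_t)j * nx + i, nz,
                    (int)sxy, kern, rad);
    }
    std::swap(cur, buf);
  }
  return cur;
}
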