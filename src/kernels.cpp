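#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <limits>

using namespace Rcpp;

// Separable convolution of a (pre-padded) matrix; kernels must have odd length.
// Output has the same size as the input; borders are handled by clamping,
// which is exact in the interior left after the caller crops the pad.
// [[Rcpp::export]]
NumericMatrix conv_sep_cpp(const NumericMatrix& x,
                           const NumericVector& ky,
                           const NumericVector& kx) {
  const int ny = x.nrow(), nx = x.ncol();
  const int ry = (ky.size() - 1) / 2, rx = (kx.size() - 1) / 2;
  NumericMatrix tmp(ny, nx), out(ny, nx);
  // along rows (y)
  for (int j = 0; j < nx; ++j) {
    for (int i = 0; i < ny; ++i) {
      double s = 0.0;
      for (int t = -ry; t <= ry; ++t) {
        int ii = i + t;
        if (ii < 0) ii = 0; else if (ii >= ny) ii = ny - 1;
        s += x(ii, j) * ky[t + ry];
      }
      tmp(i, j) = s;
    }
  }
  // along cols (x)
  for (int j = 0; j < nx; ++j) {
    for (int i = 0; i < ny; ++i) {
      double s = 0.0;
      for (int t = -rx; t <= rx; ++t) {
        int jj = j + t;
        if (jj < 0) jj = 0; else if (jj >= nx) jj = nx - 1;
        s += tmp(i, jj) * kx[t + rx];
      }
      out(i, j) = s;
    }
  }
  return out;
}

static inline double mirror_coord(double v, int n) {
  // reflect (edge sample not repeated) into [0, n-1]
  if (n == 1) return 0.0;
  const double period = 2.0 * (n - 1);
  v = std::fabs(v);
  v -= std::floor(v / period) * period; // v mod period, avoiding fmod
  if (v > n - 1) v = period - v;
  return v;
}

static inline double bilin(const NumericMatrix& m, double y, double x) {
  const int ny = m.nrow(), nx = m.ncol();
  y = mirror_coord(y, ny);
  x = mirror_coord(x, nx);
  int y0 = (int)std::floor(y), x0 = (int)std::floor(x);
  int y1 = std::min(y0 + 1, ny - 1), x1 = std::min(x0 + 1, nx - 1);
  double fy = y - y0, fx = x - x0;
  return (1 - fy) * ((1 - fx) * m(y0, x0) + fx * m(y0, x1)) +
         fy * ((1 - fx) * m(y1, x0) + fx * m(y1, x1));
}

static inline double catmull_1d(double p0, double p1, double p2, double p3, double t) {
  return 0.5 * ((2.0 * p1) + (-p0 + p2) * t +
                (2.0 * p0 - 5.0 * p1 + 4.0 * p2 - p3) * t * t +
                (-p0 + 3.0 * p1 - 3.0 * p2 + p3) * t * t * t);
}

static inline double catmull(const NumericMatrix& m, double y, double x) {
  const int ny = m.nrow(), nx = m.ncol();
  y = mirror_coord(y, ny);
  x = mirror_coord(x, nx);
  int y1 = (int)std::floor(y), x1 = (int)std::floor(x);
  double fy = y - y1, fx = x - x1;
  double col[4];
  for (int i = 0; i < 4; ++i) {
    int yi = y1 - 1 + i;
    if (yi < 0) yi = -yi;
    if (yi > ny - 1) yi = 2 * (ny - 1) - yi;
    if (yi < 0) yi = 0;
    double row[4];
    for (int j = 0; j < 4; ++j) {
      int xj = x1 - 1 + j;
      if (xj < 0) xj = -xj;
      if (xj > nx - 1) xj = 2 * (nx - 1) - xj;
      if (xj < 0) xj = 0;
      row[j] = m(yi, xj);
    }
    col[i] = catmull_1d(row[0], row[1], row[2], row[3], fx);
  }
  return catmull_1d(col[0], col[1], col[2], col[3], fy);
}

// SRRF radiality on an M-times magnified grid.
//
// For each magnified centre c, K ring points p_k = c + r (cos, sin) are
// sampled; the gradient at p_k (bilinear) defines a line; the contribution is
// sign * max(0, 1 - d/r)^6 with d the perpendicular distance from c to that
// line and sign +1 when the gradient points toward c (convergent / bright
// structure). The sixth-power ramp keeps the convergence measure tightly
// peaked so nearby emitters stay distinct. Radiality is the mean
// contribution; optional positivity clamp and intensity weighting
// (Catmull-Rom interpolated frame intensity).
// [[Rcpp::export]]
NumericMatrix radiality_cpp(const NumericMatrix& frame,
                            const NumericMatrix& gy,
                            const NumericMatrix& gx,
                            double ring_radius, int mag, int nsamples,
                            bool positivity, bool intensity_weighting) {
  const int ny = frame.nrow(), nx = frame.ncol();
  const int NY = ny * mag, NX = nx * mag;
  NumericMatrix out(NY, NX);
  const double* py_ptr = REAL(gy);
  const double* px_ptr = REAL(gx);
  double* out_ptr = REAL(out);
  std::vector<double> cy(nsamples), cx(nsamples);
  for (int k = 0; k < nsamples; ++k) {
    double th = 2.0 * M_PI * k / nsamples;
    cy[k] = ring_radius * std::sin(th);
    cx[k] = ring_radius * std::cos(th);
  }
  const double eps = 1e-12;
  const double inv_r = 1.0 / ring_radius;
  const double inv_n = 1.0 / nsamples;
  for (int J = 0; J < NX; ++J) {
    const double xc = (J + 0.5) / mag - 0.5;
    for (int I = 0; I < NY; ++I) {
      const double yc = (I + 0.5) / mag - 0.5;
      double acc = 0.0;
      for (int k = 0; k < nsamples; ++k) {
        const double py = yc + cy[k], px = xc + cx[k];
        // sample the gradient at the reflected position near borders (rare),
        // but keep the true ring-point geometry for the distance term
        double sy = py, sx = px;
        if (sy < 0.0 || sy > ny - 1) sy = mirror_coord(sy, ny);
        if (sx < 0.0 || sx > nx - 1) sx = mirror_coord(sx, nx);
        const int y0 = (int)sy, x0 = (int)sx;
        const int y1 = y0 + 1 < ny ? y0 + 1 : ny - 1;
        const int x1 = x0 + 1 < nx ? x0 + 1 : nx - 1;
        const double fy = sy - y0, fx = sx - x0;
        const double w00 = (1 - fy) * (1 - fx), w01 = (1 - fy) * fx;
        const double w10 = fy * (1 - fx), w11 = fy * fx;
        const int i00 = y0 + ny * x0, i01 = y0 + ny * x1;
        const int i10 = y1 + ny * x0, i11 = y1 + ny * x1;
        const double gyv = w00 * py_ptr[i00] + w01 * py_ptr[i01] +
                           w10 * py_ptr[i10] + w11 * py_ptr[i11];
        const double gxv = w00 * px_ptr[i00] + w01 * px_ptr[i01] +
                           w10 * px_ptr[i10] + w11 * px_ptr[i11];
        const double g2 = gyv * gyv + gxv * gxv;
        if (g2 < eps) continue; // flat sample contributes 0
        const double gn = std::sqrt(g2);
        const double vy = yc - py, vx = xc - px; // ring point -> centre
        double w = 1.0 - std::fabs(vy * gxv - vx * gyv) * inv_r / gn;
        if (w < 0.0) w = 0.0;
        const double w2 = w * w; w = w2 * w2 * w2; // (1 - d/r)^6
        acc += (vy * gyv + vx * gxv) > 0.0 ? w : -w;
      }
      double r = acc * inv_n;
      if (positivity && r < 0.0) r = 0.0;
      if (intensity_weighting) {
        r *= catmull(frame, yc, xc);
        if (positivity && r < 0.0) r = 0.0;
      }
      out_ptr[I + (long)NY * J] = r;
    }
  }
  return out;
}

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// 1-D lower envelope of parabolas.
static void edt_1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  const double INF = std::numeric_limits<double>::infinity();
  int q0 = 0;
  while (q0 < n && f[q0] == INF) ++q0;
  if (q0 == n) { // no finite site in this scanline
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = q0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact SQUARED Euclidean distance from each TRUE pixel to the nearest FALSE
// pixel; FALSE pixels get 0. Integer-valued, hence exact in doubles.
// [[Rcpp::export]]
NumericMatrix edt_sq_cpp(const LogicalMatrix& mask) {
  const int ny = mask.nrow(), nx = mask.ncol();
  const double INF = std::numeric_limits<double>::infinity();
  NumericMatrix d2(ny, nx);
  // column pass
  std::vector<double> f(std::max(ny, nx)), d(std::max(ny, nx));
  for (int j = 0; j < nx; ++j) {
    for (int i = 0; i < ny; ++i) f[i] = mask(i, j) ? INF : 0.0;
    edt_1d(f, d, ny);
    for (int i = 0; i < ny; ++i) d2(i, j) = d[i];
  }
  // row pass
  for (int i = 0; i < ny; ++i) {
    for (int j = 0; j < nx; ++j) f[j] = d2(i, j);
    edt_1d(f, d, nx);
    for (int j = 0; j < nx; ++j) d2(i, j) = d[j];
  }
  return d2;
}

// Local thickness painting: spacing(p) = max over centres c (free pixels,
// squared radius r2 = dist2(c)) with ||p - c||^2 < r2 of 2 * sqrt(r2).
// Squared distances are exact integers, so the strict open-disk comparison
// has no floating-point ambiguity. Centres processed in descending radius.
// [[Rcpp::export]]
NumericMatrix paint_spacing_cpp(const LogicalMatrix& free_mask,
                                const NumericMatrix& dist2) {
  const int ny = free_mask.nrow(), nx = free_mask.ncol();
  NumericMatrix out(ny, nx);
  struct C { double r2; int i, j; };
  std::vector<C> centres;
  centres.reserve(1024);
  for (int j = 0; j < nx; ++j)
    for (int i = 0; i < ny; ++i)
      if (free_mask(i, j) && dist2(i, j) > 0.0)
        centres.push_back({dist2(i, j), i, j});
  std::sort(centres.begin(), centres.end(),
            [](const C& a, const C& b) { return a.r2 > b.r2; });
  for (const C& c : centres) {
    const double r2 = c.r2, r = std::sqrt(r2), diam = 2.0 * r;
    int i0 = std::max(0, (int)std::floor(c.i - r));
    int i1 = std::min(ny - 1, (int)std::ceil(c.i + r));
    for (int i = i0; i <= i1; ++i) {
      const double dy2 = (double)(i - c.i) * (i - c.i);
      for (int j = std::max(0, (int)std::floor(c.j - r));
           j <= std::min(nx - 1, (int)std::ceil(c.j + r)); ++j) {
        const double dx = j - c.j;
        if (dy2 + dx * dx < r2 && out(i, j) < diam)
          out(i, j) = diam;
      }
    }
  }
  return out;
}
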