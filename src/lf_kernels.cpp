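#include <Rcpp.h>
using namespace Rcpp;

// Shear-refocus geometry shared by all kernels.
//
// The 4D radiance L(x, y, u, v) is stored column-major with dims
// (nx, ny, nu, nv). Spatial coordinates are centred microlens indices,
// angular coordinates are centred intra-subimage pixel offsets. Refocusing
// at shear parameter alpha reads the source sample
//   xs = u*(1 - 1/alpha) + x/alpha,  ys = v*(1 - 1/alpha) + y/alpha
// with bilinear or Catmull-Rom cubic interpolation in (x, y); samples outside the
// spatial extent are excluded (not zero-filled) so that downstream
// integration can renormalise per pixel.

static inline bool bilinear_fetch(const double *slab, int nx, int ny,
                                  double xi, double yi, double &out) {
  if (xi < 0.0 || yi < 0.0 || xi > nx - 1.0 || yi > ny - 1.0) return false;
  int x0 = (int)std::floor(xi), y0 = (int)std::floor(yi);
  if (x0 == nx - 1) x0--;
  if (y0 == ny - 1) y0--;
  double fx = xi - x0, fy = yi - y0;
  const double *c = slab + (R_xlen_t)y0 * nx + x0;
  double v00 = c[0], v10 = c[1], v01 = c[nx], v11 = c[nx + 1];
  if (ISNAN(v00) || ISNAN(v10) || ISNAN(v01) || ISNAN(v11)) return false;
  out = v00 * (1 - fx) * (1 - fy) + v10 * fx * (1 - fy) +
        v01 * (1 - fx) * fy + v11 * fx * fy;
  return true;
}

// Catmull-Rom weights for fractional offset f in [0, 1].
static inline void cr_weights(double f, double w[4]) {
  double f2 = f * f, f3 = f2 * f;
  w[0] = 0.5 * (-f3 + 2 * f2 - f);
  w[1] = 0.5 * (3 * f3 - 5 * f2 + 2);
  w[2] = 0.5 * (-3 * f3 + 4 * f2 + f);
  w[3] = 0.5 * (f3 - f2);
}

// Separable Catmull-Rom cubic interpolation with replicate clamping of the
// 4x4 support at the borders; exact at integer offsets. Validity follows
// the same rule as bilinear_fetch (inside the spatial extent, no NaN in
// the support).
static inline bool cubic_fetch(const double *slab, int nx, int ny,
                               double xi, double yi, double &out) {
  if (xi < 0.0 || yi < 0.0 || xi > nx - 1.0 || yi > ny - 1.0) return false;
  int x0 = (int)std::floor(xi), y0 = (int)std::floor(yi);
  if (x0 == nx - 1) x0--;
  if (y0 == ny - 1) y0--;
  double wx[4], wy[4];
  cr_weights(xi - x0, wx);
  cr_weights(yi - y0, wy);
  double acc = 0.0;
  for (int j = 0; j < 4; ++j) {
    int yj = y0 - 1 + j;
    if (yj < 0) yj = 0;
    if (yj > ny - 1) yj = ny - 1;
    double row = 0.0;
    for (int i = 0; i < 4; ++i) {
      int xi_ = x0 - 1 + i;
      if (xi_ < 0) xi_ = 0;
      if (xi_ > nx - 1) xi_ = nx - 1;
      double v = slab[(R_xlen_t)yj * nx + xi_];
      if (ISNAN(v)) return false;
      row += wx[i] * v;
    }
    acc += wy[j] * row;
  }
  out = acc;
  return true;
}

static inline bool interp_fetch(const double *slab, int nx, int ny,
                                double xi, double yi, double &out,
                                int method) {
  return method == 1 ? cubic_fetch(slab, nx, ny, xi, yi, out)
                     : bilinear_fetch(slab, nx, ny, xi, yi, out);
}

// Per-alpha first and second moments of the sheared light field over the
// valid angular aperture: sum, sum of squares and sample count at each
// spatial position, for every alpha in the sweep. From these the caller
// derives both the refocused (view-integrated) image and the angular
// standard deviation, i.e. the raw material of the defocus and
// correspondence cues, without materialising any 4D intermediate.
// With object_frame = true the sheared field is sampled at
// x + u*(1 - 1/alpha) (the refocused photograph resampled back to native
// object coordinates), so one pixel tracks one object point across the
// sweep; with false the verbatim x/alpha photograph coordinates are used.
// [[Rcpp::export]]
List lf_sweep_stats_cpp(NumericVector L, IntegerVector dims,
                        NumericVector alphas, NumericVector ucoord,
                        NumericVector vcoord, LogicalVector angmask,
                        int interp, bool object_frame) {
  int nx = dims[0], ny = dims[1], nu = dims[2], nv = dims[3];
  int na = alphas.size();
  NumericVector sum(Dimension(nx, ny, na)), sumsq(Dimension(nx, ny, na));
  IntegerVector count(Dimension(nx, ny, na));
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  const double *Lp = REAL(L);
  for (int k = 0; k < na; ++k) {
    double a = alphas[k];
    double sh = 1.0 - 1.0 / a, inva = object_frame ? 1.0 : 1.0 / a;
    double *sp = REAL(sum) + (R_xlen_t)k * nx * ny;
    double *qp = REAL(sumsq) + (R_xlen_t)k * nx * ny;
    int *cp = INTEGER(count) + (R_xlen_t)k * nx * ny;
    for (int v = 0; v < nv; ++v) {
      for (int u = 0; u < nu; ++u) {
        if (!angmask[v * nu + u]) continue;
        double du = ucoord[u] * sh, dv = vcoord[v] * sh;
        const double *slab = Lp + ((R_xlen_t)v * nu + u) * nx * ny;
        for (int y = 0; y < ny; ++y) {
          double yi = dv + (y - cy) * inva + cy;
          if (yi < 0.0 || yi > ny - 1.0) continue;
          for (int x = 0; x < nx; ++x) {
            double xi = du + (x - cx) * inva + cx;
            double val;
            if (interp_fetch(slab, nx, ny, xi, yi, val, interp)) {
              R_xlen_t o = (R_xlen_t)y * nx + x;
              sp[o] += val;
              qp[o] += val * val;
              cp[o] += 1;
            }
          }
        }
      }
    }
  }
  return List::create(_["sum"] = sum, _["sumsq"] = sumsq,
                      _["count"] = count);
}

// Full sheared 4D light field for a single alpha. Out-of-bounds samples
// become NA so the validity bookkeeping survives the shear.
// [[Rcpp::export]]
NumericVector lf_refocus_cpp(NumericVector L, IntegerVector dims,
                             double alpha, NumericVector ucoord,
                             NumericVector vcoord, LogicalVector angmask,
                             int interp) {
  int nx = dims[0], ny = dims[1], nu = dims[2], nv = dims[3];
  NumericVector out((R_xlen_t)nx * ny * nu * nv);
  out.attr("dim") = dims;
  std::fill(out.begin(), out.end(), NA_REAL);
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  double sh = 1.0 - 1.0 / alpha, inva = 1.0 / alpha;
  const double *Lp = REAL(L);
  double *op = REAL(out);
  for (int v = 0; v < nv; ++v) {
    for (int u = 0; u < nu; ++u) {
      R_xlen_t base = ((R_xlen_t)v * nu + u) * nx * ny;
      if (!angmask[v * nu + u]) continue;
      double du = ucoord[u] * sh, dv = vcoord[v] * sh;
      const double *slab = Lp + base;
      for (int y = 0; y < ny; ++y) {
        double yi = dv + (y - cy) * inva + cy;
        for (int x = 0; x < nx; ++x) {
          double xi = du + (x - cx) * inva + cx;
          double val;
          if (interp_fetch(slab, nx, ny, xi, yi, val, interp))
            op[base + (R_xlen_t)y * nx + x] = val;
        }
      }
    }
  }
  return out;
}

// Forward-render a depth-textured scene into one angular view by bilinear
// splatting: a scene sample at centred position (x, y) with shear alpha(z)
// lands at (x + (1 - 1/alpha)*u, y + (1 - 1/alpha)*v), the exact adjoint
// of the refocus shear read.
// [[Rcpp::export]]
NumericMatrix lf_splat_view_cpp(NumericMatrix intensity, NumericMatrix shear,
                                double u, double v) {
  int nx = intensity.nrow(), ny = intensity.ncol();
  NumericMatrix out(nx, ny);
  for (int y = 0; y < ny; ++y) {
    for (int x = 0; x < nx; ++x) {
      double I = intensity(x, y);
      if (ISNAN(I) || I == 0.0) continue;
      double sh = shear(x, y);
      double xi = x + sh * u, yi = y + sh * v;
      if (xi < 0.0 || yi < 0.0 || xi > nx - 1.0 || yi > ny - 1.0) continue;
      int x0 = (int)std::floor(xi), y0 = (int)std::floor(yi);
      if (x0 == nx - 1) x0--;
      if (y0 == ny - 1) y0--;
      double fx = xi - x0, fy = yi - y0;
      out(x0, y0) += I * (1 - fx) * (1 - fy);
      out(x0 + 1, y0) += I * fx * (1 - fy);
      out(x0, y0 + 1) += I * (1 - fx) * fy;
      out(x0 + 1, y0 + 1) += I * fx * fy;
    }
  }
  return out;
}
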