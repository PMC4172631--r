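#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bilinear sample of img at physical point (x, y); image centered on the
// origin, pixel (r, c) center at x = (c + 0.5) * px - fov/2,
// y = fov/2 - (r + 0.5) * px (row index grows downward). Zero outside.
static inline double sample_bilinear(const NumericMatrix &img, double x,
                                     double y, double px, double half_fov) {
  const int nr = img.nrow(), nc = img.ncol();
  double cf = (x + half_fov) / px - 0.5;  // fractional column
  double rf = (half_fov - y) / px - 0.5;  // fractional row
  int c0 = (int)std::floor(cf), r0 = (int)std::floor(rf);
  double wc = cf - c0, wr = rf - r0;
  double v = 0.0;
  for (int dr = 0; dr <= 1; ++dr) {
    int r = r0 + dr;
    if (r < 0 || r >= nr) continue;
    double wy = dr ? wr : 1.0 - wr;
    for (int dc = 0; dc <= 1; ++dc) {
      int c = c0 + dc;
      if (c < 0 || c >= nc) continue;
      double wx = dc ? wc : 1.0 - wc;
      v += wy * wx * img(r, c);
    }
  }
  return v;
}

// Joseph-style interpolating line integrals of a mu-grid (1/mm) over a
// parallel-beam geometry. Returns an n_angles x n_bins matrix of unitless
// attenuation integrals (sampling step equals the pixel size; the linear
// interpolation kernel forms a partition of unity along the ray, so an
// axis-aligned ray through one pixel integrates to exactly mu * px).
// [[Rcpp::export]]
NumericMatrix cpp_forward_project(NumericMatrix mu, double pixel_size_mm,
                                  NumericVector angles_rad,
                                  NumericVector bin_offsets_mm) {
  const int na = angles_rad.size(), nb = bin_offsets_mm.size();
  const double half_fov = 0.5 * pixel_size_mm * mu.nrow();
  const double step = pixel_size_mm;
  const double tmax = half_fov * M_SQRT2 + step;
  const int nt = (int)std::ceil(2.0 * tmax / step) + 1;
  NumericMatrix p(na, nb);
  for (int ia = 0; ia < na; ++ia) {
    const double ct = std::cos(angles_rad[ia]), st = std::sin(angles_rad[ia]);
    // detector axis u = (ct, st); ray direction v = (-st, ct)
    for (int ib = 0; ib < nb; ++ib) {
      const double s = bin_offsets_mm[ib];
      double acc = 0.0;
      double t = -tmax;
      for (int it = 0; it < nt; ++it, t += step) {
        const double x = s * ct - t * st;
        const double y = s * st + t * ct;
        if (std::fabs(x) > half_fov + step || std::fabs(y) > half_fov + step)
          continue;
        acc += sample_bilinear(mu, x, y, pixel_size_mm, half_fov);
      }
      p(ia, ib) = acc * step;
    }
  }
  return p;
}

// Backprojection of filtered projections (n_angles x n_bins) onto an
// n x n grid; linear interpolation along the detector, angular weight
// pi / n_angles applied here.
// [[Rcpp::export]]
NumericMatrix cpp_back_project(NumericMatrix q, NumericVector angles_rad,
                               NumericVector bin_offsets_mm, int n,
                               double pixel_size_mm) {
  const int na = angles_rad.size(), nb = bin_offsets_mm.size();
  const double half_fov = 0.5 * pixel_size_mm * n;
  const double s0 = bin_offsets_mm[0];
  const double ds = nb > 1 ? bin_offsets_mm[1] - bin_offsets_mm[0] : 1.0;
  const double w = M_PI / na;
  NumericMatrix img(n, n);
  for (int ia = 0; ia < na; ++ia) {
    const double ct = std::cos(angles_rad[ia]), st = std::sin(angles_rad[ia]);
    for (int r = 0; r < n; ++r) {
      const double y = half_fov - (r + 0.5) * pixel_size_mm;
      for (int c = 0; c < n; ++c) {
        const double x = (c + 0.5) * pixel_size_mm - half_fov;
        const double s = x * ct + y * st;
        const double bf = (s - s0) / ds;
        const int b0 = (int)std::floor(bf);
        if (b0 < -1 || b0 > nb - 1) continue;
        const double wb = bf - b0;
        double v = 0.0;
        if (b0 >= 0) v += (1.0 - wb) * q(ia, b0);
        if (b0 + 1 < nb) v += wb * q(ia, b0 + 1);
        img(r, c) += w * v;
      }
    }
  }
  return img;
}
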