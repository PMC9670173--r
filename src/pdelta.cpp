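#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear interpolation of a 3D column-major array at grid coordinates
// (gx, gy, gz) expressed in fractional voxel indices (0-based, voxel centers).
// Points outside the grid bounding box evaluate to 0.
static inline double trilinear_at(const double *v, const int nx, const int ny,
                                  const int nz, double gx, double gy,
                                  double gz) {
  if (gx < 0 || gy < 0 || gz < 0 || gx > nx - 1 || gy > ny - 1 || gz > nz - 1)
    return 0.0;
  int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy),
      k0 = (int)std::floor(gz);
  if (i0 == nx - 1) i0--;
  if (j0 == ny - 1) j0--;
  if (k0 == nz - 1) k0--;
  const double fx = gx - i0, fy = gy - j0, fz = gz - k0;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  const double *base = v + i0 * sx + j0 * sy + k0 * sz;
  const double c000 = base[0], c100 = base[sx], c010 = base[sy],
               c110 = base[sx + sy], c001 = base[sz], c101 = base[sx + sz],
               c011 = base[sy + sz], c111 = base[sx + sy + sz];
  const double c00 = c000 * (1 - fx) + c100 * fx;
  const double c10 = c010 * (1 - fx) + c110 * fx;
  const double c01 = c001 * (1 - fx) + c101 * fx;
  const double c11 = c011 * (1 - fx) + c111 * fx;
  const double c0 = c00 * (1 - fy) + c10 * fy;
  const double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// [[Rcpp::export(name = ".trilinear_sample")]]
NumericVector trilinear_sample(NumericVector values, IntegerVector shape,
                               NumericVector origin, NumericVector spacing,
                               NumericMatrix points) {
  const int nx = shape[0], ny = shape[1], nz = shape[2];
  const double *v = REAL(values);
  const int n = points.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double gx = (points(i, 0) - origin[0]) / spacing[0];
    const double gy = (points(i, 1) - origin[1]) / spacing[1];
    const double gz = (points(i, 2) - origin[2]) / spacing[2];
    out[i] = trilinear_at(v, nx, ny, nz, gx, gy, gz);
  }
  return out;
}

// Solid-angle integral of the (trilinearly interpolated) grid over spherical
// caps centered on the detector: for each radius r, returns
//   S(r) = int_cap D(det + r * n(theta, phi)) dOmega
// using a midpoint product rule that is uniform in mu = cos(theta) over
// [cos(theta_max), 1] and uniform in phi over [0, 2*pi); the polar axis is
// `axis` (unit vector from the detector towards the dose region). The cap
// must contain the whole support of the grid as seen from the detector.
// [[Rcpp::export(name = ".shell_integral")]]
NumericVector shell_integral(NumericVector values, IntegerVector shape,
                             NumericVector origin, NumericVector spacing,
                             NumericVector detector, NumericVector radii,
                             NumericVector axis, double cos_theta_max,
                             int n_theta, int n_phi) {
  const int nx = shape[0], ny = shape[1], nz = shape[2];
  const double *v = REAL(values);
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double hx = spacing[0], hy = spacing[1], hz = spacing[2];
  const double dx = detector[0], dy = detector[1], dz = detector[2];

  // orthonormal basis (e1, e2, axis)
  double ax = axis[0], ay = axis[1], az = axis[2];
  const double an = std::sqrt(ax * ax + ay * ay + az * az);
  ax /= an; ay /= an; az /= an;
  double rx = 1, ry = 0, rz = 0;
  if (std::fabs(ax) > 0.9) { rx = 0; ry = 1; rz = 0; }
  double e1x = ay * rz - az * ry, e1y = az * rx - ax * rz,
         e1z = ax * ry - ay * rx;
  double n1 = std::sqrt(e1x * e1x + e1y * e1y + e1z * e1z);
  e1x /= n1; e1y /= n1; e1z /= n1;
  const double e2x = ay * e1z - az * e1y, e2y = az * e1x - ax * e1z,
               e2z = ax * e1y - ay * e1x;

  const double dmu = (1.0 - cos_theta_max) / n_theta;
  const double dphi = 2.0 * M_PI / n_phi;
  const double w = dmu * dphi;

  std::vector<double> smu(n_theta), cmu(n_theta), cph(n_phi), sph(n_phi);
  for (int it = 0; it < n_theta; ++it) {
    const double mu = cos_theta_max + (it + 0.5) * dmu;
    cmu[it] = mu;
    smu[it] = std::sqrt(std::max(0.0, 1.0 - mu * mu));
  }
  for (int ip = 0; ip < n_phi; ++ip) {
    const double phi = (ip + 0.5) * dphi;
    cph[ip] = std::cos(phi);
    sph[ip] = std::sin(phi);
  }

  const int nr = radii.size();
  NumericVector out(nr);
  for (int ir = 0; ir < nr; ++ir) {
    const double r = radii[ir];
    double acc = 0.0;
    for (int it = 0; it < n_theta; ++it) {
      const double ra = r * cmu[it]; // along axis
      const double rs = r * smu[it]; // in the transverse plane
      const double bx = dx + ra * ax, by = dy + ra * ay, bz = dz + ra * az;
      for (int ip = 0; ip < n_phi; ++ip) {
        const double px = bx + rs * (cph[ip] * e1x + sph[ip] * e2x);
        const double py = by + rs * (cph[ip] * e1y + sph[ip] * e2y);
        const double pz = bz + rs * (cph[ip] * e1z + sph[ip] * e2z);
        acc += trilinear_at(v, nx, ny, nz, (px - ox) / hx, (py - oy) / hy,
                            (pz - oz) / hz);
      }
    }
    out[ir] = acc * w;
  }
  return out;
}
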