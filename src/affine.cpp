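#include <Rcpp.h>
using namespace Rcpp;

// Trilinear resampling of a cubic volume under a rigid transform.
//
// Convention (matches R-side rigid_transform): the forward transform first
// rotates the object by R about the voxel center c = floor(N/2) (0-based),
// then translates it by `shift` voxels.  The output is therefore gathered as
//   out[x] = in( R^T * (x - c - shift) + c )
// with trilinear interpolation and zero fill outside the grid.
//
// `vol` is an N^3 numeric array in R's column-major layout; `rot` is the 3x3
// rotation matrix (object rotation, not the sampling rotation); `shift` is in
// voxels.

// [[Rcpp::export(name = ".cpp_affine_resample")]]
NumericVector cpp_affine_resample(NumericVector vol, NumericMatrix rot,
                                  NumericVector shift) {
  IntegerVector dim = vol.attr("dim");
  if (dim.size() != 3 || dim[0] != dim[1] || dim[0] != dim[2])
    stop("volume must be a cubic 3-D array");
  const int n = dim[0];
  const double c = n / 2; // integer division semantics: floor(N/2)

  // sampling matrix = R^T (inverse rotation)
  double m00 = rot(0, 0), m01 = rot(1, 0), m02 = rot(2, 0);
  double m10 = rot(0, 1), m11 = rot(1, 1), m12 = rot(2, 1);
  double m20 = rot(0, 2), m21 = rot(1, 2), m22 = rot(2, 2);
  const double sx = shift[0], sy = shift[1], sz = shift[2];

  NumericVector out(vol.size());
  out.attr("dim") = dim;
  const double *v = vol.begin();
  double *o = out.begin();
  const int n2 = n * n;

  for (int z = 0; z < n; ++z) {
    const double dz = z - c - sz;
    for (int y = 0; y < n; ++y) {
      const double dy = y - c - sy;
      for (int x = 0; x < n; ++x) {
        const double dx = x - c - sx;
        const double px = m00 * dx + m01 * dy + m02 * dz + c;
        const double py = m10 * dx + m11 * dy + m12 * dz + c;
        const double pz = m20 * dx + m21 * dy + m22 * dz + c;
        const int ix = (int)std::floor(px);
        const int iy = (int)std::floor(py);
        const int iz = (int)std::floor(pz);
        if (ix < -1 || ix > n - 1 || iy < -1 || iy > n - 1 ||
            iz < -1 || iz > n - 1) {
          o[x + n * y + n2 * z] = 0.0;
          continue;
        }
        const double fx = px - ix, fy = py - iy, fz = pz - iz;
        double acc = 0.0;
        for (int kz = 0; kz <= 1; ++kz) {
          const int zz = iz + kz;
          if (zz < 0 || zz >= n) continue;
          const double wz = kz ? fz : 1.0 - fz;
          for (int ky = 0; ky <= 1; ++ky) {
            const int yy = iy + ky;
            if (yy < 0 || yy >= n) continue;
            const double wy = ky ? fy : 1.0 - fy;
            for (int kx = 0; kx <= 1; ++kx) {
              const int xx = ix + kx;
              if (xx < 0 || xx >= n) continue;
              const double wx = kx ? fx : 1.0 - fx;
              acc += wx * wy * wz * v[xx + n * yy + n2 * zz];
            }
          }
        }
        o[x + n * y + n2 * z] = acc;
      }
    }
  }
  return out;
}
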