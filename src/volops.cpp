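#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// All sampling uses trilinear (3D) or bilinear (2D) interpolation with
// out-of-bounds treated as zero density. Coordinates are 0-based voxel
// indices; the rotation centre is the geometric box centre (n-1)/2.

static inline double tri_sample(const double *v, int nx, int ny, int nz,
                                double x, double y, double z) {
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
    return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  int x1 = x0 + 1 < nx ? x0 + 1 : x0;
  int y1 = y0 + 1 < ny ? y0 + 1 : y0;
  int z1 = z0 + 1 < nz ? z0 + 1 : z0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  #define V(i,j,k) v[(i) + nx * ((j) + (size_t)ny * (k))]
  double c00 = V(x0,y0,z0) * (1-fx) + V(x1,y0,z0) * fx;
  double c10 = V(x0,y1,z0) * (1-fx) + V(x1,y1,z0) * fx;
  double c01 = V(x0,y0,z1) * (1-fx) + V(x1,y0,z1) * fx;
  double c11 = V(x0,y1,z1) * (1-fx) + V(x1,y1,z1) * fx;
  #undef V
  double c0 = c00 * (1-fy) + c10 * fy;
  double c1 = c01 * (1-fy) + c11 * fy;
  return c0 * (1-fz) + c1 * fz;
}

static inline double bi_sample(const double *im, int nx, int ny,
                               double x, double y) {
  if (x < 0 || y < 0 || x > nx - 1 || y > ny - 1) return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  int x1 = x0 + 1 < nx ? x0 + 1 : x0;
  int y1 = y0 + 1 < ny ? y0 + 1 : y0;
  double fx = x - x0, fy = y - y0;
  double c0 = im[x0 + nx * y0] * (1-fx) + im[x1 + nx * y0] * fx;
  double c1 = im[x0 + nx * y1] * (1-fx) + im[x1 + nx * y1] * fx;
  return c0 * (1-fy) + c1 * fy;
}

// Sum of anisotropic-free Gaussian pseudo-atoms on a cubic grid.
// atoms: columns x, y, z (voxel units, relative to box centre), weight,
// sigma (voxels). Evaluation truncated at 6 sigma.
// [[Rcpp::export]]
NumericVector cpp_render_gaussians(int box, NumericMatrix atoms) {
  NumericVector out(box * box * (size_t)box);
  out.attr("dim") = IntegerVector::create(box, box, box);
  double c = (box - 1) / 2.0;
  double *v = REAL(out);
  for (int a = 0; a < atoms.nrow(); ++a) {
    double ax = atoms(a, 0) + c, ay = atoms(a, 1) + c, az = atoms(a, 2) + c;
    double w = atoms(a, 3), s = atoms(a, 4);
    double cut = 6.0 * s, inv2s2 = 1.0 / (2.0 * s * s);
    int x0 = std::max(0, (int)std::ceil(ax - cut));
    int x1 = std::min(box - 1, (int)std::floor(ax + cut));
    int y0 = std::max(0, (int)std::ceil(ay - cut));
    int y1 = std::min(box - 1, (int)std::floor(ay + cut));
    int z0 = std::max(0, (int)std::ceil(az - cut));
    int z1 = std::min(box - 1, (int)std::floor(az + cut));
    for (int z = z0; z <= z1; ++z) {
      double dz2 = (z - az) * (z - az);
      for (int y = y0; y <= y1; ++y) {
        double dy2 = (y - ay) * (y - ay);
        for (int x = x0; x <= x1; ++x) {
          double d2 = (x - ax) * (x - ax) + dy2 + dz2;
          v[x + box * (y + (size_t)box * z)] += w * std::exp(-d2 * inv2s2);
        }
      }
    }
  }
  return out;
}

// Resample a volume under a rigid transform: the object is rotated by R
// about the box centre, then translated by t (voxels). Output voxel p takes
// the value of the input at R^T (p - c - t) + c.
// [[Rcpp::export]]
NumericVector cpp_rigid_resample(NumericVector vol, NumericMatrix R,
                                 NumericVector t) {
  IntegerVector dm = vol.attr("dim");
  int nx = dm[0], ny = dm[1], nz = dm[2];
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0, cz = (nz - 1) / 2.0;
  NumericVector out(vol.size());
  out.attr("dim") = dm;
  const double *v = REAL(vol);
  double *o = REAL(out);
  double r11 = R(0,0), r12 = R(0,1), r13 = R(0,2);
  double r21 = R(1,0), r22 = R(1,1), r23 = R(1,2);
  double r31 = R(2,0), r32 = R(2,1), r33 = R(2,2);
  for (int z = 0; z < nz; ++z) {
    double dz = z - cz - t[2];
    for (int y = 0; y < ny; ++y) {
      double dy = y - cy - t[1];
      for (int x = 0; x < nx; ++x) {
        double dx = x - cx - t[0];
        // R^T * d
        double sx = r11 * dx + r21 * dy + r31 * dz + cx;
        double sy = r12 * dx + r22 * dy + r32 * dz + cy;
        double sz = r13 * dx + r23 * dy + r33 * dz + cz;
        o[x + nx * (y + (size_t)ny * z)] = tri_sample(v, nx, ny, nz, sx, sy, sz);
      }
    }
  }
  return out;
}

// Project a volume along z after rotating the object by each matrix in
// Rmats (9 x n, column-major per matrix). Returns box x box x n stack.
// [[Rcpp::export]]
NumericVector cpp_project(NumericVector vol, NumericMatrix Rmats) {
  IntegerVector dm = vol.attr("dim");
  int nx = dm[0], ny = dm[1], nz = dm[2];
  int nR = Rmats.ncol();
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0, cz = (nz - 1) / 2.0;
  NumericVector out(nx * (size_t)ny * nR);
  out.attr("dim") = IntegerVector::create(nx, ny, nR);
  const double *v = REAL(vol);
  double *o = REAL(out);
  for (int m = 0; m < nR; ++m) {
    const double *R = &Rmats(0, m); // column-major 3x3: R[0..8]
    for (int z = 0; z < nz; ++z) {
      double dz = z - cz;
      for (int y = 0; y < ny; ++y) {
        double dy = y - cy;
        for (int x = 0; x < nx; ++x) {
          double dx = x - cx;
          // R^T * d  (object rotated by R; sample source = R^T p)
          double sx = R[0] * dx + R[1] * dy + R[2] * dz + cx;
          double sy = R[3] * dx + R[4] * dy + R[5] * dz + cy;
          double sz = R[6] * dx + R[7] * dy + R[8] * dz + cz;
          o[x + nx * (y + (size_t)ny * m)] += tri_sample(v, nx, ny, nz, sx, sy, sz);
        }
      }
    }
  }
  return out;
}

// Real-space backprojection: smear each image back along its viewing axis.
// For orientation R (the matrix used to project), voxel p maps to image
// coordinates (q1, q2) of R^T... inverse: projection sampled the volume at
// R^T p, so volume voxel w contributes to pixel (Rw)_xy; hence voxel w
// accumulates image value at q = R w (first two components).
// Per-image weights scale both the accumulated density and the coverage.
// Returns list(volume, coverage).
// [[Rcpp::export]]
List cpp_backproject(NumericVector images, NumericMatrix Rmats,
                     NumericVector weights) {
  IntegerVector dm = images.attr("dim");
  int nx = dm[0], ny = dm[1], nimg = dm[2];
  int box = nx;
  double c = (box - 1) / 2.0;
  NumericVector vol(box * box * (size_t)box), cov(box * box * (size_t)box);
  vol.attr("dim") = IntegerVector::create(box, box, box);
  cov.attr("dim") = IntegerVector::create(box, box, box);
  double *v = REAL(vol), *cv = REAL(cov);
  const double *im = REAL(images);
  for (int m = 0; m < nimg; ++m) {
    const double *R = &Rmats(0, m);
    const double *img = im + (size_t)nx * ny * m;
    double wgt = weights[m];
    for (int z = 0; z < box; ++z) {
      double dz = z - c;
      for (int y = 0; y < box; ++y) {
        double dy = y - c;
        for (int x = 0; x < box; ++x) {
          double dx = x - c;
          double q1 = R[0] * dx + R[3] * dy + R[6] * dz + c;
          double q2 = R[1] * dx + R[4] * dy + R[7] * dz + c;
          if (q1 >= 0 && q2 >= 0 && q1 <= nx - 1 && q2 <= ny - 1) {
            size_t idx = x + box * (y + (size_t)box * z);
            v[idx] += wgt * bi_sample(img, nx, ny, q1, q2);
            cv[idx] += wgt;
          }
        }
      }
    }
  }
  return List::create(Named("volume") = vol, Named("coverage") = cov);
}

// Rotate every image of a stack in-plane by `angle_deg` (counterclockwise,
// about the image centre).
// [[Rcpp::export]]
NumericVector cpp_rotate_stack(NumericVector images, double angle_deg) {
  IntegerVector dm = images.attr("dim");
  int nx = dm[0], ny = dm[1], nimg = dm[2];
  double c = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  double a = angle_deg * M_PI / 180.0;
  double ca = std::cos(a), sa = std::sin(a);
  NumericVector out(images.size());
  out.attr("dim") = dm;
  const double *im = REAL(images);
  double *o = REAL(out);
  for (int m = 0; m < nimg; ++m) {
    const double *img = im + (size_t)nx * ny * m;
    double *dst = o + (size_t)nx * ny * m;
    for (int y = 0; y < ny; ++y) {
      double dy = y - cy;
      for (int x = 0; x < nx; ++x) {
        double dx = x - c;
        double sx =  ca * dx + sa * dy + c;
        double sy = -sa * dx + ca * dy + cy;
        dst[x + nx * y] = bi_sample(img, nx, ny, sx, sy);
      }
    }
  }
  return out;
}

// Masked NCC between a reference and a volume over a list of integer
// shifts. mask_xyz: 0-based voxel coordinates (n x 3) of mask voxels;
// refvals: reference density at those voxels; shifts: k x 3 integers.
// The volume is sampled at mask + shift (out of bounds -> 0).
// [[Rcpp::export]]
NumericVector cpp_masked_ncc_shifts(NumericVector vol, IntegerMatrix mask_xyz,
                                    NumericVector refvals, IntegerMatrix shifts) {
  IntegerVector dm = vol.attr("dim");
  int nx = dm[0], ny = dm[1], nz = dm[2];
  const double *v = REAL(vol);
  int n = mask_xyz.nrow(), k = shifts.nrow();
  double rmean = 0;
  for (int i = 0; i < n; ++i) rmean += refvals[i];
  rmean /= n;
  double rss = 0;
  for (int i = 0; i < n; ++i) rss += (refvals[i] - rmean) * (refvals[i] - rmean);
  NumericVector out(k);
  std::vector<double> buf(n);
  for (int s = 0; s < k; ++s) {
    int sx = shifts(s, 0), sy = shifts(s, 1), sz = shifts(s, 2);
    double m = 0;
    for (int i = 0; i < n; ++i) {
      int x = mask_xyz(i, 0) + sx, y = mask_xyz(i, 1) + sy, z = mask_xyz(i, 2) + sz;
      double val = 0;
      if (x >= 0 && y >= 0 && z >= 0 && x < nx && y < ny && z < nz)
        val = v[x + nx * (y + (size_t)ny * z)];
      buf[i] = val;
      m += val;
    }
    m /= n;
    double num = 0, vss = 0;
    for (int i = 0; i < n; ++i) {
      double dv = buf[i] - m;
      num += (refvals[i] - rmean) * dv;
      vss += dv * dv;
    }
    out[s] = (rss > 0 && vss > 0) ? num / std::sqrt(rss * vss) : 0.0;
  }
  return out;
}
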