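// Cone-beam projector core.
//
// Geometry convention (shared with the R layer): right-handed world frame
// with origin at the isocenter, z along the animal (craniocaudal) axis,
// gantry rotating in the x-y plane, angle measured CCW from +x.  At angle
// theta the source sits at SID*(cos t, sin t, 0); the flat detector is
// centered at -(SDD-SID)*(cos t, sin t, 0) with in-plane axis
// u = (-sin t, cos t, 0) and axial axis v = (0, 0, 1).  Volumes are
// cell-centered: world = origin + (index + 0.5) * voxel_size.
//
// Rays are integrated by trilinear sampling at a fixed nominal step of half
// a voxel, each sample scaled by the actual step length.  The adjoint
// scatters the same trilinear weights along the same sample positions, so
// forward and backprojection form a matched transpose pair by construction.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Grid {
  int nx, ny, nz;
  double vox;
  double ox, oy, oz;  // corner of the grid (not first cell center)
};

struct Ray {
  double sx, sy, sz;  // source
  double dx, dy, dz;  // unit direction
  double t0, t1;      // param range intersecting the grid AABB
};

// Slab intersection of the ray with the grid bounding box.
inline bool clip_ray(const Grid &g, Ray &r) {
  double t0 = 0.0, t1 = 1e300;
  const double lo[3] = {g.ox, g.oy, g.oz};
  const double hi[3] = {g.ox + g.nx * g.vox, g.oy + g.ny * g.vox,
                        g.oz + g.nz * g.vox};
  const double s[3] = {r.sx, r.sy, r.sz};
  const double d[3] = {r.dx, r.dy, r.dz};
  for (int k = 0; k < 3; ++k) {
    if (std::fabs(d[k]) < 1e-12) {
      if (s[k] <= lo[k] || s[k] >= hi[k]) return false;
    } else {
      double inv = 1.0 / d[k];
      double ta = (lo[k] - s[k]) * inv;
      double tb = (hi[k] - s[k]) * inv;
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
    }
  }
  if (t1 <= t0) return false;
  r.t0 = t0;
  r.t1 = t1;
  return true;
}

// Trilinear gather at world position p; cells outside the grid contribute 0.
// Interior samples (all 8 neighbors in bounds, the common case) take an
// unchecked fused path.
inline double sample_trilinear(const double *vol, const Grid &g, double px,
                               double py, double pz) {
  double inv = 1.0 / g.vox;
  double gx = (px - g.ox) * inv - 0.5;
  double gy = (py - g.oy) * inv - 0.5;
  double gz = (pz - g.oz) * inv - 0.5;
  int ix = (int)std::floor(gx), iy = (int)std::floor(gy),
      iz = (int)std::floor(gz);
  double fx = gx - ix, fy = gy - iy, fz = gz - iz;
  if (ix >= 0 && ix + 1 < g.nx && iy >= 0 && iy + 1 < g.ny && iz >= 0 &&
      iz + 1 < g.nz) {
    const size_t nx = g.nx, nxny = (size_t)g.nx * g.ny;
    const double *p = vol + ix + nx * iy + nxny * iz;
    double c00 = p[0] + fx * (p[1] - p[0]);
    double c10 = p[nx] + fx * (p[nx + 1] - p[nx]);
    double c01 = p[nxny] + fx * (p[nxny + 1] - p[nxny]);
    double c11 = p[nxny + nx] + fx * (p[nxny + nx + 1] - p[nxny + nx]);
    double c0 = c00 + fy * (c10 - c00);
    double c1 = c01 + fy * (c11 - c01);
    return c0 + fz * (c1 - c0);
  }
  double acc = 0.0;
  for (int c = 0; c < 8; ++c) {
    int jx = ix + (c & 1), jy = iy + ((c >> 1) & 1), jz = iz + ((c >> 2) & 1);
    if (jx < 0 || jx >= g.nx || jy < 0 || jy >= g.ny || jz < 0 || jz >= g.nz)
      continue;
    double w = ((c & 1) ? fx : 1.0 - fx) * (((c >> 1) & 1) ? fy : 1.0 - fy) *
               (((c >> 2) & 1) ? fz : 1.0 - fz);
    acc += w * vol[jx + (size_t)g.nx * (jy + (size_t)g.ny * jz)];
  }
  return acc;
}

// Trilinear scatter: exact transpose of sample_trilinear.
inline void scatter_trilinear(double *vol, const Grid &g, double px, double py,
                              double pz, double val) {
  double inv = 1.0 / g.vox;
  double gx = (px - g.ox) * inv - 0.5;
  double gy = (py - g.oy) * inv - 0.5;
  double gz = (pz - g.oz) * inv - 0.5;
  int ix = (int)std::floor(gx), iy = (int)std::floor(gy),
      iz = (int)std::floor(gz);
  double fx = gx - ix, fy = gy - iy, fz = gz - iz;
  if (ix >= 0 && ix + 1 < g.nx && iy >= 0 && iy + 1 < g.ny && iz >= 0 &&
      iz + 1 < g.nz) {
    const size_t nx = g.nx, nxny = (size_t)g.nx * g.ny;
    double *p = vol + ix + nx * iy + nxny * iz;
    double wx0 = 1.0 - fx, wy0 = 1.0 - fy, wz0 = 1.0 - fz;
    double v0 = val * wz0, v1 = val * fz;
    p[0] += wx0 * wy0 * v0;
    p[1] += fx * wy0 * v0;
    p[nx] += wx0 * fy * v0;
    p[nx + 1] += fx * fy * v0;
    p[nxny] += wx0 * wy0 * v1;
    p[nxny + 1] += fx * wy0 * v1;
    p[nxny + nx] += wx0 * fy * v1;
    p[nxny + nx + 1] += fx * fy * v1;
    return;
  }
  for (int c = 0; c < 8; ++c) {
    int jx = ix + (c & 1), jy = iy + ((c >> 1) & 1), jz = iz + ((c >> 2) & 1);
    if (jx < 0 || jx >= g.nx || jy < 0 || jy >= g.ny || jz < 0 || jz >= g.nz)
      continue;
    double w = ((c & 1) ? fx : 1.0 - fx) * (((c >> 1) & 1) ? fy : 1.0 - fy) *
               (((c >> 2) & 1) ? fz : 1.0 - fz);
    vol[jx + (size_t)g.nx * (jy + (size_t)g.ny * jz)] += w * val;
  }
}

struct Detector {
  double sid, sdd, pitch, off_u, off_v;
  int nu, nv;
};

// Build the ray for detector pixel (iu, iv) at gantry angle theta (radians).
inline Ray pixel_ray(const Detector &det, double ct, double st, int iu,
                     int iv) {
  Ray r;
  r.sx = det.sid * ct;
  r.sy = det.sid * st;
  r.sz = 0.0;
  double du = (iu - 0.5 * (det.nu - 1)) * det.pitch + det.off_u;
  double dv = (iv - 0.5 * (det.nv - 1)) * det.pitch + det.off_v;
  // detector center + du * u_hat + dv * v_hat
  double px = -(det.sdd - det.sid) * ct - du * st;
  double py = -(det.sdd - det.sid) * st + du * ct;
  double pz = dv;
  double dx = px - r.sx, dy = py - r.sy, dz = pz - r.sz;
  double n = std::sqrt(dx * dx + dy * dy + dz * dz);
  r.dx = dx / n;
  r.dy = dy / n;
  r.dz = dz / n;
  return r;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_forward_project")]]
NumericVector cpp_forward_project(NumericVector vol, IntegerVector dims,
                                  double voxel, NumericVector origin,
                                  NumericVector angles_rad, double sid,
                                  double sdd, int nu, int nv, double pitch,
                                  double off_u, double off_v,
                                  double step_frac) {
  Grid g{dims[0], dims[1], dims[2], voxel, origin[0], origin[1], origin[2]};
  Detector det{sid, sdd, pitch, off_u, off_v, nu, nv};
  const int na = angles_rad.size();
  NumericVector out((size_t)nu * nv * na);
  const double *v = vol.begin();
  double *o = out.begin();
  const double step = step_frac * voxel;
  for (int a = 0; a < na; ++a) {
    double ct = std::cos(angles_rad[a]), st = std::sin(angles_rad[a]);
    for (int iv = 0; iv < nv; ++iv) {
      for (int iu = 0; iu < nu; ++iu) {
        Ray r = pixel_ray(det, ct, st, iu, iv);
        double val = 0.0;
        if (clip_ray(g, r)) {
          double len = r.t1 - r.t0;
          int n = (int)std::ceil(len / step);
          if (n < 1) n = 1;
          double ds = len / n;
          double acc = 0.0;
          for (int k = 0; k < n; ++k) {
            double t = r.t0 + (k + 0.5) * ds;
            acc += sample_trilinear(v, g, r.sx + t * r.dx, r.sy + t * r.dy,
                                    r.sz + t * r.dz);
          }
          val = acc * ds;
        }
        o[iu + (size_t)nu * (iv + (size_t)nv * a)] = val;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nu, nv, na);
  return out;
}

// [[Rcpp::export(name = ".cpp_backproject")]]
NumericVector cpp_backproject(NumericVector frames, IntegerVector dims,
                              double voxel, NumericVector origin,
                              NumericVector angles_rad, double sid, double sdd,
                              int nu, int nv, double pitch, double off_u,
                              double off_v, double step_frac) {
  Grid g{dims[0], dims[1], dims[2], voxel, origin[0], origin[1], origin[2]};
  Detector det{sid, sdd, pitch, off_u, off_v, nu, nv};
  const int na = angles_rad.size();
  NumericVector out((size_t)g.nx * g.ny * g.nz);
  double *v = out.begin();
  const double *f = frames.begin();
  const double step = step_frac * voxel;
  for (int a = 0; a < na; ++a) {
    double ct = std::cos(angles_rad[a]), st = std::sin(angles_rad[a]);
    for (int iv = 0; iv < nv; ++iv) {
      for (int iu = 0; iu < nu; ++iu) {
        double val = f[iu + (size_t)nu * (iv + (size_t)nv * a)];
        if (val == 0.0) continue;
        Ray r = pixel_ray(det, ct, st, iu, iv);
        if (!clip_ray(g, r)) continue;
        double len = r.t1 - r.t0;
        int n = (int)std::ceil(len / step);
        if (n < 1) n = 1;
        double ds = len / n;
        double w = val * ds;
        for (int k = 0; k < n; ++k) {
          double t = r.t0 + (k + 0.5) * ds;
          scatter_trilinear(v, g, r.sx + t * r.dx, r.sy + t * r.dy,
                            r.sz + t * r.dz, w);
        }
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// Rasterize the parametric multi-mouse phantom into an HU grid.
//
// mice: one row per mouse with columns
//   cx cy cz  body semi-axes (ax ay az)  hu_body
//   inner semi-axes (bx by bz)  hu_lung  hu_liver  diaphragm_z  disp
// tumors: one row per tumor: mouse_index(0-based) cx cy cz radius hu
// bed: (cy, cz, radius, hu, enabled) — cylinder along x.
// [[Rcpp::export(name = ".cpp_rasterize_phantom")]]
NumericVector cpp_rasterize_phantom(IntegerVector dims, double voxel,
                                    NumericVector origin, NumericMatrix mice,
                                    NumericMatrix tumors, NumericVector bed,
                                    double hu_air) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((size_t)nx * ny * nz, hu_air);
  double *v = out.begin();
  const double ox = origin[0], oy = origin[1], oz = origin[2];

  // Bed cylinder along the x (bed row) axis.
  if (bed.size() >= 5 && bed[4] > 0.5) {
    const double bcy = bed[0], bcz = bed[1], br = bed[2], bhu = bed[3];
    for (int k = 0; k < nz; ++k) {
      double z = oz + (k + 0.5) * voxel - bcz;
      for (int j = 0; j < ny; ++j) {
        double y = oy + (j + 0.5) * voxel - bcy;
        if (y * y + z * z > br * br) continue;
        double *row = v + (size_t)nx * (j + (size_t)ny * k);
        for (int i = 0; i < nx; ++i) row[i] = bhu;
      }
    }
  }

  const int nm = mice.nrow();
  for (int m = 0; m < nm; ++m) {
    const double cx = mice(m, 0), cy = mice(m, 1), cz = mice(m, 2);
    const double ax = mice(m, 3), ay = mice(m, 4), az = mice(m, 5);
    const double hu_body = mice(m, 6);
    const double bx = mice(m, 7), by = mice(m, 8), bz = mice(m, 9);
    const double hu_lung = mice(m, 10), hu_liver = mice(m, 11);
    const double dia_z = mice(m, 12) - mice(m, 13);  // rest - caudal disp

    int i0 = std::max(0, (int)std::floor((cx - ax - ox) / voxel - 1));
    int i1 = std::min(nx - 1, (int)std::ceil((cx + ax - ox) / voxel + 1));
    int j0 = std::max(0, (int)std::floor((cy - ay - oy) / voxel - 1));
    int j1 = std::min(ny - 1, (int)std::ceil((cy + ay - oy) / voxel + 1));
    int k0 = std::max(0, (int)std::floor((cz - az - oz) / voxel - 1));
    int k1 = std::min(nz - 1, (int)std::ceil((cz + az - oz) / voxel + 1));

    for (int k = k0; k <= k1; ++k) {
      double z = oz + (k + 0.5) * voxel;
      double ez = (z - cz) / az, iz2 = (z - cz) / bz;
      for (int j = j0; j <= j1; ++j) {
        double y = oy + (j + 0.5) * voxel;
        double ey = (y - cy) / ay, iy2 = (y - cy) / by;
        for (int i = i0; i <= i1; ++i) {
          double x = ox + (i + 0.5) * voxel;
          double ex = (x - cx) / ax, ix2 = (x - cx) / bx;
          if (ex * ex + ey * ey + ez * ez > 1.0) continue;
          size_t idx = i + (size_t)nx * (j + (size_t)ny * k);
          if (ix2 * ix2 + iy2 * iy2 + iz2 * iz2 <= 1.0)
            v[idx] = (z > dia_z) ? hu_lung : hu_liver;
          else
            v[idx] = hu_body;
        }
      }
    }
  }

  // Tumors ride with the liver: centers shifted caudally by the mouse's
  // displacement, clipped to the liver region (inner ellipsoid, z <= dia).
  const int nt = tumors.nrow();
  for (int t = 0; t < nt; ++t) {
    int m = (int)tumors(t, 0);
    if (m < 0 || m >= nm) continue;
    const double disp = mice(m, 13);
    const double tcx = tumors(t, 1), tcy = tumors(t, 2),
                 tcz = tumors(t, 3) - disp;
    const double tr = tumors(t, 4), thu = tumors(t, 5);
    const double cx = mice(m, 0), cy = mice(m, 1), cz = mice(m, 2);
    const double bx = mice(m, 7), by = mice(m, 8), bz = mice(m, 9);
    const double dia_z = mice(m, 12) - disp;

    int i0 = std::max(0, (int)std::floor((tcx - tr - ox) / voxel - 1));
    int i1 = std::min(nx - 1, (int)std::ceil((tcx + tr - ox) / voxel + 1));
    int j0 = std::max(0, (int)std::floor((tcy - tr - oy) / voxel - 1));
    int j1 = std::min(ny - 1, (int)std::ceil((tcy + tr - oy) / voxel + 1));
    int k0 = std::max(0, (int)std::floor((tcz - tr - oz) / voxel - 1));
    int k1 = std::min(nz - 1, (int)std::ceil((tcz + tr - oz) / voxel + 1));

    for (int k = k0; k <= k1; ++k) {
      double z = oz + (k + 0.5) * voxel;
      if (z > dia_z) continue;
      double dz = z - tcz, iz2 = (z - cz) / bz;
      for (int j = j0; j <= j1; ++j) {
        double y = oy + (j + 0.5) * voxel;
        double dy = y - tcy, iy2 = (y - cy) / by;
        for (int i = i0; i <= i1; ++i) {
          double x = ox + (i + 0.5) * voxel;
          double dx = x - tcx, ix2 = (x - cx) / bx;
          if (dx * dx + dy * dy + dz * dz > tr * tr) continue;
          if (ix2 * ix2 + iy2 * iy2 + iz2 * iz2 > 1.0) continue;
          v[i + (size_t)nx * (j + (size_t)ny * k)] = thu;
        }
      }
    }
  }

  out.attr("dim") = dims;
  return out;
}
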