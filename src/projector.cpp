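#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Fan-beam geometry conventions shared by all routines:
//  - image is an R matrix (nr x nc, column-major); row i (0-based) has
//    y = -nr*dx/2 + (i+0.5)*dx, column j has x = -nc*dx/2 + (j+0.5)*dx,
//    so rows index y from the bottom and the isocenter is the grid center;
//  - the source for view angle beta sits at sad*(cos beta, sin beta);
//  - detector bins lie on an equiangular arc centered on the source; bin k
//    (0-based) views the ray at angle gamma_k = (k-(nb-1)/2)*dgamma from the
//    central ray, with dgamma = bin_width / sdd.

struct RayHit {
  std::vector<int> pix;     // 0-based column-major pixel index
  std::vector<double> len;  // intersection length (cm)
};

// Exact Siddon traversal of one ray through the pixel grid.
static void siddon_ray(double sx, double sy, double dxr, double dyr,
                       int nr, int nc, double dx, RayHit &hit) {
  hit.pix.clear();
  hit.len.clear();
  const double xmin = -0.5 * nc * dx, xmax = 0.5 * nc * dx;
  const double ymin = -0.5 * nr * dx, ymax = 0.5 * nr * dx;
  const double eps = 1e-12;

  // parametric entry/exit of the bounding box (slab method)
  double t0 = 0.0, t1 = std::numeric_limits<double>::infinity();
  if (std::fabs(dxr) < eps) {
    if (sx <= xmin || sx >= xmax) return;
  } else {
    double ta = (xmin - sx) / dxr, tb = (xmax - sx) / dxr;
    if (ta > tb) std::swap(ta, tb);
    t0 = std::max(t0, ta);
    t1 = std::min(t1, tb);
  }
  if (std::fabs(dyr) < eps) {
    if (sy <= ymin || sy >= ymax) return;
  } else {
    double ta = (ymin - sy) / dyr, tb = (ymax - sy) / dyr;
    if (ta > tb) std::swap(ta, tb);
    t0 = std::max(t0, ta);
    t1 = std::min(t1, tb);
  }
  if (t0 >= t1) return;

  // start just inside the box
  double t = t0;
  double px = sx + (t + eps) * dxr, py = sy + (t + eps) * dyr;
  int ix = (int)std::floor((px - xmin) / dx);
  int iy = (int)std::floor((py - ymin) / dx);
  if (ix < 0) ix = 0; if (ix > nc - 1) ix = nc - 1;
  if (iy < 0) iy = 0; if (iy > nr - 1) iy = nr - 1;

  int stepx = (dxr > eps) ? 1 : ((dxr < -eps) ? -1 : 0);
  int stepy = (dyr > eps) ? 1 : ((dyr < -eps) ? -1 : 0);
  const double inf = std::numeric_limits<double>::infinity();
  double tMaxX = inf, tMaxY = inf, tDeltaX = inf, tDeltaY = inf;
  if (stepx != 0) {
    double bx = xmin + (ix + (stepx > 0 ? 1 : 0)) * dx;
    tMaxX = (bx - sx) / dxr;
    tDeltaX = dx / std::fabs(dxr);
  }
  if (stepy != 0) {
    double by = ymin + (iy + (stepy > 0 ? 1 : 0)) * dx;
    tMaxY = (by - sy) / dyr;
    tDeltaY = dx / std::fabs(dyr);
  }

  while (t < t1 - eps) {
    double tnext = std::min(std::min(tMaxX, tMaxY), t1);
    double seg = tnext - t;
    if (seg > eps) {
      hit.pix.push_back(iy + ix * nr);
      hit.len.push_back(seg);
    }
    t = tnext;
    if (tnext >= t1 - eps) break;
    if (tMaxX <= tMaxY) { ix += stepx; tMaxX += tDeltaX; }
    else                { iy += stepy; tMaxY += tDeltaY; }
    if (ix < 0 || ix >= nc || iy < 0 || iy >= nr) break;
  }
}

// [[Rcpp::export]]
List cpp_siddon_triplets(int nr, int nc, double dx, double sad, double sdd,
                         int nb, double dgamma, NumericVector angles) {
  const int nv = angles.size();
  std::vector<int> ri, ci;
  std::vector<double> xv;
  ri.reserve((size_t)nv * nb * 8);
  ci.reserve((size_t)nv * nb * 8);
  xv.reserve((size_t)nv * nb * 8);
  RayHit hit;
  for (int v = 0; v < nv; ++v) {
    const double beta = angles[v];
    const double sx = sad * std::cos(beta), sy = sad * std::sin(beta);
    for (int k = 0; k < nb; ++k) {
      const double gamma = (k - 0.5 * (nb - 1)) * dgamma;
      const double phi = beta + M_PI + gamma;
      siddon_ray(sx, sy, std::cos(phi), std::sin(phi), nr, nc, dx, hit);
      const int row = v * nb + k;
      for (size_t m = 0; m < hit.pix.size(); ++m) {
        ri.push_back(row);
        ci.push_back(hit.pix[m]);
        xv.push_back(hit.len[m]);
      }
    }
  }
  return List::create(_["i"] = wrap(ri), _["j"] = wrap(ci), _["x"] = wrap(xv));
}

// Matrix-free forward projection of K stacked images (M x K, column-major
// flattened with the same pixel convention). Returns (nv*nb) x K line
// integrals, view-major row order.
// [[Rcpp::export]]
NumericMatrix cpp_siddon_project(NumericMatrix images, int nr, int nc,
                                 double dx, double sad, double sdd, int nb,
                                 double dgamma, NumericVector angles) {
  const int nv = angles.size();
  const int K = images.ncol();
  if (images.nrow() != nr * nc) stop("image stack has wrong number of pixels");
  NumericMatrix out(nv * nb, K);
  RayHit hit;
  for (int v = 0; v < nv; ++v) {
    const double beta = angles[v];
    const double sx = sad * std::cos(beta), sy = sad * std::sin(beta);
    for (int k = 0; k < nb; ++k) {
      const double gamma = (k - 0.5 * (nb - 1)) * dgamma;
      const double phi = beta + M_PI + gamma;
      siddon_ray(sx, sy, std::cos(phi), std::sin(phi), nr, nc, dx, hit);
      const int row = v * nb + k;
      for (int q = 0; q < K; ++q) {
        double acc = 0.0;
        const double *img = &images(0, q);
        for (size_t m = 0; m < hit.pix.size(); ++m)
          acc += img[hit.pix[m]] * hit.len[m];
        out(row, q) = acc;
      }
    }
  }
  return out;
}

// Pixel-driven weighted backprojection for equiangular fan-beam FBP.
// qf: filtered, cosine-weighted sinogram (nv x nb). Accumulates
// dbeta * sum_v qf(v, gamma'(x,y)) / L(x,y)^2 with linear interpolation
// across detector bins; L is the source-to-pixel distance.
// [[Rcpp::export]]
NumericMatrix cpp_fan_backproject(NumericMatrix qf, NumericVector angles,
                                  int nr, int nc, double dx, double sad,
                                  double dgamma, double dbeta) {
  const int nv = angles.size();
  const int nb = qf.ncol();
  NumericMatrix img(nr, nc);
  const double x0 = -0.5 * nc * dx + 0.5 * dx;
  const double y0 = -0.5 * nr * dx + 0.5 * dx;
  for (int v = 0; v < nv; ++v) {
    const double beta = angles[v];
    const double sx = sad * std::cos(beta), sy = sad * std::sin(beta);
    const double d0x = -std::cos(beta), d0y = -std::sin(beta);
    const double *qv = &qf(v, 0);
    for (int j = 0; j < nc; ++j) {
      const double x = x0 + j * dx;
      for (int i = 0; i < nr; ++i) {
        const double y = y0 + i * dx;
        const double vx = x - sx, vy = y - sy;
        const double L2 = vx * vx + vy * vy;
        const double gamma = std::atan2(d0x * vy - d0y * vx, d0x * vx + d0y * vy);
        const double tpos = gamma / dgamma + 0.5 * (nb - 1);
        const int k0 = (int)std::floor(tpos);
        if (k0 < 0 || k0 >= nb - 1) continue;
        const double w = tpos - k0;
        const double qval = (1.0 - w) * qv[(size_t)k0 * nv] +
                            w * qv[(size_t)(k0 + 1) * nv];
        img(i, j) += dbeta * qval / L2;
      }
    }
  }
  return img;
}
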