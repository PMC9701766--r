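#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Rasterize the union footprint of a set of 2D triangles onto a pixel grid.
// tri: n x 6 matrix (x1,y1,x2,y2,x3,y3) in continuous pixel units where pixel
// centers sit at integer coordinates 1..nx, 1..ny. Returns an nx x ny 0/1
// matrix indexed [ix, iy] (x fastest), suitable for contourLines(x, y, z).
// [[Rcpp::export]]
IntegerMatrix cpp_fill_triangles(NumericMatrix tri, int nx, int ny) {
  IntegerMatrix out(nx, ny);
  const double eps = 1e-9;
  for (int k = 0; k < tri.nrow(); ++k) {
    double x1 = tri(k, 0), y1 = tri(k, 1);
    double x2 = tri(k, 2), y2 = tri(k, 3);
    double x3 = tri(k, 4), y3 = tri(k, 5);
    double det = (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1);
    if (std::fabs(det) < 1e-12) continue;
    int ix0 = std::max(1, (int)std::ceil(std::min(std::min(x1, x2), x3) - eps));
    int ix1 = std::min(nx, (int)std::floor(std::max(std::max(x1, x2), x3) + eps));
    int iy0 = std::max(1, (int)std::ceil(std::min(std::min(y1, y2), y3) - eps));
    int iy1 = std::min(ny, (int)std::floor(std::max(std::max(y1, y2), y3) + eps));
    for (int iy = iy0; iy <= iy1; ++iy) {
      for (int ix = ix0; ix <= ix1; ++ix) {
        double px = ix, py = iy;
        double a = ((x2 - px) * (y3 - py) - (x3 - px) * (y2 - py)) / det;
        double b = ((x3 - px) * (y1 - py) - (x1 - px) * (y3 - py)) / det;
        double c = 1.0 - a - b;
        if (a >= -1e-9 && b >= -1e-9 && c >= -1e-9) out(ix - 1, iy - 1) = 1;
      }
    }
  }
  return out;
}

static inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// Squared distance from point p to triangle (a,b,c); Ericson's closest-point
// region decomposition.
static double pt_tri_sqdist(const double *p, const double *a, const double *b,
                            const double *c) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  double cx = p[0], cy = p[1], cz = p[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    cx = a[0]; cy = a[1]; cz = a[2];
  } else {
    double bp[3];
    for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
    double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
    double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
    if (d3 >= 0.0 && d4 <= d3) {
      cx = b[0]; cy = b[1]; cz = b[2];
    } else {
      double vc = d1 * d4 - d3 * d2;
      if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
        double v = d1 / (d1 - d3);
        cx = a[0] + v * ab[0]; cy = a[1] + v * ab[1]; cz = a[2] + v * ab[2];
      } else {
        double cp[3];
        for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
        double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
        double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
        if (d6 >= 0.0 && d5 <= d6) {
          cx = c[0]; cy = c[1]; cz = c[2];
        } else {
          double vb = d5 * d2 - d1 * d6;
          if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
            double w = d2 / (d2 - d6);
            cx = a[0] + w * ac[0]; cy = a[1] + w * ac[1]; cz = a[2] + w * ac[2];
          } else {
            double va = d3 * d6 - d5 * d4;
            if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
              double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
              cx = b[0] + w * (c[0] - b[0]);
              cy = b[1] + w * (c[1] - b[1]);
              cz = b[2] + w * (c[2] - b[2]);
            } else {
              double denom = 1.0 / (va + vb + vc);
              double v = clamp01(vb * denom), w = clamp01(vc * denom);
              cx = a[0] + ab[0] * v + ac[0] * w;
              cy = a[1] + ab[1] * v + ac[1] * w;
              cz = a[2] + ab[2] * v + ac[2] * w;
            }
          }
        }
      }
    }
  }
  double dx = p[0] - cx, dy = p[1] - cy, dz = p[2] - cz;
  return dx * dx + dy * dy + dz * dz;
}

// Minimum Euclidean distance from each row of P to the triangle surface
// (V, F). F is 1-based. Brute force with per-triangle bounding-box pruning.
// [[Rcpp::export]]
NumericVector cpp_point_mesh_distance(NumericMatrix P, NumericMatrix V,
                                      IntegerMatrix F) {
  int np = P.nrow(), nf = F.nrow();
  std::vector<double> lo(3 * nf), hi(3 * nf);
  std::vector<double> tv(9 * nf);
  for (int f = 0; f < nf; ++f) {
    for (int k = 0; k < 3; ++k) {
      int vi = F(f, k) - 1;
      for (int d = 0; d < 3; ++d) tv[9 * f + 3 * k + d] = V(vi, d);
    }
    for (int d = 0; d < 3; ++d) {
      double a = tv[9 * f + d], b = tv[9 * f + 3 + d], c = tv[9 * f + 6 + d];
      lo[3 * f + d] = std::min(std::min(a, b), c);
      hi[3 * f + d] = std::max(std::max(a, b), c);
    }
  }
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    double p[3] = {P(i, 0), P(i, 1), P(i, 2)};
    double best = R_PosInf;
    for (int f = 0; f < nf; ++f) {
      double bb = 0.0;
      for (int d = 0; d < 3; ++d) {
        double v = p[d];
        double l = lo[3 * f + d], h = hi[3 * f + d];
        double e = v < l ? l - v : (v > h ? v - h : 0.0);
        bb += e * e;
      }
      if (bb >= best) continue;
      double d2 = pt_tri_sqdist(p, &tv[9 * f], &tv[9 * f + 3], &tv[9 * f + 6]);
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Inside/outside test for points against a mesh made of one or more closed
// components (comp gives a 1-based component id per face). A point is inside
// if it is inside at least one component, by +z ray-crossing parity.
// [[Rcpp::export]]
LogicalVector cpp_points_in_mesh(NumericMatrix P, NumericMatrix V,
                                 IntegerMatrix F, IntegerVector comp,
                                 int ncomp) {
  int np = P.nrow(), nf = F.nrow();
  LogicalVector out(np);
  std::vector<int> parity(ncomp);
  for (int i = 0; i < np; ++i) {
    double px = P(i, 0), py = P(i, 1), pz = P(i, 2);
    std::fill(parity.begin(), parity.end(), 0);
    for (int f = 0; f < nf; ++f) {
      int i1 = F(f, 0) - 1, i2 = F(f, 1) - 1, i3 = F(f, 2) - 1;
      double x1 = V(i1, 0), y1 = V(i1, 1);
      double x2 = V(i2, 0), y2 = V(i2, 1);
      double x3 = V(i3, 0), y3 = V(i3, 1);
      double det = (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1);
      if (std::fabs(det) < 1e-14) continue;
      double a = ((x2 - px) * (y3 - py) - (x3 - px) * (y2 - py)) / det;
      double b = ((x3 - px) * (y1 - py) - (x1 - px) * (y3 - py)) / det;
      double c = 1.0 - a - b;
      if (a < 0.0 || b < 0.0 || c < 0.0) continue;
      double z = a * V(i1, 2) + b * V(i2, 2) + c * V(i3, 2);
      if (z > pz) parity[comp[f] - 1] ^= 1;
    }
    bool inside = false;
    for (int cpt = 0; cpt < ncomp; ++cpt)
      if (parity[cpt]) { inside = true; break; }
    out[i] = inside;
  }
  return out;
}

// Voxel occupancy by column sweep: for every (x, y) voxel-column center,
// collect z-crossings with each closed component's faces, then fill voxels
// whose centers fall inside an odd-parity interval of any component.
// Returns a logical vector in array order (x fastest, then y, then z).
// [[Rcpp::export]]
LogicalVector cpp_voxelize_grid(NumericMatrix V, IntegerMatrix F,
                                IntegerVector comp, int ncomp,
                                NumericVector origin, double vox,
                                IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double ox = origin[0], oy = origin[1], oz = origin[2];
  int ncol = nx * ny;
  std::vector<std::vector<double>> cross((size_t)ncol * ncomp);
  int nf = F.nrow();
  for (int f = 0; f < nf; ++f) {
    int i1 = F(f, 0) - 1, i2 = F(f, 1) - 1, i3 = F(f, 2) - 1;
    double x1 = V(i1, 0), y1 = V(i1, 1), z1 = V(i1, 2);
    double x2 = V(i2, 0), y2 = V(i2, 1), z2 = V(i2, 2);
    double x3 = V(i3, 0), y3 = V(i3, 1), z3 = V(i3, 2);
    double det = (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1);
    if (std::fabs(det) < 1e-14) continue;
    double xmin = std::min(std::min(x1, x2), x3);
    double xmax = std::max(std::max(x1, x2), x3);
    double ymin = std::min(std::min(y1, y2), y3);
    double ymax = std::max(std::max(y1, y2), y3);
    int ix0 = std::max(0, (int)std::ceil((xmin - ox) / vox));
    int ix1 = std::min(nx - 1, (int)std::floor((xmax - ox) / vox));
    int iy0 = std::max(0, (int)std::ceil((ymin - oy) / vox));
    int iy1 = std::min(ny - 1, (int)std::floor((ymax - oy) / vox));
    int cidx = comp[f] - 1;
    for (int iy = iy0; iy <= iy1; ++iy) {
      double py = oy + iy * vox;
      for (int ix = ix0; ix <= ix1; ++ix) {
        double px = ox + ix * vox;
        double a = ((x2 - px) * (y3 - py) - (x3 - px) * (y2 - py)) / det;
        double b = ((x3 - px) * (y1 - py) - (x1 - px) * (y3 - py)) / det;
        double c = 1.0 - a - b;
        if (a < 0.0 || b < 0.0 || c < 0.0) continue;
        double z = a * z1 + b * z2 + c * z3;
        cross[(size_t)(iy * nx + ix) * ncomp + cidx].push_back(z);
      }
    }
  }
  LogicalVector out((R_xlen_t)nx * ny * nz);
  for (int iy = 0; iy < ny; ++iy) {
    for (int ix = 0; ix < nx; ++ix) {
      for (int cpt = 0; cpt < ncomp; ++cpt) {
        std::vector<double> &zs = cross[(size_t)(iy * nx + ix) * ncomp + cpt];
        if (zs.size() < 2) continue;
        std::sort(zs.begin(), zs.end());
        size_t npair = zs.size() / 2;
        for (size_t p = 0; p < npair; ++p) {
          double z0 = zs[2 * p], z1v = zs[2 * p + 1];
          int iz0 = (int)std::ceil((z0 - oz) / vox - 1e-9);
          int iz1 = (int)std::floor((z1v - oz) / vox + 1e-9);
          if (iz0 < 0) iz0 = 0;
          if (iz1 > nz - 1) iz1 = nz - 1;
          for (int iz = iz0; iz <= iz1; ++iz)
            out[(R_xlen_t)iz * nx * ny + (R_xlen_t)iy * nx + ix] = true;
        }
      }
    }
  }
  return out;
}

// For each row of A (2D), index (1-based) and distance of the nearest row of B.
// [[Rcpp::export]]
List cpp_nn2d(NumericMatrix A, NumericMatrix B) {
  int na = A.nrow(), nb = B.nrow();
  IntegerVector idx(na);
  NumericVector dist(na);
  for (int i = 0; i < na; ++i) {
    double ax = A(i, 0), ay = A(i, 1);
    double best = R_PosInf;
    int bj = 0;
    for (int j = 0; j < nb; ++j) {
      double dx = B(j, 0) - ax, dy = B(j, 1) - ay;
      double d2 = dx * dx + dy * dy;
      if (d2 < best) { best = d2; bj = j; }
    }
    idx[i] = bj + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}
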