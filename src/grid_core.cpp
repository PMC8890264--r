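#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <array>
#include <algorithm>
using namespace Rcpp;

// Density grids are stored as R arrays of dim (nch, np, np, np): channel is
// the fastest-varying index. Linear index = ch + nch*(ix + np*(iy + np*iz)).
// Grid point (ix,iy,iz) sits at origin + (ix,iy,iz)*res.

struct GridGeom {
  double ox, oy, oz, res;
  int np, nch;
  double radius, cut; // kernel radius and absolute cutoff distance
  double r2inv;       // 1/r^2
};

static inline double kernel_val(double d2, const GridGeom &g) {
  return std::exp(-2.0 * d2 * g.r2inv);
}

// Accumulate sign * atom densities into grid (modified in place). Returns
// the induced change in sum(grid^2), so callers can track an L2 loss
// incrementally: updating a voxel from v to v + d changes the sum by
// 2 v d + d^2.
static double splat(std::vector<double> &grid, const GridGeom &g,
                    const double *coords, const double *types, int natoms,
                    double sign) {
  double dloss = 0.0;
  const double cut2 = g.cut * g.cut;
  for (int a = 0; a < natoms; ++a) {
    const double x = coords[a], y = coords[a + natoms], z = coords[a + 2 * natoms];
    int lo[3], hi[3];
    const double c[3] = {x, y, z}, org[3] = {g.ox, g.oy, g.oz};
    bool outside = false;
    for (int ax = 0; ax < 3; ++ax) {
      lo[ax] = (int)std::ceil((c[ax] - g.cut - org[ax]) / g.res);
      hi[ax] = (int)std::floor((c[ax] + g.cut - org[ax]) / g.res);
      if (lo[ax] < 0) lo[ax] = 0;
      if (hi[ax] > g.np - 1) hi[ax] = g.np - 1;
      if (lo[ax] > hi[ax]) outside = true;
    }
    if (outside) continue;
    for (int iz = lo[2]; iz <= hi[2]; ++iz) {
      const double dz = g.oz + iz * g.res - z, dz2 = dz * dz;
      for (int iy = lo[1]; iy <= hi[1]; ++iy) {
        const double dy = g.oy + iy * g.res - y, dyz2 = dy * dy + dz2;
        if (dyz2 > cut2) continue;
        for (int ix = lo[0]; ix <= hi[0]; ++ix) {
          const double dx = g.ox + ix * g.res - x, d2 = dx * dx + dyz2;
          if (d2 > cut2) continue;
          const double k = sign * kernel_val(d2, g);
          double *cell = grid.data() + (size_t)g.nch * (ix + (size_t)g.np * (iy + (size_t)g.np * iz));
          for (int ch = 0; ch < g.nch; ++ch) {
            const double t = types[a + (size_t)natoms * ch];
            if (t != 0.0) {
              const double d = t * k;
              dloss += (2.0 * cell[ch] + d) * d;
              cell[ch] += d;
            }
          }
        }
      }
    }
  }
  return dloss;
}

static GridGeom make_geom(NumericVector origin, double res, int np, int nch,
                          double radius, double cutoff_mult) {
  GridGeom g;
  g.ox = origin[0]; g.oy = origin[1]; g.oz = origin[2];
  g.res = res; g.np = np; g.nch = nch;
  g.radius = radius; g.cut = cutoff_mult * radius;
  g.r2inv = 1.0 / (radius * radius);
  return g;
}

// [[Rcpp::export]]
NumericVector cpp_density(NumericMatrix coords, NumericMatrix types,
                          NumericVector origin, double res, int np, int nch,
                          double radius, double cutoff_mult) {
  GridGeom g = make_geom(origin, res, np, nch, radius, cutoff_mult);
  std::vector<double> grid((size_t)nch * np * np * np, 0.0);
  splat(grid, g, coords.begin(), types.begin(), coords.nrow(), 1.0);
  NumericVector out(grid.begin(), grid.end());
  out.attr("dim") = IntegerVector::create(nch, np, np, np);
  return out;
}

// Gradient of sum((model - ref)^2) w.r.t. atom coordinates, given the
// residual grid (model - ref). dL/dx_a = sum_{c,p} 2 resid t_ac dk/dx_a,
// with dk/dx_a = -4/r^2 (x_a - p) k(d).
static void l2_grad(const std::vector<double> &resid, const GridGeom &g,
                    const double *coords, const double *types, int natoms,
                    double *grad /* natoms x 3, column-major */) {
  const double cut2 = g.cut * g.cut;
  for (int a = 0; a < natoms; ++a) {
    const double x = coords[a], y = coords[a + natoms], z = coords[a + 2 * natoms];
    double gx = 0, gy = 0, gz = 0;
    int lo[3], hi[3];
    const double c[3] = {x, y, z}, org[3] = {g.ox, g.oy, g.oz};
    bool outside = false;
    for (int ax = 0; ax < 3; ++ax) {
      lo[ax] = (int)std::ceil((c[ax] - g.cut - org[ax]) / g.res);
      hi[ax] = (int)std::floor((c[ax] + g.cut - org[ax]) / g.res);
      if (lo[ax] < 0) lo[ax] = 0;
      if (hi[ax] > g.np - 1) hi[ax] = g.np - 1;
      if (lo[ax] > hi[ax]) outside = true;
    }
    if (!outside) {
      for (int iz = lo[2]; iz <= hi[2]; ++iz) {
        const double dz = g.oz + iz * g.res - z, dz2 = dz * dz;
        for (int iy = lo[1]; iy <= hi[1]; ++iy) {
          const double dy = g.oy + iy * g.res - y, dyz2 = dy * dy + dz2;
          if (dyz2 > cut2) continue;
          for (int ix = lo[0]; ix <= hi[0]; ++ix) {
            const double dx = g.ox + ix * g.res - x, d2 = dx * dx + dyz2;
            if (d2 > cut2) continue;
            const double k = kernel_val(d2, g);
            const double *cell = resid.data() + (size_t)g.nch * (ix + (size_t)g.np * (iy + (size_t)g.np * iz));
            double w = 0.0;
            for (int ch = 0; ch < g.nch; ++ch) {
              const double t = types[a + (size_t)natoms * ch];
              if (t != 0.0) w += t * cell[ch];
            }
            // resid = model - ref; moving toward -grad decreases L2
            const double f = 2.0 * w * (-4.0 * g.r2inv) * k;
            gx += f * (-dx); gy += f * (-dy); gz += f * (-dz);
          }
        }
      }
    }
    grad[a] = gx; grad[a + natoms] = gy; grad[a + 2 * natoms] = gz;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_l2_gradient(NumericMatrix coords, NumericMatrix types,
                              NumericVector ref, NumericVector origin,
                              double res, int np, int nch, double radius,
                              double cutoff_mult) {
  GridGeom g = make_geom(origin, res, np, nch, radius, cutoff_mult);
  const size_t nvox = (size_t)nch * np * np * np;
  std::vector<double> resid(nvox);
  for (size_t i = 0; i < nvox; ++i) resid[i] = -ref[i];
  splat(resid, g, coords.begin(), types.begin(), coords.nrow(), 1.0);
  NumericMatrix grad(coords.nrow(), 3);
  l2_grad(resid, g, coords.begin(), types.begin(), coords.nrow(), grad.begin());
  return grad;
}

// Joint gradient descent on all atom coordinates with backtracking step
// control. Keeps the best iterate; returns refined coords, final L2 and the
// number of accepted steps.
// [[Rcpp::export]]
List cpp_refine(NumericMatrix coords_in, NumericMatrix types, NumericVector ref,
                NumericVector origin, double res, int np, int nch,
                double radius, double cutoff_mult, int max_steps,
                double step_size, double grad_tol) {
  GridGeom g = make_geom(origin, res, np, nch, radius, cutoff_mult);
  const int natoms = coords_in.nrow();
  const size_t nvox = (size_t)nch * np * np * np;

  std::vector<double> coords(coords_in.begin(), coords_in.end());
  std::vector<double> resid(nvox);
  for (size_t i = 0; i < nvox; ++i) resid[i] = -ref[i];
  splat(resid, g, coords.data(), types.begin(), natoms, 1.0);
  double loss = 0.0;
  for (size_t i = 0; i < nvox; ++i) loss += resid[i] * resid[i];

  if (natoms == 0 || max_steps <= 0) {
    return List::create(_["coords"] = coords_in, _["loss"] = loss, _["steps"] = 0);
  }

  std::vector<double> grad(3 * natoms), trial(3 * natoms);
  double lr = step_size;
  int accepted = 0;
  bool nonfinite = false;

  for (int it = 0; it < max_steps; ++it) {
    l2_grad(resid, g, coords.data(), types.begin(), natoms, grad.data());
    double gmax = 0.0;
    for (int i = 0; i < 3 * natoms; ++i) {
      if (!std::isfinite(grad[i])) { nonfinite = true; break; }
      gmax = std::max(gmax, std::fabs(grad[i]));
    }
    if (nonfinite) break;
    if (gmax < grad_tol) break;
    bool moved = false;
    while (lr >= 1e-7) {
      for (int i = 0; i < 3 * natoms; ++i) trial[i] = coords[i] - lr * grad[i];
      // trial residual: remove old atoms, add trial atoms (loss tracked
      // incrementally through the voxel updates)
      double newloss = loss;
      newloss += splat(resid, g, coords.data(), types.begin(), natoms, -1.0);
      newloss += splat(resid, g, trial.data(), types.begin(), natoms, 1.0);
      if (newloss <= loss) {
        coords.swap(trial);
        loss = newloss;
        lr *= 1.2;
        ++accepted;
        moved = true;
        break;
      }
      // revert
      splat(resid, g, trial.data(), types.begin(), natoms, -1.0);
      splat(resid, g, coords.data(), types.begin(), natoms, 1.0);
      lr *= 0.5;
    }
    if (!moved) break;
  }
  if (nonfinite) stop("non-finite gradient during coordinate refinement");

  NumericMatrix out(natoms, 3);
  std::copy(coords.begin(), coords.end(), out.begin());
  // exact final loss, clearing any drift from incremental updates
  std::vector<double> resid2(nvox);
  for (size_t i = 0; i < nvox; ++i) resid2[i] = -ref[i];
  splat(resid2, g, coords.data(), types.begin(), natoms, 1.0);
  double final_loss = 0.0;
  for (size_t i = 0; i < nvox; ++i) final_loss += resid2[i] * resid2[i];
  return List::create(_["coords"] = out, _["loss"] = final_loss,
                      _["steps"] = accepted);
}

// 26-neighbor local maxima of the first n_elem channels of a residual grid,
// at or above threshold. A voxel qualifies if its value is >= all in-bounds
// neighbors within the same channel. Returns (ix, iy, iz, ch, value) rows
// (0-based indices), sorted by value descending then linear index.
// [[Rcpp::export]]
NumericMatrix cpp_detect_peaks(NumericVector resid, int np, int nch,
                               int n_elem, double threshold) {
  std::vector<std::array<double, 5>> hits;
  const size_t strideY = (size_t)np, strideZ = (size_t)np * np;
  for (int ch = 0; ch < n_elem; ++ch) {
    for (int iz = 0; iz < np; ++iz)
      for (int iy = 0; iy < np; ++iy)
        for (int ix = 0; ix < np; ++ix) {
          const size_t vox = ix + strideY * iy + strideZ * iz;
          const double v = resid[ch + (size_t)nch * vox];
          if (v < threshold) continue;
          bool ismax = true;
          for (int dz = -1; dz <= 1 && ismax; ++dz)
            for (int dy = -1; dy <= 1 && ismax; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                if (!dx && !dy && !dz) continue;
                const int jx = ix + dx, jy = iy + dy, jz = iz + dz;
                if (jx < 0 || jy < 0 || jz < 0 || jx >= np || jy >= np || jz >= np)
                  continue;
                const double u = resid[ch + (size_t)nch * (jx + strideY * jy + strideZ * jz)];
                if (u > v) { ismax = false; break; }
              }
          if (ismax) hits.push_back({(double)ix, (double)iy, (double)iz,
                                     (double)ch, v});
        }
  }
  std::stable_sort(hits.begin(), hits.end(),
                   [](const std::array<double, 5> &a, const std::array<double, 5> &b) {
                     return a[4] > b[4];
                   });
  NumericMatrix out(hits.size(), 5);
  for (size_t i = 0; i < hits.size(); ++i)
    for (int j = 0; j < 5; ++j) out(i, j) = hits[i][j];
  return out;
}

// Lattice-snap polish: for each atom in turn, try the 8 grid nodes at the
// corners of its cell and keep the best strict improvement of the L2. The
// truncated kernel makes the loss discontinuous at support boundaries, so
// gradient descent can converge a hair away from an on-lattice optimum;
// this pass fixes exactly that case and is inert off-lattice.
// [[Rcpp::export]]
List cpp_snap_polish(NumericMatrix coords_in, NumericMatrix types,
                     NumericVector ref, NumericVector origin, double res,
                     int np, int nch, double radius, double cutoff_mult) {
  GridGeom g = make_geom(origin, res, np, nch, radius, cutoff_mult);
  const int natoms = coords_in.nrow();
  const size_t nvox = (size_t)nch * np * np * np;
  std::vector<double> coords(coords_in.begin(), coords_in.end());
  std::vector<double> resid(nvox);
  for (size_t i = 0; i < nvox; ++i) resid[i] = -ref[i];
  splat(resid, g, coords.data(), types.begin(), natoms, 1.0);
  double loss = 0.0;
  for (size_t i = 0; i < nvox; ++i) loss += resid[i] * resid[i];

  const double org[3] = {g.ox, g.oy, g.oz};
  std::vector<double> trial(3 * natoms);
  // sweep until a full pass makes no move: one atom's snap can unlock a
  // neighbor's (overlapping kernel supports couple their losses)
  bool changed = true;
  for (int sweep = 0; sweep < 8 && changed; ++sweep) {
  changed = false;
  for (int a = 0; a < natoms; ++a) {
    double cur[3] = {coords[a], coords[a + natoms], coords[a + 2 * natoms]};
    double best[3] = {cur[0], cur[1], cur[2]};
    double best_loss = loss;
    for (int corner = 0; corner < 8; ++corner) {
      double cand[3];
      bool onlat = true;
      for (int ax = 0; ax < 3; ++ax) {
        double idx = (cur[ax] - org[ax]) / g.res;
        double node = (corner >> ax & 1) ? std::ceil(idx) : std::floor(idx);
        if (node < 0) node = 0;
        if (node > g.np - 1) node = g.np - 1;
        cand[ax] = org[ax] + node * g.res;
        if (cand[ax] != cur[ax]) onlat = false;
      }
      if (onlat) continue;
      std::copy(coords.begin(), coords.end(), trial.begin());
      trial[a] = cand[0]; trial[a + natoms] = cand[1];
      trial[a + 2 * natoms] = cand[2];
      // move only atom a: remove its old density, add candidate
      double newloss = loss;
      double oc[3] = {coords[a], coords[a + natoms], coords[a + 2 * natoms]};
      std::vector<double> oneold(oc, oc + 3), onenew(cand, cand + 3);
      // single-atom splat needs a 1 x nch type row for atom a
      std::vector<double> trow(g.nch);
      for (int ch = 0; ch < g.nch; ++ch)
        trow[ch] = types(a, ch);
      newloss += splat(resid, g, oneold.data(), trow.data(), 1, -1.0);
      newloss += splat(resid, g, onenew.data(), trow.data(), 1, 1.0);
      if (newloss < best_loss) {
        best_loss = newloss;
        best[0] = cand[0]; best[1] = cand[1]; best[2] = cand[2];
      }
      // revert
      splat(resid, g, onenew.data(), trow.data(), 1, -1.0);
      splat(resid, g, oneold.data(), trow.data(), 1, 1.0);
    }
    if (best_loss < loss) {
      double oc[3] = {coords[a], coords[a + natoms], coords[a + 2 * natoms]};
      std::vector<double> oneold(oc, oc + 3), onenew(best, best + 3);
      std::vector<double> trow(g.nch);
      for (int ch = 0; ch < g.nch; ++ch) trow[ch] = types(a, ch);
      splat(resid, g, oneold.data(), trow.data(), 1, -1.0);
      splat(resid, g, onenew.data(), trow.data(), 1, 1.0);
      coords[a] = best[0]; coords[a + natoms] = best[1];
      coords[a + 2 * natoms] = best[2];
      loss = best_loss;
      changed = true;
    }
  }
  }
  NumericMatrix out(natoms, 3);
  std::copy(coords.begin(), coords.end(), out.begin());
  std::vector<double> resid2(nvox);
  for (size_t i = 0; i < nvox; ++i) resid2[i] = -ref[i];
  splat(resid2, g, coords.data(), types.begin(), natoms, 1.0);
  double final_loss = 0.0;
  for (size_t i = 0; i < nvox; ++i) final_loss += resid2[i] * resid2[i];
  return List::create(_["coords"] = out, _["loss"] = final_loss);
}
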