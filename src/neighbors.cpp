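#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Uniform-grid cell list over a point set. Cells are cubes of side `cs`;
// indices are counting-sorted so each cell owns a contiguous slice of `order`.
struct CellList {
  double ox, oy, oz, cs;
  int nx, ny, nz;
  std::vector<int> start;  // size ncell+1
  std::vector<int> order;  // point indices grouped by cell

  CellList(const NumericMatrix &Y, double cell_size) {
    const int n = Y.nrow();
    cs = cell_size;
    ox = oy = oz = 0.0;
    double mx = 0, my = 0, mz = 0;
    if (n > 0) {
      ox = mx = Y(0, 0); oy = my = Y(0, 1); oz = mz = Y(0, 2);
      for (int i = 1; i < n; ++i) {
        ox = std::min(ox, Y(i, 0)); mx = std::max(mx, Y(i, 0));
        oy = std::min(oy, Y(i, 1)); my = std::max(my, Y(i, 1));
        oz = std::min(oz, Y(i, 2)); mz = std::max(mz, Y(i, 2));
      }
    }
    nx = std::max(1, (int)std::floor((mx - ox) / cs) + 1);
    ny = std::max(1, (int)std::floor((my - oy) / cs) + 1);
    nz = std::max(1, (int)std::floor((mz - oz) / cs) + 1);
    const int ncell = nx * ny * nz;
    std::vector<int> cell(n);
    std::vector<int> cnt(ncell + 1, 0);
    for (int i = 0; i < n; ++i) {
      int cx = std::min(nx - 1, std::max(0, (int)std::floor((Y(i, 0) - ox) / cs)));
      int cy = std::min(ny - 1, std::max(0, (int)std::floor((Y(i, 1) - oy) / cs)));
      int cz = std::min(nz - 1, std::max(0, (int)std::floor((Y(i, 2) - oz) / cs)));
      cell[i] = (cz * ny + cy) * nx + cx;
      cnt[cell[i] + 1]++;
    }
    for (int c = 0; c < ncell; ++c) cnt[c + 1] += cnt[c];
    start = cnt;
    order.resize(n);
    std::vector<int> fill(start.begin(), start.end() - 1);
    for (int i = 0; i < n; ++i) order[fill[cell[i]]++] = i;
  }
};

// Histogram of pair distances between point sets X and Y within rmax,
// bin width dr, optionally excluding pairs on the same chain. Pairs are
// counted once per ordered (i in X, j in Y) combination; identical atoms
// (distance ~0) are skipped so overlapping selections stay well-defined.
// [[Rcpp::export]]
NumericVector pair_hist_cpp(NumericMatrix X, IntegerVector chainX,
                            NumericMatrix Y, IntegerVector chainY,
                            double rmax, double dr, bool exclude_same_chain) {
  const int nbin = (int)std::ceil(rmax / dr);
  NumericVector hist(nbin);
  if (X.nrow() == 0 || Y.nrow() == 0) return hist;
  const double cs = std::max(rmax / 6.0, 0.15);
  CellList cl(Y, cs);
  const double r2max = rmax * rmax;
  const int reach = (int)std::ceil(rmax / cs);

  for (int i = 0; i < X.nrow(); ++i) {
    const double xi = X(i, 0), yi = X(i, 1), zi = X(i, 2);
    const int ci = chainX.size() ? chainX[i] : -1;
    int cx = (int)std::floor((xi - cl.ox) / cl.cs);
    int cy = (int)std::floor((yi - cl.oy) / cl.cs);
    int cz = (int)std::floor((zi - cl.oz) / cl.cs);
    for (int az = std::max(0, cz - reach); az <= std::min(cl.nz - 1, cz + reach); ++az) {
      // squared distance from point to nearest face of the cell slab, per axis
      double dz = 0.0;
      if (az > cz) dz = (az - cz - 1) * cl.cs + (cl.oz + (cz + 1) * cl.cs - zi);
      else if (az < cz) dz = (cz - az - 1) * cl.cs + (zi - (cl.oz + cz * cl.cs));
      if (dz < 0) dz = 0;
      if (dz * dz > r2max) continue;
      for (int ay = std::max(0, cy - reach); ay <= std::min(cl.ny - 1, cy + reach); ++ay) {
        double dy = 0.0;
        if (ay > cy) dy = (ay - cy - 1) * cl.cs + (cl.oy + (cy + 1) * cl.cs - yi);
        else if (ay < cy) dy = (cy - ay - 1) * cl.cs + (yi - (cl.oy + cy * cl.cs));
        if (dy < 0) dy = 0;
        if (dz * dz + dy * dy > r2max) continue;
        for (int ax = std::max(0, cx - reach); ax <= std::min(cl.nx - 1, cx + reach); ++ax) {
          double dx = 0.0;
          if (ax > cx) dx = (ax - cx - 1) * cl.cs + (cl.ox + (cx + 1) * cl.cs - xi);
          else if (ax < cx) dx = (cx - ax - 1) * cl.cs + (xi - (cl.ox + cx * cl.cs));
          if (dx < 0) dx = 0;
          if (dx * dx + dy * dy + dz * dz > r2max) continue;
          const int c = (az * cl.ny + ay) * cl.nx + ax;
          for (int s = cl.start[c]; s < cl.start[c + 1]; ++s) {
            const int j = cl.order[s];
            if (exclude_same_chain && chainY.size() && chainY[j] == ci) continue;
            const double ddx = Y(j, 0) - xi, ddy = Y(j, 1) - yi, ddz = Y(j, 2) - zi;
            const double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
            if (d2 >= r2max || d2 < 1e-12) continue;
            int b = (int)(std::sqrt(d2) / dr);
            if (b >= nbin) b = nbin - 1;
            hist[b] += 1.0;
          }
        }
      }
    }
  }
  return hist;
}

// All pairs (i in X, j in Y) with 0 < d <= cutoff. 1-based indices.
// [[Rcpp::export]]
List neighbor_pairs_cpp(NumericMatrix X, NumericMatrix Y, double cutoff) {
  std::vector<int> ii, jj;
  std::vector<double> dd;
  if (X.nrow() > 0 && Y.nrow() > 0) {
    const double cs = std::max(cutoff, 0.05);
    CellList cl(Y, cs);
    const double c2 = cutoff * cutoff;
    for (int i = 0; i < X.nrow(); ++i) {
      const double xi = X(i, 0), yi = X(i, 1), zi = X(i, 2);
      int cx = (int)std::floor((xi - cl.ox) / cl.cs);
      int cy = (int)std::floor((yi - cl.oy) / cl.cs);
      int cz = (int)std::floor((zi - cl.oz) / cl.cs);
      for (int az = std::max(0, cz - 1); az <= std::min(cl.nz - 1, cz + 1); ++az)
        for (int ay = std::max(0, cy - 1); ay <= std::min(cl.ny - 1, cy + 1); ++ay)
          for (int ax = std::max(0, cx - 1); ax <= std::min(cl.nx - 1, cx + 1); ++ax) {
            if (std::abs(ax - cx) > 1 || std::abs(ay - cy) > 1 || std::abs(az - cz) > 1) continue;
            const int c = (az * cl.ny + ay) * cl.nx + ax;
            for (int s = cl.start[c]; s < cl.start[c + 1]; ++s) {
              const int j = cl.order[s];
              const double ddx = Y(j, 0) - xi, ddy = Y(j, 1) - yi, ddz = Y(j, 2) - zi;
              const double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
              if (d2 > c2 || d2 < 1e-12) continue;
              ii.push_back(i + 1);
              jj.push_back(j + 1);
              dd.push_back(std::sqrt(d2));
            }
          }
    }
  }
  return List::create(_["i"] = wrap(ii), _["j"] = wrap(jj), _["d"] = wrap(dd));
}

// Shrake-Rupley accessible surface area. radii_ext = vdW radius + probe
// radius per atom (nm). Test points on a golden-spiral sphere; a point
// survives if inside no neighbouring extended sphere.
// [[Rcpp::export]]
NumericVector sasa_cpp(NumericMatrix X, NumericVector radii_ext, int n_points) {
  const int n = X.nrow();
  NumericVector area(n);
  if (n == 0) return area;
  double rmaxext = 0.0;
  for (int i = 0; i < n; ++i) rmaxext = std::max(rmaxext, radii_ext[i]);
  const double cutoff = 2.0 * rmaxext;
  const double cs = std::max(cutoff, 0.05);
  CellList cl(X, cs);

  // golden-spiral unit sphere
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    const double z = 1.0 - 2.0 * (k + 0.5) / n_points;
    const double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    px[k] = r * std::cos(ga * k);
    py[k] = r * std::sin(ga * k);
    pz[k] = z;
  }

  std::vector<int> nbr;
  for (int i = 0; i < n; ++i) {
    const double xi = X(i, 0), yi = X(i, 1), zi = X(i, 2), ri = radii_ext[i];
    nbr.clear();
    int cx = (int)std::floor((xi - cl.ox) / cl.cs);
    int cy = (int)std::floor((yi - cl.oy) / cl.cs);
    int cz = (int)std::floor((zi - cl.oz) / cl.cs);
    for (int az = std::max(0, cz - 1); az <= std::min(cl.nz - 1, cz + 1); ++az)
      for (int ay = std::max(0, cy - 1); ay <= std::min(cl.ny - 1, cy + 1); ++ay)
        for (int ax = std::max(0, cx - 1); ax <= std::min(cl.nx - 1, cx + 1); ++ax) {
          const int c = (az * cl.ny + ay) * cl.nx + ax;
          for (int s = cl.start[c]; s < cl.start[c + 1]; ++s) {
            const int j = cl.order[s];
            if (j == i) continue;
            const double dx = X(j, 0) - xi, dy = X(j, 1) - yi, dz = X(j, 2) - zi;
            const double lim = ri + radii_ext[j];
            if (dx * dx + dy * dy + dz * dz < lim * lim) nbr.push_back(j);
          }
        }
    int acc = 0;
    for (int k = 0; k < n_points; ++k) {
      const double tx = xi + ri * px[k], ty = yi + ri * py[k], tz = zi + ri * pz[k];
      bool free_pt = true;
      for (size_t m = 0; m < nbr.size(); ++m) {
        const int j = nbr[m];
        const double dx = X(j, 0) - tx, dy = X(j, 1) - ty, dz = X(j, 2) - tz;
        if (dx * dx + dy * dy + dz * dz < radii_ext[j] * radii_ext[j]) { free_pt = false; break; }
      }
      if (free_pt) ++acc;
    }
    area[i] = 4.0 * M_PI * ri * ri * (double)acc / n_points;
  }
  return area;
}
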