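// Parallel-beam projection / back-projection kernels and an exact
// order-statistics median filter.
//
// Geometry convention (shared with the R layer): angles in radians,
// counter-clockwise, theta = 0 sends rays along +y; pixel centres at integer
// coordinates 0..n-1; rotation about the central pixel c = (n-1)/2; the
// detector axis t satisfies t = (x - c) cos(theta) + (y - c) sin(theta).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Line integrals of a square slice: rotate the image so rays align with the
// y axis (bilinear interpolation, zero outside) and sum columns.
// Returns n_angles x n.
// [[Rcpp::export]]
arma::mat cpp_project_slice(const arma::mat& img, const arma::vec& theta) {
  const int n = img.n_rows;
  if ((int)img.n_cols != n) Rcpp::stop("slice must be square");
  const double c = (n - 1) / 2.0;
  const int na = theta.n_elem;
  mat out(na, n, fill::zeros);
  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(theta[a]), st = std::sin(theta[a]);
    for (int xp = 0; xp < n; ++xp) {
      double acc = 0.0;
      const double dxp = xp - c;
      for (int yp = 0; yp < n; ++yp) {
        const double dyp = yp - c;
        const double px = c + dxp * ct - dyp * st;  // source column
        const double py = c + dxp * st + dyp * ct;  // source row
        if (px < 0 || px > n - 1 || py < 0 || py > n - 1) continue;
        const int x0 = (int)std::floor(px), y0 = (int)std::floor(py);
        const int x1 = std::min(x0 + 1, n - 1), y1 = std::min(y0 + 1, n - 1);
        const double fx = px - x0, fy = py - y0;
        acc += (1 - fy) * ((1 - fx) * img(y0, x0) + fx * img(y0, x1)) +
               fy * ((1 - fx) * img(y1, x0) + fx * img(y1, x1));
      }
      out(a, xp) = acc;
    }
  }
  return out;
}

// Back-projection of a filtered sinogram (n_angles x n) onto an n x n grid
// with linear interpolation along the detector. Caller applies the
// pi/(2 n_angles) scale.
// [[Rcpp::export]]
arma::mat cpp_backproject(const arma::mat& fsino, const arma::vec& theta,
                          const int n) {
  const double c = (n - 1) / 2.0;
  const int na = theta.n_elem;
  mat rec(n, n, fill::zeros);
  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(theta[a]), st = std::sin(theta[a]);
    for (int x = 0; x < n; ++x) {
      const double tx = (x - c) * ct;
      for (int y = 0; y < n; ++y) {
        const double t = tx + (y - c) * st + c;
        if (t < 0 || t > n - 1) continue;
        const int t0 = (int)std::floor(t);
        const int t1 = std::min(t0 + 1, n - 1);
        const double ft = t - t0;
        rec(y, x) += (1 - ft) * fsino(a, t0) + ft * fsino(a, t1);
      }
    }
  }
  return rec;
}

// mirror reflection without edge repeat: -1 -> 1, n -> n-2
static inline int reflect(int i, const int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * (n - 1) - i;
  }
  return i;
}

// Exact 3-D median filter, cube (default) or ball neighbourhood of the given
// radius, mirror-reflected edges.
// [[Rcpp::export]]
arma::cube cpp_median3d(const arma::cube& vol, const int radius,
                        const bool ball) {
  const int ny = vol.n_rows, nx = vol.n_cols, nz = vol.n_slices;
  cube out(ny, nx, nz);
  std::vector<std::array<int, 3>> offs;
  const double r2 = (double)radius * radius + 1e-9;
  for (int dz = -radius; dz <= radius; ++dz)
    for (int dx = -radius; dx <= radius; ++dx)
      for (int dy = -radius; dy <= radius; ++dy) {
        if (ball && dy * dy + dx * dx + dz * dz > r2) continue;
        offs.push_back({dy, dx, dz});
      }
  std::vector<double> buf(offs.size());
  const size_t m = offs.size() / 2;  // odd count: true middle order statistic
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        for (size_t k = 0; k < offs.size(); ++k)
          buf[k] = vol(reflect(y + offs[k][0], ny),
                       reflect(x + offs[k][1], nx),
                       reflect(z + offs[k][2], nz));
        std::nth_element(buf.begin(), buf.begin() + m, buf.end());
        out(y, x, z) = buf[m];
      }
  return out;
}

// 2-D variant (disc neighbourhood when ball = true).
// [[Rcpp::export]]
arma::mat cpp_median2d(const arma::mat& img, const int radius,
                       const bool ball) {
  const int ny = img.n_rows, nx = img.n_cols;
  mat out(ny, nx);
  std::vector<std::array<int, 2>> offs;
  const double r2 = (double)radius * radius + 1e-9;
  for (int dx = -radius; dx <= radius; ++dx)
    for (int dy = -radius; dy <= radius; ++dy) {
      if (ball && dy * dy + dx * dx > r2) continue;
      offs.push_back({dy, dx});
    }
  std::vector<double> buf(offs.size());
  const size_t m = offs.size() / 2;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      for (size_t k = 0; k < offs.size(); ++k)
        buf[k] = img(reflect(y + offs[k][0], ny), reflect(x + offs[k][1], nx));
      std::nth_element(buf.begin(), buf.begin() + m, buf.end());
      out(y, x) = buf[m];
    }
  return out;
}
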