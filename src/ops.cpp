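// Compute-heavy image operations: real-space volume projection, bilinear
// image rotation, Fourier CTF application, and the exhaustive in-plane
// rotation + FFT shift search used by global projection matching.
//
// Conventions: arrays are indexed [x, y(, z)] with x fastest (R array
// layout); images are square (n x n) with the rotation/shift origin at the
// centre pixel n/2 (0-based). All angles here are radians.

#include <RcppArmadillo.h>
#include <fftw3.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double trilinear(const arma::cube& v, double x, double y, double z) {
  const int nx = v.n_rows, ny = v.n_cols, nz = v.n_slices;
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
    return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
      z1 = std::min(z0 + 1, nz - 1);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  double c00 = v(x0, y0, z0) * (1 - fx) + v(x1, y0, z0) * fx;
  double c10 = v(x0, y1, z0) * (1 - fx) + v(x1, y1, z0) * fx;
  double c01 = v(x0, y0, z1) * (1 - fx) + v(x1, y0, z1) * fx;
  double c11 = v(x0, y1, z1) * (1 - fx) + v(x1, y1, z1) * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

static inline double bilinear(const arma::mat& m, double x, double y) {
  const int nx = m.n_rows, ny = m.n_cols;
  if (x < 0 || y < 0 || x > nx - 1 || y > ny - 1) return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1);
  double fx = x - x0, fy = y - y0;
  return m(x0, y0) * (1 - fx) * (1 - fy) + m(x1, y0) * fx * (1 - fy) +
         m(x0, y1) * (1 - fx) * fy + m(x1, y1) * fx * fy;
}

// Line-integral projection of vol viewed along the orientation whose ZYZ
// Euler matrix is R (image coords -> map coords), then shifted by (sx, sy)
// pixels. out(u) = sum_z vol(R * (u - c - s, z - c)) in voxel units.
// [[Rcpp::export]]
arma::mat cpp_project_volume(const arma::cube& vol, const arma::mat& R,
                             double sx, double sy) {
  const int n = vol.n_rows;
  const double c = n / 2;
  arma::mat out(n, n, arma::fill::zeros);
  for (int iy = 0; iy < n; ++iy) {
    double v = iy - c - sy;
    for (int ix = 0; ix < n; ++ix) {
      double u = ix - c - sx;
      double acc = 0.0;
      // base point at z = -c and per-step increment along the view axis
      double px = R(0, 0) * u + R(0, 1) * v + R(0, 2) * (-c) + c;
      double py = R(1, 0) * u + R(1, 1) * v + R(1, 2) * (-c) + c;
      double pz = R(2, 0) * u + R(2, 1) * v + R(2, 2) * (-c) + c;
      for (int iz = 0; iz < n; ++iz) {
        acc += trilinear(vol, px, py, pz);
        px += R(0, 2); py += R(1, 2); pz += R(2, 2);
      }
      out(ix, iy) = acc;
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_project_batch(const arma::cube& vol, const arma::cube& Rs) {
  const int n = vol.n_rows, m = Rs.n_slices;
  arma::cube out(n, n, m);
  for (int j = 0; j < m; ++j)
    out.slice(j) = cpp_project_volume(vol, Rs.slice(j), 0.0, 0.0);
  return out;
}

// Rotate image content counter-clockwise by psi about the centre pixel:
// out(u) = img(Rot(-psi) (u - c) + c), bilinear.
// [[Rcpp::export]]
arma::mat cpp_rotate_image(const arma::mat& img, double psi) {
  const int n = img.n_rows;
  const double c = n / 2;
  const double cs = std::cos(psi), sn = std::sin(psi);
  arma::mat out(n, img.n_cols, arma::fill::zeros);
  for (unsigned int iy = 0; iy < img.n_cols; ++iy) {
    double v = iy - c;
    for (int ix = 0; ix < n; ++ix) {
      double u = ix - c;
      out(ix, iy) = bilinear(img, cs * u + sn * v + c, -sn * u + cs * v + c);
    }
  }
  return out;
}

// Shift image content by (sx, sy) pixels: out(u) = img(u - s), bilinear.
// [[Rcpp::export]]
arma::mat cpp_shift_image(const arma::mat& img, double sx, double sy) {
  const int n = img.n_rows;
  arma::mat out(n, img.n_cols, arma::fill::zeros);
  for (unsigned int iy = 0; iy < img.n_cols; ++iy)
    for (int ix = 0; ix < n; ++ix)
      out(ix, iy) = bilinear(img, ix - sx, iy - sy);
  return out;
}

// Multiply the 2D DFT of img by the (real, DFT-layout) filter and invert.
// [[Rcpp::export]]
arma::mat cpp_fourier_filter(const arma::mat& img, const arma::mat& filt) {
  arma::cx_mat F = arma::fft2(arma::cx_mat(img, arma::mat(img.n_rows, img.n_cols, arma::fill::zeros)));
  F %= arma::cx_mat(filt, arma::mat(filt.n_rows, filt.n_cols, arma::fill::zeros));
  return arma::real(arma::ifft2(F));
}

// Zero-mean, unit-variance normalisation over a binary mask; pixels outside
// the mask are set to zero. Degenerate (constant) images come back all-zero.
static arma::mat mask_normalize(const arma::mat& img, const arma::uvec& idx,
                                double nmask) {
  arma::vec vals(idx.n_elem);
  for (unsigned int k = 0; k < idx.n_elem; ++k) vals(k) = img(idx(k));
  double mu = arma::mean(vals);
  double sd = std::sqrt(arma::accu(arma::square(vals - mu)) / nmask);
  arma::mat out(img.n_rows, img.n_cols, arma::fill::zeros);
  if (sd < 1e-12) return out;
  for (unsigned int k = 0; k < idx.n_elem; ++k)
    out(idx(k)) = (img(idx(k)) - mu) / sd;
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_mask_normalize(const arma::mat& img, const arma::mat& mask) {
  arma::uvec idx = arma::find(mask > 0.5);
  return mask_normalize(img, idx, (double)idx.n_elem);
}

// Exhaustive global alignment of one experimental image against a stack of
// reference images. For each reference, searches every in-plane angle in
// `psis` with a per-angle FFT translational search bounded by max_shift,
// under a circular mask; returns the maximising (ncc, psi, sx, sy) per
// reference. The model is exp(u) ~ ref(Rot(-psi)(u - s)): psi and s are the
// in-plane rotation and shift that map the reference onto the experimental
// image.
// [[Rcpp::export]]
List cpp_global_search(const arma::mat& exp_img, const arma::cube& refs,
                       const arma::vec& psis, const arma::mat& mask,
                       int max_shift) {
  const int n = exp_img.n_rows;
  const int nn = n * n;
  const int nref = refs.n_slices, npsi = psis.n_elem;
  arma::uvec midx = arma::find(mask > 0.5);
  const double nmask = (double)midx.n_elem;
  const double inv_nn = 1.0 / nn;

  // shared FFTW plans (unnormalised backward; scaling folded in below)
  std::vector<std::complex<double>> fin(nn), fout(nn);
  fftw_plan fwd = fftw_plan_dft_2d(n, n, reinterpret_cast<fftw_complex*>(fin.data()),
                                   reinterpret_cast<fftw_complex*>(fout.data()),
                                   FFTW_FORWARD, FFTW_ESTIMATE);
  fftw_plan bwd = fftw_plan_dft_2d(n, n, reinterpret_cast<fftw_complex*>(fin.data()),
                                   reinterpret_cast<fftw_complex*>(fout.data()),
                                   FFTW_BACKWARD, FFTW_ESTIMATE);
  auto fft_of = [&](const arma::mat& m, std::complex<double>* dst) {
    for (int k = 0; k < nn; ++k) fin[k] = m(k);
    fftw_execute(fwd);
    std::copy(fout.begin(), fout.end(), dst);
  };

  // FFTs of the rotated, mask-normalised experimental image, one per psi
  std::vector<std::vector<std::complex<double>>> E(npsi,
      std::vector<std::complex<double>>(nn));
  for (int a = 0; a < npsi; ++a) {
    arma::mat er = (psis(a) == 0.0) ? exp_img : cpp_rotate_image(exp_img, -psis(a));
    fft_of(mask_normalize(er, midx, nmask), E[a].data());
  }

  // wrapped shift offsets to scan
  std::vector<int> offs;
  for (int t = -max_shift; t <= max_shift; ++t) offs.push_back(((t % n) + n) % n);
  std::vector<int> tval;
  for (int t = -max_shift; t <= max_shift; ++t) tval.push_back(t);

  arma::vec ncc(nref), psi_out(nref), sx_out(nref), sy_out(nref);
  std::vector<std::complex<double>> Rf(nn);
  std::vector<double> Cbest(nn);
  for (int j = 0; j < nref; ++j) {
    fft_of(mask_normalize(refs.slice(j), midx, nmask), Rf.data());
    double best = -2.0; int bpsi = 0, btx = 0, bty = 0;
    for (int a = 0; a < npsi; ++a) {
      const std::complex<double>* Ea = E[a].data();
      for (int k = 0; k < nn; ++k) fin[k] = std::conj(Rf[k]) * Ea[k];
      fftw_execute(bwd);
      bool hit = false;
      for (size_t qy = 0; qy < offs.size(); ++qy) {
        const int base = offs[qy] * n;
        for (size_t qx = 0; qx < offs.size(); ++qx) {
          double v = fout[offs[qx] + base].real() * inv_nn;
          if (v > best) { best = v; bpsi = a; btx = tval[qx]; bty = tval[qy]; hit = true; }
        }
      }
      if (hit)
        for (int k = 0; k < nn; ++k) Cbest[k] = fout[k].real() * inv_nn;
    }
    // sub-pixel refinement: separable 3-point parabola about the peak
    double tx = btx, ty = bty, val = best;
    {
      int x0 = ((btx % n) + n) % n, y0 = ((bty % n) + n) % n;
      int xm = (x0 + n - 1) % n, xp = (x0 + 1) % n;
      int ym = (y0 + n - 1) % n, yp = (y0 + 1) % n;
      double cxm = Cbest[xm + n * y0], cx0 = Cbest[x0 + n * y0],
             cxp = Cbest[xp + n * y0];
      double cym = Cbest[x0 + n * ym], cyp = Cbest[x0 + n * yp];
      double dx = 0.0, dy = 0.0, gain = 0.0;
      double denx = cxm - 2 * cx0 + cxp, deny = cym - 2 * cx0 + cyp;
      if (denx < -1e-12) { dx = 0.5 * (cxm - cxp) / denx; gain += -0.25 * (cxm - cxp) * dx; }
      if (deny < -1e-12) { dy = 0.5 * (cym - cyp) / deny; gain += -0.25 * (cym - cyp) * dy; }
      if (std::fabs(dx) <= 1.0 && std::fabs(dy) <= 1.0) {
        tx = btx + dx; ty = bty + dy; val = cx0 + gain;
      }
    }
    val /= nmask;
    ncc(j) = std::max(-1.0, std::min(1.0, val));
    psi_out(j) = psis(bpsi);
    // correlation peak t is in the rotated-experimental frame: s = Rot(psi) t
    double cs = std::cos(psis(bpsi)), sn = std::sin(psis(bpsi));
    sx_out(j) = cs * tx - sn * ty;
    sy_out(j) = sn * tx + cs * ty;
  }
  fftw_destroy_plan(fwd);
  fftw_destroy_plan(bwd);
  return List::create(_["ncc"] = ncc, _["psi"] = psi_out,
                      _["sx"] = sx_out, _["sy"] = sy_out);
}

// Apply one real DFT-layout filter to every slice of a stack.
// [[Rcpp::export]]
arma::cube cpp_filter_cube(const arma::cube& stack, const arma::mat& filt) {
  arma::cube out(stack.n_rows, stack.n_cols, stack.n_slices);
  arma::cx_mat cf(filt, arma::mat(filt.n_rows, filt.n_cols, arma::fill::zeros));
  for (unsigned int j = 0; j < stack.n_slices; ++j) {
    arma::cx_mat F = arma::fft2(arma::cx_mat(stack.slice(j),
                      arma::mat(stack.n_rows, stack.n_cols, arma::fill::zeros)));
    out.slice(j) = arma::real(arma::ifft2(F % cf));
  }
  return out;
}
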