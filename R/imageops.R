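# Image-domain operations: containers for maps and particle images, volume
# projection, CTF simulation, normalisation, and the exhaustive in-plane +
# shift alignment search behind global projection matching.

#' Map volume container
#'
#' @param data 3D numeric array, cubic with even side.
#' @param voxel_size Voxel edge length in Angstrom.
#' @return Object of class \code{MapVolume}.
#' @export
map_volume <- function(data, voxel_size = 1) {
  d <- dim(data)
  if (length(d) != 3L || length(unique(d)) != 1L)
    stop("invalid input: map volume must be a cubic 3D array")
  if (d[1] %% 2L != 0L) stop("invalid input: map box size must be even")
  if (!all(is.finite(data))) stop("invalid input: map contains non-finite values")
  structure(list(data = data, voxel_size = voxel_size), class = "MapVolume")
}

#' @export
print.MapVolume <- function(x, ...) {
  cat("MapVolume ", paste(dim(x$data), collapse = "x"), " voxels, ",
      x$voxel_size, " A/voxel\n", sep = "")
  invisible(x)
}

#' Particle image container
#'
#' @param data Square numeric matrix.
#' @param pixel_size Pixel size in Angstrom.
#' @return Object of class \code{ParticleImage}.
#' @export
particle_image <- function(data, pixel_size = 1) {
  if (!is.matrix(data) || nrow(data) != ncol(data))
    stop("invalid input: particle image must be a square matrix")
  structure(list(data = data, pixel_size = pixel_size), class = "ParticleImage")
}

#' Particle orientation (Euler angles + origin shift)
#'
#' ZYZ Euler angles in degrees and a 2D origin shift in pixels. \code{rot}
#' and \code{psi} are wrapped to [-180, 180); \code{tilt} must lie in
#' [0, 180].
#'
#' @param rot,tilt,psi Euler angles, degrees.
#' @param shift_x,shift_y Origin shift, pixels.
#' @return Object of class \code{Orientation}.
#' @export
orientation <- function(rot = 0, tilt = 0, psi = 0, shift_x = 0, shift_y = 0) {
  wrap <- function(a) ((a + 180) %% 360) - 180
  if (!is.finite(tilt) || tilt < 0 || tilt > 180)
    stop("invalid orientation: tilt must be in [0, 180]")
  structure(list(rot = wrap(rot), tilt = tilt, psi = wrap(psi),
                 shift_x = shift_x, shift_y = shift_y), class = "Orientation")
}

#' Project a map volume at an orientation
#'
#' Real-space line-integral projection: the volume is sampled along the
#' viewing axis defined by the ZYZ Euler matrix of \code{o} (trilinear
#' interpolation) and summed, then translated by the orientation's origin
#' shift. Linear in the volume; pixel sums equal voxel sums (voxel units) up
#' to interpolation loss at the box edge.
#'
#' @param vol A [map_volume()].
#' @param o An [orientation()].
#' @return A [particle_image()] with the map's voxel size as pixel size.
#' @export
project_volume <- function(vol, o) {
  if (!inherits(vol, "MapVolume")) stop("invalid input: not a MapVolume")
  R <- euler_matrix(o$rot, o$tilt, o$psi)
  img <- cpp_project_volume(vol$data, R, o$shift_x, o$shift_y)
  particle_image(img, vol$voxel_size)
}

## Euler matrices for a set of directions (psi = 0), stacked as 3x3xn
direction_matrices <- function(dirs) {
  dirs <- rbind(dirs)
  eu <- direction_to_euler(dirs)
  Rs <- array(0, c(3, 3, nrow(dirs)))
  for (i in seq_len(nrow(dirs)))
    Rs[, , i] <- euler_matrix(eu$rot[i], eu$tilt[i], 0)
  Rs
}

#' Project a map at every node of a projection grid
#'
#' @param vol A [map_volume()].
#' @param grid A [sample_projection_grid()].
#' @return List with \code{images} (n x n x n_dir array) and
#'   \code{directions} (n_dir x 3).
#' @export
project_grid <- function(vol, grid) {
  Rs <- direction_matrices(grid$directions)
  list(images = cpp_project_batch(vol$data, Rs), directions = grid$directions)
}

## Relativistic electron wavelength (Angstrom) at acceleration voltage kV
electron_wavelength <- function(kv) {
  v <- kv * 1e3
  12.2639 / sqrt(v + 0.97845e-6 * v^2)
}

#' Contrast transfer function parameters
#'
#' @param defocus_u,defocus_v Defocus along the astigmatism major/minor axes,
#'   Angstrom (positive = underfocus).
#' @param astig_angle Azimuth of the major defocus axis, degrees.
#' @param voltage Acceleration voltage, kV.
#' @param cs Spherical aberration, mm.
#' @param amplitude_contrast Amplitude contrast fraction in [0, 1].
#' @param phase_shift Additional phase shift (phase plate), degrees.
#' @return Object of class \code{CTFParams}.
#' @export
ctf_params <- function(defocus_u = 15000, defocus_v = defocus_u,
                       astig_angle = 0, voltage = 300, cs = 2.7,
                       amplitude_contrast = 0.07, phase_shift = 0) {
  if (amplitude_contrast < 0 || amplitude_contrast > 1)
    stop("invalid CTF: amplitude contrast must be in [0, 1]")
  structure(list(defocus_u = defocus_u, defocus_v = defocus_v,
                 astig_angle = astig_angle, voltage = voltage, cs = cs,
                 amplitude_contrast = amplitude_contrast,
                 phase_shift = phase_shift), class = "CTFParams")
}

#' Evaluate the weak-phase contrast transfer function
#'
#' CTF(f, theta) = -sqrt(1 - A^2) sin(gamma) - A cos(gamma) with
#' gamma = pi lambda dz(theta) f^2 - (pi/2) Cs lambda^3 f^4 + phase shift and
#' dz(theta) = (U+V)/2 + (U-V)/2 cos 2(theta - theta_astig).
#'
#' @param ctf A [ctf_params()].
#' @param freq Spatial frequency, 1/Angstrom (vectorised).
#' @param azimuth Azimuth of the frequency vector, radians.
#' @return CTF value(s) in [-1, 1].
#' @export
ctf_evaluate <- function(ctf, freq, azimuth = 0) {
  lambda <- electron_wavelength(ctf$voltage)
  dz <- (ctf$defocus_u + ctf$defocus_v) / 2 +
    (ctf$defocus_u - ctf$defocus_v) / 2 *
      cos(2 * (azimuth - ctf$astig_angle * DEG2RAD))
  gamma <- pi * lambda * dz * freq^2 -
    (pi / 2) * (ctf$cs * 1e7) * lambda^3 * freq^4 +
    ctf$phase_shift * DEG2RAD
  A <- ctf$amplitude_contrast
  -sqrt(1 - A^2) * sin(gamma) - A * cos(gamma)
}

## CTF evaluated on the unshifted 2D DFT frequency layout of an n x n image
ctf_image <- function(ctf, n, pixel_size) {
  k <- c(0:(n / 2), (-(n / 2 - 1)):(-1)) / (n * pixel_size)
  fx <- matrix(k, n, n)
  fy <- t(fx)
  ctf_evaluate(ctf, sqrt(fx^2 + fy^2), atan2(fy, fx))
}

#' Apply a CTF to an image
#'
#' Multiplies the image's 2D Fourier transform by the CTF and inverts.
#'
#' @param img A [particle_image()].
#' @param ctf A [ctf_params()], or NULL for a pass-through identity.
#' @return Filtered [particle_image()].
#' @export
apply_ctf <- function(img, ctf) {
  if (is.null(ctf)) return(img)
  filt <- ctf_image(ctf, nrow(img$data), img$pixel_size)
  particle_image(cpp_fourier_filter(img$data, filt), img$pixel_size)
}

## binary circular mask about the centre pixel n/2 (0-based)
circular_mask <- function(n, radius) {
  cx <- n / 2
  x <- matrix(0:(n - 1), n, n) - cx
  y <- t(x)
  (x^2 + y^2 <= radius^2) * 1
}

#' Normalise an image to zero mean and unit variance under a circular mask
#'
#' Pixels outside the mask are zeroed. A constant (zero-variance) image
#' cannot be normalised and is returned as all zeros with attribute
#' \code{degenerate = TRUE}.
#'
#' @param img A [particle_image()].
#' @param mask_radius Mask radius in pixels; default 0.45 x box size.
#' @return Normalised [particle_image()] (attribute \code{degenerate} set on
#'   constant input).
#' @export
normalize_image <- function(img, mask_radius = 0.45 * nrow(img$data)) {
  n <- nrow(img$data)
  if (mask_radius > n / 2) stop("mask radius exceeds half the box size")
  m <- circular_mask(n, mask_radius)
  out <- cpp_mask_normalize(img$data, m)
  res <- particle_image(out, img$pixel_size)
  attr(res, "degenerate") <- all(out == 0)
  res
}

#' Exhaustive 2D alignment of an image pair
#'
#' Searches every in-plane rotation (step \code{rot_step}) with a per-angle
#' FFT translational search bounded by \code{max_shift}, maximising the
#' normalised cross correlation under a circular mask of radius 0.45 x box.
#' The returned \code{psi}/\code{shift} map the reference onto the
#' experimental image.
#'
#' @param exp_img,ref Two [particle_image()]s of equal size.
#' @param rot_step In-plane angular step, degrees.
#' @param max_shift Maximum shift searched, pixels; default box/8.
#' @return List with \code{ncc} (in [-1, 1]), \code{psi} (degrees) and
#'   \code{shift} (length-2, pixels).
#' @export
align2d <- function(exp_img, ref, rot_step = 5, max_shift = nrow(exp_img$data) / 8) {
  if (!identical(dim(exp_img$data), dim(ref$data)))
    stop("invalid input: image dimensions differ")
  n <- nrow(exp_img$data)
  refs <- array(ref$data, c(n, n, 1))
  psis <- seq(0, 360 - rot_step, by = rot_step) * DEG2RAD
  res <- cpp_global_search(exp_img$data, refs, psis,
                           circular_mask(n, 0.45 * n), as.integer(max_shift))
  list(ncc = res$ncc[1], psi = res$psi[1] / DEG2RAD,
       shift = c(res$sx[1], res$sy[1]))
}

#' Global angular search: top-xi most similar map projections
#'
#' Aligns an experimental image against every projection of a grid via
#' [align2d()]'s search and returns the \code{xi} best matches by NCC
#' (ties broken by lower grid index).
#'
#' @param exp_img A [particle_image()].
#' @param grid_projections A [project_grid()] result (optionally CTF
#'   filtered), or any list with \code{images} (n x n x n_dir array) and
#'   \code{directions}.
#' @param xi Number of most similar projections to keep (default 7).
#' @param rot_step In-plane angular step, degrees.
#' @param max_shift Maximum shift searched, pixels.
#' @return Object of class \code{MatchSet}: list with \code{directions}
#'   (xi x 3), \code{weights} (NCC, non-increasing), \code{psi}, \code{shift}
#'   (xi x 2), \code{grid_index}.
#' @export
global_search <- function(exp_img, grid_projections, xi = 7, rot_step = 5,
                          max_shift = nrow(exp_img$data) / 8) {
  ndir <- dim(grid_projections$images)[3]
  if (xi > ndir)
    stop("invalid parameter: xi exceeds the number of grid projections")
  n <- nrow(exp_img$data)
  psis <- seq(0, 360 - rot_step, by = rot_step) * DEG2RAD
  res <- cpp_global_search(exp_img$data, grid_projections$images, psis,
                           circular_mask(n, 0.45 * n), as.integer(max_shift))
  ord <- order(-res$ncc, seq_len(ndir))[seq_len(xi)]
  structure(list(directions = grid_projections$directions[ord, , drop = FALSE],
                 weights = res$ncc[ord], psi = res$psi[ord] / DEG2RAD,
                 shift = cbind(res$sx[ord], res$sy[ord]), grid_index = ord),
            class = "MatchSet")
}

#' @export
print.MatchSet <- function(x, ...) {
  cat("MatchSet with", length(x$weights), "matches; NCC range [",
      round(min(x$weights), 3), ",", round(max(x$weights), 3), "]\n")
  invisible(x)
}
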