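# Whole-pipeline driver: for every particle, run the global projection-
# matching search, build its noise-free perfect counterpart, calibrate the
# clusterability and accuracy statistics between the perfect and the
# Monte-Carlo noise references, and summarise the Q value.

#' Particle stack container
#'
#' @param images n x n x N numeric array of particle images.
#' @param pixel_size Pixel size in Angstrom.
#' @return Object of class \code{ParticleStack}.
#' @export
particle_stack <- function(images, pixel_size = 1) {
  if (length(dim(images)) == 2L) images <- array(images, c(dim(images), 1))
  if (length(dim(images)) != 3L || dim(images)[1] != dim(images)[2])
    stop("invalid input: stack must be an n x n x N array of square images")
  structure(list(images = images, pixel_size = pixel_size),
            class = "ParticleStack")
}

#' @export
print.ParticleStack <- function(x, ...) {
  d <- dim(x$images)
  cat("ParticleStack ", d[3], " images of ", d[1], "x", d[2], " px, ",
      x$pixel_size, " A/px\n", sep = "")
  invisible(x)
}

## CTFParams from one row of a particle record table (NULL if absent)
record_ctf <- function(rec) {
  if (!isTRUE(rec$has_ctf)) return(NULL)
  ctf_params(defocus_u = rec$defocus_u, defocus_v = rec$defocus_v,
             astig_angle = rec$astig_angle, voltage = rec$voltage,
             cs = rec$cs, amplitude_contrast = rec$amplitude_contrast,
             phase_shift = rec$phase_shift)
}

#' Per-particle alignment precision and accuracy validation
#'
#' For each particle image: (i) a global alignment search against projections
#' of the map on a regular angular grid yields the top-xi matches, from which
#' the clusterability statistic alpha (precision) and, in full mode, the
#' accuracy statistic chi against the recorded orientation are computed;
#' (ii) the particle's noise-free perfect counterpart (the map projected at
#' the particle's recorded orientation and shift, distorted by the same CTF)
#' is pushed through an identical, independent search to give the good
#' references alpha_good and chi_good; (iii) both statistics are mapped
#' linearly between the Monte-Carlo random-orientation noise reference
#' (score 0) and the perfect reference (score 1). The Q value is the
#' percentage of particles with both scores >= tau.
#'
#' In precision-only mode (no recorded orientations, e.g. ranking ab initio
#' maps) the perfect counterpart is built at the orientation of the
#' particle's own best match and only the precision score is reported.
#'
#' @param vol A [map_volume()].
#' @param stack A [particle_stack()] with the same box and pixel size.
#' @param records Data frame of per-particle metadata as returned by
#'   [read_particles_star()] (orientation + CTF columns); may be NULL in
#'   precision-only mode.
#' @param xi Number of most similar projections kept (default 7).
#' @param delta Angular sampling of the projection grid, degrees (default 5).
#' @param M Monte-Carlo repeats for the noise references (default 500).
#' @param tau Score threshold for the Q value (default 0.5).
#' @param rot_step In-plane search step, degrees (default: delta).
#' @param max_shift Translational search bound, pixels (default box/8).
#' @param sym Point-group label or [symmetry_group()].
#' @param seed Run-level seed; all Monte-Carlo substreams derive from it.
#' @param mode \code{"full"} or \code{"precision"}.
#' @param verbose Print progress every 100 particles.
#' @return Object of class \code{ValidationReport}: list with \code{scores}
#'   (per-particle data frame: alpha, alpha_good, chi, chi_good, q_p, q_a,
#'   pass, flag), \code{Q} (percent, NA in precision mode),
#'   \code{alpha_noise}, and \code{params}.
#' @export
validate_particles <- function(vol, stack, records = NULL, xi = 7, delta = 5,
                               M = 500, tau = 0.5, rot_step = delta,
                               max_shift = NULL, sym = "C1", seed = 1L,
                               mode = c("full", "precision"),
                               verbose = FALSE) {
  mode <- match.arg(mode)
  if (is.character(sym)) sym <- symmetry_group(sym)
  if (!inherits(vol, "MapVolume")) stop("invalid input: vol is not a MapVolume")
  if (!inherits(stack, "ParticleStack")) stop("invalid input: not a ParticleStack")
  n <- dim(vol$data)[1]
  if (dim(stack$images)[1] != n)
    stop("invalid input: stack box size (", dim(stack$images)[1],
         ") does not match map box size (", n, ")")
  if (abs(stack$pixel_size - vol$voxel_size) > 1e-6)
    stop("invalid input: stack pixel size does not match map voxel size")
  N <- dim(stack$images)[3]
  if (is.null(max_shift)) max_shift <- n / 8

  if (mode == "full") {
    if (is.null(records))
      stop("missing orientation: full mode requires particle records ",
           "(columns rot, tilt, psi)")
    if (!all(records$has_orientation))
      stop("missing orientation: records lack angle columns (rot, tilt, psi) ",
           "for ", sum(!records$has_orientation), " particle(s); ",
           "use mode = 'precision' or supply angles")
  }
  if (!is.null(records) && nrow(records) != N)
    stop("invalid input: ", nrow(records), " metadata rows for ", N, " images")

  # reproducible substreams, independent of evaluation order
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, N + 1L))
  grid <- sample_projection_grid(delta, sym)
  gp <- project_grid(vol, grid)
  alpha_noise <- as.numeric(noise_alpha_reference(xi, M, sym, seeds[N + 1L]))

  psis <- seq(0, 360 - rot_step, by = rot_step) * DEG2RAD
  mask <- circular_mask(n, 0.45 * n)

  score_one <- function(m) {
    rec <- if (is.null(records)) NULL else records[m, , drop = FALSE]
    ctf <- if (is.null(rec)) NULL else record_ctf(rec)
    refs <- if (is.null(ctf)) gp$images else
      cpp_filter_cube(gp$images, ctf_image(ctf, n, vol$voxel_size))
    gpm <- list(images = refs, directions = gp$directions)

    exp_img <- particle_image(stack$images[, , m], stack$pixel_size)
    ms <- global_search(exp_img, gpm, xi, rot_step, max_shift)
    alpha_m <- clusterability_alpha(ms, sym)

    # perfect counterpart orientation: recorded, or best match in precision mode
    if (mode == "full") {
      o <- orientation(rec$rot, rec$tilt, rec$psi, rec$shift_x, rec$shift_y)
    } else {
      eu <- direction_to_euler(ms$directions[1, ])
      # align2d's in-plane angle maps the reference onto the image; the
      # equivalent Euler psi of the projection has the opposite sign
      o <- orientation(eu$rot, eu$tilt, -ms$psi[1], ms$shift[1, 1], ms$shift[1, 2])
    }
    perfect <- apply_ctf(project_volume(vol, o), ctf)
    ms_good <- global_search(perfect, gpm, xi, rot_step, max_shift)
    alpha_good <- clusterability_alpha(ms_good, sym)
    q_p <- precision_score(alpha_m, alpha_good, alpha_noise)

    chi_m <- chi_good <- chi_noise <- q_a <- NA_real_
    if (mode == "full") {
      p_hat <- euler_to_direction(rec$rot, rec$tilt)
      chi_m <- accuracy_chi(p_hat, ms, sym)
      chi_good <- accuracy_chi(p_hat, ms_good, sym)
      chi_noise <- as.numeric(noise_chi_reference(p_hat, xi, M, sym, seeds[m]))
      q_a <- accuracy_score(chi_m, chi_good, chi_noise)
    }
    flag <- if (is.na(q_p) || (mode == "full" && is.na(q_a)))
      "degenerate-reference" else "ok"
    if (verbose && m %% 100 == 0) message("  particle ", m, "/", N)
    data.frame(particle = m, alpha = alpha_m, alpha_good = alpha_good,
               chi = chi_m, chi_good = chi_good, chi_noise = chi_noise,
               q_p = q_p, q_a = q_a, flag = flag)
  }

  scores <- do.call(rbind, lapply(seq_len(N), score_one))
  scores$pass <- if (mode == "full")
    !is.na(scores$q_p) & !is.na(scores$q_a) & scores$q_p >= tau & scores$q_a >= tau
  else !is.na(scores$q_p) & scores$q_p >= tau
  Q <- if (mode == "full") q_value(scores, tau) else NA_real_

  structure(list(scores = scores, Q = Q,
                 alpha_noise = as.numeric(alpha_noise),
                 mean_q_p = mean(scores$q_p, na.rm = TRUE),
                 frac_precise = 100 * mean(!is.na(scores$q_p) & scores$q_p >= tau),
                 frac_accurate = if (mode == "full")
                   100 * mean(!is.na(scores$q_a) & scores$q_a >= tau) else NA_real_,
                 params = list(xi = xi, delta = delta, M = M, tau = tau,
                               rot_step = rot_step, max_shift = max_shift,
                               sym = sym$label, seed = seed, mode = mode)),
            class = "ValidationReport")
}

#' @export
print.ValidationReport <- function(x, ...) {
  cat("ValidationReport:", nrow(x$scores), "particles, mode", x$params$mode, "\n")
  if (x$params$mode == "full")
    cat(sprintf("  Q = %.1f%% (precise %.1f%%, accurate %.1f%%) at tau = %g\n",
                x$Q, x$frac_precise, x$frac_accurate, x$params$tau))
  else
    cat(sprintf("  mean q_p = %.3f, precise %.1f%% at tau = %g\n",
                x$mean_q_p, x$frac_precise, x$params$tau))
  invisible(x)
}
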