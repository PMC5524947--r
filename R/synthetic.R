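# Synthetic data: Gaussian-blob phantom volumes and simulated particle
# datasets with ground-truth labels, emulating the populations the scoring
# method is designed to separate — true projections with CTF and additive
# white Gaussian noise, pure-noise images, bright-spot artifact images, and
# wrong-conformation particles from a perturbed phantom.

#' Phantom volume specification
#'
#' A sum of isotropic 3D Gaussian blobs. The default is a deliberately
#' asymmetric (C1) twelve-blob arrangement in a 32-voxel box at 3 A/voxel:
#' many small, well-separated blobs of unequal weight give the projections
#' enough fine, chiral structure to pin down the viewing direction (and to
#' distinguish a view from its mirror-image antipodal view); the
#' default perturbation displaces two blobs by a few voxels to model an
#' alternative conformation.
#'
#' @param box Box size, voxels (even).
#' @param voxel_size Voxel size, Angstrom.
#' @param centers k x 3 matrix of blob centres, voxels relative to the box
#'   centre.
#' @param sigma Length-k blob standard deviations, voxels.
#' @param amplitude Length-k blob amplitudes.
#' @param perturbation k x 3 matrix of displacement vectors (voxels) defining
#'   the alternative conformation.
#' @return Object of class \code{PhantomSpec}.
#' @export
phantom_spec <- function(box = 32, voxel_size = 3,
                         centers = rbind(c(1.78, -0.78, 2.89),
                                         c(-0.11, 3.11, 5.60),
                                         c(-5.14, 1.24, -2.50),
                                         c(5.40, -2.14, 5.12),
                                         c(5.81, -0.80, 1.73),
                                         c(5.57, 5.07, 0.29),
                                         c(-6.29, 1.00, 3.42),
                                         c(-4.73, -1.88, -5.45),
                                         c(4.56, -3.14, 1.83),
                                         c(4.14, 4.92, 2.89),
                                         c(1.26, -0.09, -0.11),
                                         c(6.39, -2.22, 3.30)),
                         sigma = c(1.01, 1.17, 1.73, 1.49, 1.30, 1.35,
                                   1.03, 1.78, 1.35, 1.77, 1.71, 1.51),
                         amplitude = c(0.99, 0.85, 0.73, 0.74, 0.76, 0.91,
                                       0.62, 0.90, 0.87, 0.67, 0.70, 0.81),
                         perturbation = {
                           p <- matrix(0, 12, 3)
                           p[2, ] <- c(3, -2, 2); p[4, ] <- c(-2, 3, -2)
                           p
                         }) {
  centers <- rbind(centers)
  if (any(sigma <= 0)) stop("invalid spec: blob sigma must be positive")
  if (nrow(centers) != length(sigma) || nrow(centers) != length(amplitude))
    stop("invalid spec: centers, sigma and amplitude lengths differ")
  structure(list(box = box, voxel_size = voxel_size, centers = centers,
                 sigma = sigma, amplitude = amplitude,
                 perturbation = rbind(perturbation)), class = "PhantomSpec")
}

#' Rasterise a phantom specification into a map volume
#'
#' @param spec A [phantom_spec()].
#' @param perturbed Apply the spec's displacement set (alternative
#'   conformation)?
#' @return A [map_volume()].
#' @export
make_phantom <- function(spec = phantom_spec(), perturbed = FALSE) {
  n <- spec$box
  ctr <- spec$centers
  if (perturbed) ctr <- ctr + spec$perturbation
  if (any(abs(ctr) + 3 * spec$sigma > n / 2))
    stop("invalid spec: blob extends outside the box")
  ax <- (0:(n - 1)) - n / 2
  vol <- array(0, c(n, n, n))
  for (k in seq_len(nrow(ctr))) {
    gx <- exp(-(ax - ctr[k, 1])^2 / (2 * spec$sigma[k]^2))
    gy <- exp(-(ax - ctr[k, 2])^2 / (2 * spec$sigma[k]^2))
    gz <- exp(-(ax - ctr[k, 3])^2 / (2 * spec$sigma[k]^2))
    vol <- vol + spec$amplitude[k] * (gx %o% gy %o% gz)
  }
  map_volume(vol, spec$voxel_size)
}

## largest-remainder apportionment of n into fractions f (sums to n exactly)
largest_remainder <- function(n, f) {
  raw <- n * f / sum(f)
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    ord <- order(-(raw - cnt), seq_along(f))
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  as.integer(cnt)
}

#' Simulate a labelled particle dataset from a map
#'
#' Signal particles are projections of \code{vol} at uniform random
#' orientations (uniform in-plane angle, shifts up to box/10 pixels),
#' CTF-distorted at a random defocus and degraded with additive white
#' Gaussian noise at the requested SNR (masked signal variance over noise
#' variance). Contaminant classes: \code{noise} (noise only, at the
#' signal-class noise level), \code{artifact} (signal plus one bright
#' Gaussian spot of amplitude 5 x the clean-signal RMS), and \code{altconf}
#' (the same pipeline on the perturbed phantom). A stated fraction of the
#' recorded orientations is replaced by uniform random ones and logged.
#'
#' @param vol A [map_volume()] (the "true" map; used for the signal class).
#' @param n Number of particles.
#' @param snr Target signal-to-noise ratio (variance ratio under the mask);
#'   \code{Inf} for noiseless.
#' @param defocus_range Length-2 defocus range, Angstrom.
#' @param class_fractions Named fractions for classes signal, noise,
#'   artifact, altconf (summing to 1).
#' @param corruption_fraction Fraction of recorded orientations replaced by
#'   random ones.
#' @param spec The [phantom_spec()] used for the altconf class (its
#'   perturbed volume); defaults to [phantom_spec()] when needed.
#' @param seed Integer seed (full determinism).
#' @return Object of class \code{SimulatedDataset}: list with \code{stack}
#'   (a [particle_stack()]), \code{records} (metadata rows as from
#'   [read_particles_star()]), \code{labels} (character class per image),
#'   \code{corrupted} (logical, which recorded orientations were
#'   randomised), \code{true} (data frame of generating orientations) and
#'   \code{clean} (noise-free images, for diagnostics).
#' @export
simulate_dataset <- function(vol, n = 200, snr = 0.1,
                             defocus_range = c(5000, 20000),
                             class_fractions = c(signal = 1, noise = 0,
                                                 artifact = 0, altconf = 0),
                             corruption_fraction = 0,
                             spec = phantom_spec(), seed = 1L) {
  cls_names <- c("signal", "noise", "artifact", "altconf")
  f <- class_fractions[cls_names]
  f[is.na(f)] <- 0
  if (abs(sum(f) - 1) > 1e-9) stop("invalid fractions: must sum to 1")
  counts <- largest_remainder(n, f)
  labels <- rep(cls_names, counts)

  box <- dim(vol$data)[1]
  alt_vol <- if (counts[4] > 0) make_phantom(spec, perturbed = TRUE) else NULL
  mask <- circular_mask(box, 0.45 * box)
  midx <- mask > 0.5

  with_seed(seed, {
    dirs <- random_directions_in_au(n, symmetry_group("C1"), seed = sample.int(2^31 - 2, 1))
    eu <- direction_to_euler(dirs)
    psi <- stats::runif(n, -180, 180)
    sx <- stats::runif(n, -box / 10, box / 10)
    sy <- stats::runif(n, -box / 10, box / 10)
    defocus <- stats::runif(n, defocus_range[1], defocus_range[2])

    images <- array(0, c(box, box, n))
    clean <- array(0, c(box, box, n))
    noise_sd_ref <- NA_real_
    for (m in seq_len(n)) {
      src <- switch(labels[m], signal = vol, artifact = vol,
                    altconf = alt_vol, noise = NULL)
      ctf <- ctf_params(defocus_u = defocus[m])
      if (!is.null(src)) {
        img <- project_volume(src, orientation(eu$rot[m], eu$tilt[m], psi[m],
                                               sx[m], sy[m]))
        img <- apply_ctf(img, ctf)$data
      } else {
        img <- matrix(0, box, box)
      }
      if (labels[m] == "artifact") {
        rms <- sqrt(mean(img[midx]^2))
        spot_c <- stats::runif(2, box / 2 - 0.3 * box, box / 2 + 0.3 * box)
        axx <- (0:(box - 1))
        g <- exp(-(axx - spot_c[1])^2 / (2 * 2.5^2)) %o%
          exp(-(axx - spot_c[2])^2 / (2 * 2.5^2))
        img <- img + 5 * rms * g
      }
      clean[, , m] <- img
      sig_var <- stats::var(img[midx])
      if (labels[m] %in% c("signal", "artifact", "altconf") && is.finite(sig_var))
        noise_sd_ref <- if (is.na(noise_sd_ref)) sqrt(sig_var) else noise_sd_ref
      nsd <- if (is.infinite(snr)) 0 else {
        base_var <- if (labels[m] == "noise") {
          # match the signal-class noise level: variance of a probe projection
          if (is.na(noise_sd_ref)) {
            probe <- apply_ctf(project_volume(vol, orientation(eu$rot[m], eu$tilt[m],
                                                               psi[m], 0, 0)), ctf)$data
            stats::var(probe[midx])
          } else noise_sd_ref^2
        } else sig_var
        sqrt(base_var / snr)
      }
      images[, , m] <- img + if (nsd > 0)
        matrix(stats::rnorm(box * box, 0, nsd), box, box) else 0
    }

    # recorded orientations: true, except a corrupted subset
    n_cor <- round(corruption_fraction * n)
    corrupted <- rep(FALSE, n)
    rec_rot <- eu$rot; rec_tilt <- eu$tilt; rec_psi <- psi
    if (n_cor > 0) {
      idx <- sample.int(n, n_cor)
      corrupted[idx] <- TRUE
      rd <- random_directions_in_au(n_cor, symmetry_group("C1"),
                                    seed = sample.int(2^31 - 2, 1))
      reu <- direction_to_euler(rd)
      rec_rot[idx] <- reu$rot; rec_tilt[idx] <- reu$tilt
      rec_psi[idx] <- stats::runif(n_cor, -180, 180)
    }

    records <- data.frame(rot = rec_rot, tilt = rec_tilt, psi = rec_psi,
                          shift_x = sx, shift_y = sy,
                          defocus_u = defocus, defocus_v = defocus,
                          astig_angle = 0, voltage = 300, cs = 2.7,
                          amplitude_contrast = 0.07, phase_shift = 0,
                          has_orientation = TRUE, has_ctf = TRUE,
                          image_name = sprintf("%06d@stack.mrcs", seq_len(n)),
                          stringsAsFactors = FALSE)
    structure(list(stack = particle_stack(images, vol$voxel_size),
                   records = records, labels = labels, corrupted = corrupted,
                   true = data.frame(rot = eu$rot, tilt = eu$tilt, psi = psi,
                                     shift_x = sx, shift_y = sy),
                   clean = clean, snr = snr, seed = seed),
              class = "SimulatedDataset")
  })
}

#' @export
print.SimulatedDataset <- function(x, ...) {
  cat("SimulatedDataset:", length(x$labels), "particles (",
      paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
            collapse = ", "), "), SNR", x$snr, "\n")
  invisible(x)
}
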