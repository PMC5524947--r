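test_that("projection of a spherically symmetric blob is view independent", {
  # box and width chosen so trilinear interpolation error sits below the
  # 1e-3 bound being asserted
  vol <- gaussian_blob_volume(64, sigma = 7)
  set.seed(21)
  imgs <- lapply(1:20, function(i)
    project_volume(vol, orientation(runif(1, -180, 180), runif(1, 0, 180),
                                    runif(1, -180, 180)))$data)
  ref <- imgs[[1]]
  for (im in imgs[-1]) {
    rel <- sqrt(mean((im - ref)^2)) / sqrt(mean(ref^2))
    expect_lt(rel, 1e-3)
  }
})

test_that("projection conserves mass and is linear in the volume", {
  vol <- make_phantom()
  o <- orientation(35, 70, 10)
  p <- project_volume(vol, o)
  expect_lt(abs(sum(p$data) - sum(vol$data)) / sum(vol$data), 0.005)

  # single central impulse projects to the image centre for any view
  imp <- array(0, c(32, 32, 32)); imp[17, 17, 17] <- 1   # 0-based centre 16
  vimp <- map_volume(imp, 1)
  for (ang in list(c(0, 0), c(40, 55), c(-120, 130))) {
    pi1 <- project_volume(vimp, orientation(ang[1], ang[2], 0))$data
    w <- which(pi1 > 0, arr.ind = TRUE)
    com <- colSums(w * pi1[pi1 > 0]) / sum(pi1)
    expect_equal(unname(com), c(17, 17), tolerance = 0.05)
  }

  v2 <- gaussian_blob_volume(32, sigma = 3)
  a <- 2.5; b <- -1.25
  mix <- map_volume(a * vol$data + b * v2$data, vol$voxel_size)
  pm <- project_volume(mix, o)$data
  plin <- a * project_volume(vol, o)$data + b * project_volume(v2, o)$data
  expect_lt(sqrt(mean((pm - plin)^2)) / sqrt(mean(plin^2)), 1e-6)
})

test_that("CTF evaluation matches its closed forms", {
  ctf <- ctf_params(defocus_u = 10000, voltage = 300, cs = 2.7,
                    amplitude_contrast = 0.1)
  expect_equal(ctf_evaluate(ctf, 0), -0.1)

  # first zero for 1 um underfocus, 300 kV, Cs 2.7 mm, no amplitude contrast:
  # root-find gamma(f) = pi (independent of the CTF expression itself)
  ctf0 <- ctf_params(defocus_u = 10000, voltage = 300, cs = 2.7,
                     amplitude_contrast = 0)
  lambda <- cryoval:::electron_wavelength(300)
  gamma_f <- function(f) pi * lambda * 10000 * f^2 - pi / 2 * 2.7e7 * lambda^3 * f^4
  f_oracle <- uniroot(function(f) gamma_f(f) - pi, c(1e-4, 0.1))$root
  f_impl <- uniroot(function(f) ctf_evaluate(ctf0, f), c(1e-4, 0.1))$root
  expect_lt(abs(f_impl - f_oracle) / f_oracle, 0.01)

  # astigmatism: value at azimuth theta equals the non-astigmatic value at
  # the effective defocus (U+V)/2 + (U-V)/2 cos 2(theta - theta_ast)
  cta <- ctf_params(defocus_u = 15000, defocus_v = 9000, astig_angle = 30)
  for (th in c(0, 0.7, 2.1)) {
    dz <- (15000 + 9000) / 2 + (15000 - 9000) / 2 * cos(2 * (th - 30 * pi / 180))
    expect_equal(ctf_evaluate(cta, 0.05, th),
                 ctf_evaluate(ctf_params(defocus_u = dz), 0.05, 0),
                 tolerance = 1e-12)
  }
})

test_that("applying a CTF is a bounded Fourier multiplier", {
  z <- particle_image(matrix(0, 32, 32), 1.5)
  ctf <- ctf_params(defocus_u = 12000)
  expect_equal(apply_ctf(z, ctf)$data, matrix(0, 32, 32))
  expect_identical(apply_ctf(z, NULL)$data, z$data)   # identity pass-through

  set.seed(22)
  img <- particle_image(matrix(rnorm(32 * 32), 32, 32), 1.5)
  out <- apply_ctf(img, ctf)
  expect_lte(sum(out$data^2), sum(img$data^2) * (1 + 1e-9))
})

test_that("mask normalisation gives zero mean, unit variance, affine invariance", {
  set.seed(23)
  img <- particle_image(matrix(rnorm(32 * 32, 5, 3), 32, 32), 1)
  nrm <- normalize_image(img)
  m <- cryoval:::circular_mask(32, 0.45 * 32) > 0.5
  expect_lt(abs(mean(nrm$data[m])), 1e-9)
  expect_equal(sum(nrm$data[m]^2) / sum(m), 1, tolerance = 1e-9)
  expect_false(attr(nrm, "degenerate"))

  aff <- particle_image(3.7 * img$data + 11, 1)
  expect_equal(normalize_image(aff)$data, nrm$data, tolerance = 1e-9)

  flat <- normalize_image(particle_image(matrix(2, 32, 32), 1))
  expect_true(attr(flat, "degenerate"))
})

test_that("align2d recovers known transformations", {
  vol <- make_phantom()
  ref <- project_volume(vol, orientation(25, 75, 0))

  self <- align2d(ref, ref)
  expect_equal(self$ncc, 1, tolerance = 1e-6)
  expect_equal(self$psi, 0)
  expect_equal(self$shift, c(0, 0))

  shifted <- particle_image(cryoval:::cpp_shift_image(ref$data, 3, -2),
                            ref$pixel_size)
  a <- align2d(shifted, ref, rot_step = 5, max_shift = 4)
  expect_lt(max(abs(a$shift - c(3, -2))), 1)
  expect_equal(a$psi, 0)

  # independent noise pairs: ncc below the permutation-null 99.9th percentile
  set.seed(24)
  null_ncc <- replicate(200, {
    e <- particle_image(matrix(rnorm(1024), 32, 32), 1)
    r <- particle_image(matrix(rnorm(1024), 32, 32), 1)
    align2d(e, r, rot_step = 30, max_shift = 2)$ncc
  })
  e <- particle_image(matrix(rnorm(1024), 32, 32), 1)
  r <- particle_image(matrix(rnorm(1024), 32, 32), 1)
  expect_lte(align2d(e, r, rot_step = 30, max_shift = 2)$ncc,
             quantile(null_ncc, 0.999) + 1e-9)
})

test_that("align2d is symmetric in its arguments up to interpolation error", {
  vol <- make_phantom()
  a <- project_volume(vol, orientation(10, 60, 0))
  b <- project_volume(vol, orientation(10, 60, 40))
  f <- align2d(a, b, rot_step = 5, max_shift = 3)
  g <- align2d(b, a, rot_step = 5, max_shift = 3)
  expect_equal(f$ncc, g$ncc, tolerance = 1e-3)
})

test_that("global search finds the generating grid node and honours xi", {
  vol <- make_phantom()
  grid <- sample_projection_grid(15, symmetry_group("C1"))
  gp <- project_grid(vol, grid)
  j <- 40L
  exact <- particle_image(gp$images[, , j], vol$voxel_size)
  ms <- global_search(exact, gp, xi = 5, rot_step = 10, max_shift = 3)
  expect_identical(ms$grid_index[1], j)
  expect_equal(ms$weights[1], 1, tolerance = 1e-6)
  expect_identical(length(ms$weights), 5L)
  expect_true(all(diff(ms$weights) <= 1e-12))

  # off-grid view: best match within 1.5 * delta of the truth
  off <- project_volume(vol, orientation(33, 61, 17))
  ms2 <- global_search(off, gp, xi = 5, rot_step = 5, max_shift = 3)
  truth <- euler_to_direction(33, 61)
  d1 <- geodesic_distance(truth, ms2$directions[1, ])
  expect_lt(d1 * 180 / pi, 1.5 * 15)

  expect_error(global_search(off, gp, xi = nrow(grid$directions) + 1),
               "xi exceeds")
})
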